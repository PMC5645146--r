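# Brute-force oracles, written in plain R and independent of the package's
# C++ dynamic programming: graph walks are enumerated by explicit recursion
# and strings by literal expansion. Only usable at toy sizes, which is the
# point.

oracle_successors <- function(v, sigma, k) {
  powkm1 <- as.integer(sigma^(k - 1))
  as.integer((v %% powkm1) * sigma + 0:(sigma - 1))
}

# all walks with exactly `ell` edges among alive vertices; returns a list of
# integer vectors (ell + 1 vertices each)
oracle_walks <- function(sigma, k, alive, ell) {
  out <- list()
  recurse <- function(path, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (u in oracle_successors(path[length(path)], sigma, k))
      if (alive[u + 1L]) recurse(c(path, u), left - 1L)
  }
  for (v in which(alive) - 1L) recurse(v, ell)
  out
}

# number of walks (any length >= 0) through each vertex of an acyclic
# residual graph, by enumerating all walks of every length
oracle_paths_through <- function(sigma, k, alive) {
  counts <- numeric(sigma^k)
  maxlen <- sum(alive)
  for (l in 0:maxlen) {
    walks <- oracle_walks(sigma, k, alive, l)
    for (w in walks) {
      for (v in unique(w)) counts[v + 1L] <- counts[v + 1L] + 1L
    }
    if (length(walks) == 0L) break
  }
  counts
}

# Kahn's algorithm in plain R
oracle_is_acyclic <- function(sigma, k, alive) {
  n <- sigma^k
  indeg <- integer(n)
  for (v in which(alive) - 1L) {
    for (u in oracle_successors(v, sigma, k))
      if (alive[u + 1L]) indeg[u + 1L] <- indeg[u + 1L] + 1L
  }
  queue <- which(alive & indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L] - 1L
    queue <- queue[-1L]
    seen <- seen + 1L
    for (u in oracle_successors(v, sigma, k)) {
      if (!alive[u + 1L]) next
      indeg[u + 1L] <- indeg[u + 1L] - 1L
      if (indeg[u + 1L] == 0L) queue <- c(queue, u + 1L)
    }
  }
  seen == sum(alive)
}

# random residual graph over a small space that is acyclic and carries at
# most max_paths walks in total (all lengths)
oracle_random_dag <- function(sigma, k, max_paths = 200) {
  n <- sigma^k
  repeat {
    alive <- runif(n) < runif(1, 0.2, 0.6)
    if (!any(alive)) next
    if (!oracle_is_acyclic(sigma, k, alive)) next
    total <- 0
    ok <- TRUE
    for (l in 0:sum(alive)) {
      w <- length(oracle_walks(sigma, k, alive, l))
      total <- total + w
      if (total > max_paths) { ok <- FALSE; break }
      if (w == 0L) break
    }
    if (ok) return(alive)
  }
}

# every string of length L over the alphabet, as a character vector
oracle_all_strings <- function(chars, L) {
  grid <- do.call(expand.grid,
                  c(rep(list(chars), L), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_len(L)), drop = FALSE], 1L, paste, collapse = "")
}

# does the set (character k-mers) hit every L-long string?
oracle_hits_all <- function(kmers, chars, L) {
  strings <- oracle_all_strings(chars, L)
  for (s in strings) {
    hit <- FALSE
    for (w in kmers) if (grepl(w, s, fixed = TRUE)) { hit <- TRUE; break }
    if (!hit) return(FALSE)
  }
  TRUE
}

# exact minimum UHS size by exhaustive subset search (tiny instances only);
# searches subset sizes from 1 upward so the first hit is the minimum
oracle_min_uhs_size <- function(space, L) {
  n <- space$n_kmers
  all_kmers <- kmer_decode(0:(n - 1L), space)
  strings <- oracle_all_strings(space$chars, L)
  windows <- lapply(strings, function(s) {
    starts <- 1:(nchar(s) - space$k + 1L)
    unique(substring(s, starts, starts + space$k - 1L))
  })
  for (size in 1:n) {
    combos <- utils::combn(n, size)
    for (j in seq_len(ncol(combos))) {
      sel <- all_kmers[combos[, j]]
      if (all(vapply(windows, function(w) any(w %in% sel), logical(1))))
        return(size)
    }
  }
  n
}
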