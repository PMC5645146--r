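test_that("bounded tables satisfy the base case and toy examples", {
  sp <- kmer_space(3, "01")
  g <- residual_graph(sp, mykkeltveit_set(sp))
  tabs <- bounded_tables(g, 3L)
  alive <- g$alive
  expect_true(all(tabs$D[alive, 1] == "1"))  # D(v,0) = 1
  expect_true(all(tabs$F[alive, 1] == "1"))
  expect_true(all(tabs$D[!alive, ] == "0"))

  # two-vertex graph u -> v: 110 -> 101 over {0,1}, k = 3 (no back edge,
  # no self-loops, different rotation classes)
  sp2 <- kmer_space(3, "01")
  keep <- kmer_encode(c("110", "101"), sp2)
  g2 <- residual_graph(sp2, setdiff(0:7, keep))
  t2 <- bounded_tables(g2, 1L)
  u <- kmer_encode("110", sp2) + 1L
  v <- kmer_encode("101", sp2) + 1L
  expect_equal(t2$D[u, 2], "1")
  expect_equal(t2$D[v, 2], "0")
  expect_equal(t2$F[v, 2], "1")
  expect_equal(t2$F[u, 2], "0")
  # path graph of 2 edges: T = 1 everywhere on it
  h2 <- hitting_numbers(bounded_tables(g2, 1L))
  expect_equal(h2[c(u, v)], c("1", "1"))
})

test_that("unbounded tables match the hand-evaluated chain", {
  # chain a -> b -> c over binary 3-mers: 110 -> 100 -> 001; the vertices
  # come from three different rotation classes, so no extra edge closes a
  # cycle among them
  sp <- kmer_space(3, "01")
  keep <- kmer_encode(c("110", "100", "001"), sp)
  g <- residual_graph(sp, setdiff(0:7, keep))
  tt <- unbounded_tables(g)
  a <- kmer_encode("110", sp) + 1L
  b <- kmer_encode("100", sp) + 1L
  cc <- kmer_encode("001", sp) + 1L
  expect_equal(as.numeric(tt$F[c(a, b, cc)]), c(1, 2, 3))
  expect_equal(as.numeric(tt$D[c(a, b, cc)]), c(3, 2, 1))
  expect_equal(as.numeric(tt$T[c(a, b, cc)]), c(3, 4, 3))
})

test_that("longest path and counts agree with brute-force enumeration", {
  set.seed(41)
  for (rep in 1:20) {
    sigma <- 2L
    k <- sample(3:4, 1L)
    alive <- oracle_random_dag(sigma, k, max_paths = 150)
    sp <- kmer_space(k, "01")
    g <- residual_graph(sp, which(!alive) - 1L)

    # longest path by exhaustive walk enumeration
    lp_oracle <- -1L
    for (l in 0:sum(alive)) {
      if (length(oracle_walks(sigma, k, alive, l)) == 0L) break
      lp_oracle <- l
    }
    expect_equal(longest_path_edges(g), lp_oracle)

    if (lp_oracle < 0L) next
    ell <- lp_oracle
    tabs <- bounded_tables(g, ell)
    for (i in 0:ell) {
      walks <- oracle_walks(sigma, k, alive, i)
      expect_equal(sum(as.numeric(tabs$D[, i + 1L])), length(walks))
      expect_equal(sum(as.numeric(tabs$F[, i + 1L])), length(walks))
      # D(v, i) counts walks starting at v
      starts <- table(factor(vapply(walks, `[`, integer(1), 1L),
                             levels = 0:(sp$n_kmers - 1L)))
      expect_equal(as.numeric(tabs$D[, i + 1L]), as.numeric(starts))
    }
    # T(v, ell) counts ell-walks through v; sum identity
    h <- as.numeric(hitting_numbers(tabs))
    walks <- oracle_walks(sigma, k, alive, ell)
    through <- numeric(sp$n_kmers)
    for (w in walks)
      for (v in unique(w)) through[v + 1L] <- through[v + 1L] + 1L
    expect_equal(h, through)
    expect_equal(sum(h), (ell + 1) * length(walks))
  }
})

test_that("length-free counts match all-length enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    alive <- oracle_random_dag(2L, 3L, max_paths = 150)
    sp <- kmer_space(3, "01")
    g <- residual_graph(sp, which(!alive) - 1L)
    tt <- unbounded_tables(g)
    expect_equal(as.numeric(tt$T), oracle_paths_through(2L, 3L, alive))
  }
})

test_that("degenerate graphs are handled", {
  sp <- kmer_space(2, "01")
  g_empty <- residual_graph(sp, 0:3)
  expect_equal(longest_path_edges(g_empty), -1L)
  g_one <- residual_graph(sp, setdiff(0:3, kmer_encode("01", sp)))
  expect_equal(longest_path_edges(g_one), 0L)   # vertex alive, no edge
  h <- hitting_numbers(bounded_tables(g_one, 0L))
  expect_equal(h[kmer_encode("01", sp) + 1L], "1") # the empty path at v
  expect_error(bounded_tables(residual_graph(sp, integer(0)), 2L), "cycle")
})

test_that("exact counts do not overflow at depth", {
  # all 4^k vertices alive minus nothing is cyclic, so count walks on the
  # full graph instead: number of ell-edge walks = sigma^(k + ell) exactly
  # 256 starts times 4^60 step choices = 4^64 = 2^128 walks exactly
  n_walk <- uhskit:::cpp_count_walks(4L, 4L, rep(TRUE, 256), 60L)
  expect_equal(as.character(n_walk),
               "340282366920938463463374607431768211456")
})
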