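#' Window selection schemes
#'
#' A selection scheme picks one k-mer occurrence from every window of w
#' consecutive k-mers (a window of w k-mers spans L = k + w - 1 bases):
#'
#' * `"lexicographic"` -- the classical minimizer: the smallest k-mer in
#'   the window under lexicographic order, leftmost occurrence on ties.
#' * `"random"` -- a minimizer under a seeded pseudo-random total order of
#'   all k-mers; avoids always favouring low-complexity k-mers such as
#'   poly-A.
#' * `"uhs"` -- the lexicographically smallest k-mer in the window *that
#'   belongs to the supplied universal hitting set*. The UHS property for
#'   L = k + w - 1 guarantees every window contains a member (this is
#'   asserted at scan time).
#'
#' @param kind one of `"lexicographic"`, `"random"`, `"uhs"`.
#' @param window window size w in k-mers (w >= 1).
#' @param space a [kmer_space()]; for `"uhs"` inferred from `set`.
#' @param set a [kmer_set()], required for `"uhs"`.
#' @param seed integer seed, required for `"random"`.
#' @return an object of class `selection_scheme`.
#' @export
selection_scheme <- function(kind = c("lexicographic", "random", "uhs"),
                             window, space = NULL, set = NULL, seed = NULL) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("window must be a positive integer", call. = FALSE)
  if (kind == "uhs") {
    if (!inherits(set, "kmer_set"))
      stop("`set` (a kmer_set) is required for the uhs scheme", call. = FALSE)
    space <- set$space
  }
  if (is.null(space))
    stop("`space` is required", call. = FALSE)
  stopifnot_space(space)
  rank <- switch(kind,
    lexicographic = NULL, # rank of a k-mer is its code
    random = {
      if (is.null(seed)) stop("`seed` is required for the random scheme",
                              call. = FALSE)
      random_kmer_order(space, seed)
    },
    uhs = {
      member <- set_membership(set)
      # members keep their code rank; non-members sort after every member
      r <- 0:(space$n_kmers - 1L)
      r[!member] <- r[!member] + space$n_kmers
      r
    })
  structure(list(kind = kind, k = space$k, window = window,
                 L = space$k + window - 1L, space = space,
                 rank = rank, seed = seed),
            class = "selection_scheme")
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat(sprintf("%s selection: k = %d, window = %d k-mers (L = %d)\n",
              x$kind, x$k, x$window, x$L))
  invisible(x)
}

#' Seeded pseudo-random ordering of all k-mers
#'
#' Returns an integer rank vector of length sigma^k: entry code + 1 holds
#' the rank of that k-mer under a seeded random permutation. Deterministic
#' for a given seed; the global random number generator state is left
#' untouched.
#'
#' @param space a [kmer_space()].
#' @param seed integer seed.
#' @return integer vector of ranks 0..sigma^k - 1.
#' @export
random_kmer_order <- function(space, seed) {
  stopifnot_space(space)
  with_local_seed(seed, sample.int(space$n_kmers) - 1L)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic i.i.d. sequence
#'
#' Fixture generator for scanner experiments: each position is drawn
#' independently from `composition`. Deterministic per seed, without
#' touching the global random number generator state.
#'
#' @param length sequence length (>= 1).
#' @param composition probability vector over the alphabet (default
#'   uniform).
#' @param seed integer seed (optional; when omitted the global RNG is
#'   used).
#' @param alphabet the alphabet (default DNA).
#' @return a single string.
#' @export
synth_sequence <- function(length, composition = NULL, seed = NULL,
                           alphabet = "ACGT") {
  space <- kmer_space(1L, alphabet)
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (is.null(composition)) composition <- rep(1, space$sigma)
  if (base::length(composition) != space$sigma || any(composition < 0) ||
      sum(composition) <= 0)
    stop("composition must be a non-negative probability vector over the alphabet",
         call. = FALSE)
  draw <- function() sample(space$chars, length, replace = TRUE,
                            prob = composition)
  chars <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  paste(chars, collapse = "")
}

# split a sequence into maximal runs of alphabet characters; returns a
# list of (offset, chars) pairs (0-based offsets)
split_runs <- function(seq, space) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- chars %in% space$chars
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i)
    list(offset = starts[i] - 1L, chars = chars[starts[i]:ends[i]]))
}

scan_one_run <- function(chars, scheme) {
  space <- scheme$space
  digits <- match(chars, space$chars) - 1L
  codes <- cpp_rolling_codes(digits, space$sigma, space$k)
  if (length(codes) < scheme$window) return(NULL)
  rank <- if (is.null(scheme$rank)) codes else scheme$rank[codes + 1L]
  sel <- cpp_window_select(as.numeric(rank), scheme$window)
  if (scheme$kind == "uhs" &&
      any(scheme$rank[codes[sel + 1L] + 1L] >= space$n_kmers))
    stop("window without a hitting-set member: the supplied set is not a UHS for L = ",
         scheme$L, call. = FALSE)
  list(positions = sel, codes = codes[sel + 1L],
       n_windows = length(codes) - scheme$window + 1L,
       run_length = length(chars))
}

new_scan_report <- function(runs, scheme, sequences_scanned, bases_scanned,
                            skipped_runs) {
  positions <- integer(0)
  codes <- integer(0)
  n_windows <- 0L
  gap_means <- numeric(0)
  gap_weights <- numeric(0)
  for (r in runs) {
    positions <- c(positions, r$offset + r$positions)
    codes <- c(codes, r$codes)
    n_windows <- n_windows + r$n_windows
    if (length(r$positions) >= 2L) {
      gap_means <- c(gap_means, mean(diff(r$positions)))
      gap_weights <- c(gap_weights, r$run_length)
    }
  }
  avg_distance <- if (length(gap_means))
    sum(gap_means * gap_weights) / sum(gap_weights) else NA_real_
  structure(list(
    scheme = scheme$kind, k = scheme$k, window = scheme$window, L = scheme$L,
    distinct_selected = length(unique(codes)),
    selected_positions = positions,
    selected_codes = codes,
    n_selected = length(positions),
    n_windows = n_windows,
    avg_distance = avg_distance,
    sequences_scanned = sequences_scanned,
    bases_scanned = bases_scanned,
    skipped_runs = skipped_runs
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("%s scan (k = %d, L = %d): %d sequence(s), %d bases, %d windows\n",
              x$scheme, x$k, x$L, x$sequences_scanned, x$bases_scanned,
              x$n_windows))
  cat(sprintf("  %d selected positions, %d distinct k-mers, mean gap %.2f\n",
              x$n_selected, x$distinct_selected, x$avg_distance))
  invisible(x)
}

#' Scan a sequence with a selection scheme
#'
#' Applies the scheme to every window of `scheme$window` consecutive
#' k-mers. A k-mer occurrence selected by several overlapping windows is
#' recorded once (selection is position-deduplicated), which is what makes
#' sparse schemes valuable: the fewer distinct selections, the smaller the
#' downstream index. Characters outside the alphabet split the sequence
#' into independent runs; runs shorter than L are skipped with a notice.
#'
#' Reported statistics: `distinct_selected` (distinct selected k-mers),
#' `selected_positions` (0-based start coordinates), and `avg_distance`
#' (mean difference of consecutive selected positions, computed per run
#' and averaged across runs weighted by run length).
#'
#' @param seq a single sequence string.
#' @param scheme a [selection_scheme()].
#' @param quiet suppress skipped-run notices.
#' @return an object of class `scan_report`.
#' @export
select_kmers <- function(seq, scheme, quiet = FALSE) {
  if (!inherits(scheme, "selection_scheme"))
    stop("`scheme` must be a selection_scheme", call. = FALSE)
  if (length(seq) != 1L)
    stop("`seq` must be a single string; use scan_fasta() for sets",
         call. = FALSE)
  runs <- split_runs(seq, scheme$space)
  skipped <- 0L
  out <- list()
  for (r in runs) {
    res <- scan_one_run(r$chars, scheme)
    if (is.null(res)) {
      skipped <- skipped + 1L
      if (!quiet)
        message(sprintf("run of %d bases shorter than L = %d: skipped",
                        length(r$chars), scheme$L))
      next
    }
    res$offset <- r$offset
    out[[length(out) + 1L]] <- res
  }
  new_scan_report(out, scheme, sequences_scanned = 1L,
                  bases_scanned = sum(vapply(runs, function(r)
                    length(r$chars), integer(1))),
                  skipped_runs = skipped)
}

#' Scan a FASTA file with a selection scheme
#'
#' Reads a (plain or gzipped) FASTA file and applies the scheme to every
#' record. Records are split at non-alphabet characters (Ns and ambiguity
#' codes) into runs, each scanned independently; positions are reported
#' per record in the `per_record` list, and the aggregate report pools
#' distinct k-mers across all records and length-weights the per-run mean
#' gaps.
#'
#' @param path FASTA file path.
#' @param scheme a [selection_scheme()].
#' @param quiet suppress skipped-run notices.
#' @return a list with `aggregate` (a `scan_report`) and `per_record`
#'   (named list of `scan_report`s).
#' @export
scan_fasta <- function(path, scheme, quiet = TRUE) {
  if (!inherits(scheme, "selection_scheme"))
    stop("`scheme` must be a selection_scheme", call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  per_record <- list()
  all_runs <- list()
  bases <- 0L
  skipped <- 0L
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    rep_i <- select_kmers(s, scheme, quiet = quiet)
    per_record[[names(seqs)[i]]] <- rep_i
    bases <- bases + rep_i$bases_scanned
    skipped <- skipped + rep_i$skipped_runs
    if (rep_i$n_selected > 0L)
      all_runs[[length(all_runs) + 1L]] <- list(
        offset = 0L, positions = rep_i$selected_positions,
        codes = rep_i$selected_codes, n_windows = rep_i$n_windows,
        run_length = rep_i$bases_scanned,
        gap = rep_i$avg_distance)
  }
  agg <- new_scan_report(list(), scheme, sequences_scanned = length(seqs),
                         bases_scanned = bases, skipped_runs = skipped)
  # pool across records: distinct over the union, gaps length-weighted
  agg$distinct_selected <- length(unique(unlist(lapply(per_record, function(r)
    r$selected_codes))))
  agg$n_selected <- sum(vapply(per_record, function(r) r$n_selected,
                               integer(1)))
  agg$n_windows <- sum(vapply(per_record, function(r) r$n_windows,
                              integer(1)))
  gaps <- vapply(per_record, function(r) r$avg_distance, numeric(1))
  wts <- vapply(per_record, function(r) as.numeric(r$bases_scanned),
                numeric(1))
  ok <- !is.na(gaps)
  agg$avg_distance <- if (any(ok)) sum(gaps[ok] * wts[ok]) / sum(wts[ok])
                      else NA_real_
  agg$selected_positions <- NULL # coordinates are per record
  agg$selected_codes <- NULL
  list(aggregate = agg, per_record = per_record)
}
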