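#' Verify that a k-mer set is a universal hitting set
#'
#' A set is a universal hitting set for window length L when every L-long
#' string over the alphabet contains a member. Two independent oracles are
#' provided. The walk oracle counts the l-edge walks (l = L - k) in the
#' complete de Bruijn graph restricted to non-members -- each avoiding
#' L-long string is exactly one such walk, cycles included, so a positive
#' count certifies failure and the lexicographically smallest avoiding
#' string is reconstructed as a witness. The exhaustive oracle literally
#' enumerates all sigma^L strings; it is only feasible for small sigma^L
#' but is independent of all graph machinery.
#'
#' @param set a [kmer_set()].
#' @param L window length (>= k).
#' @param method `"walk"`, `"exhaustive"`, or `"auto"` (exhaustive when
#'   sigma^L <= `exhaustive_cap`, walk otherwise).
#' @param exhaustive_cap largest sigma^L enumerated in auto mode.
#' @return an object of class `uhs_verification`: list with `is_uhs`,
#'   `method`, `L`, `n_avoiding` (exact count as a decimal string) and
#'   `witness` (the smallest avoiding L-long string, or NA).
#' @examples
#' sp <- kmer_space(2)
#' verify_uhs(kmer_set(0:15, sp), L = 5)$is_uhs   # all k-mers: TRUE
#' @export
verify_uhs <- function(set, L, method = c("auto", "walk", "exhaustive"),
                       exhaustive_cap = 2^20) {
  if (!inherits(set, "kmer_set"))
    stop("`set` must be a kmer_set", call. = FALSE)
  method <- match.arg(method)
  space <- set$space
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < space$k)
    stop("L must be a single integer >= k", call. = FALSE)
  if (method == "auto")
    method <- if (space$sigma^L <= exhaustive_cap) "exhaustive" else "walk"
  members <- set_membership(set)
  if (method == "exhaustive") {
    res <- cpp_exhaustive_avoiding(space$sigma, space$k, L, members)
    n_avoid <- format(res$n_avoiding, scientific = FALSE)
    witness <- if (res$n_avoiding > 0)
      paste(space$chars[res$witness + 1L], collapse = "")
    else NA_character_
  } else {
    ell <- L - space$k
    n_avoid <- as.character(cpp_count_walks(space$sigma, space$k, !members, ell))
    witness <- NA_character_
    if (n_avoid != "0") {
      walk <- cpp_lex_smallest_walk(space$sigma, space$k, !members, ell)
      witness <- spell_path(walk, space)
    }
  }
  structure(list(is_uhs = n_avoid == "0", method = method, L = L,
                 n_avoiding = n_avoid, witness = witness),
            class = "uhs_verification")
}

#' @export
print.uhs_verification <- function(x, ...) {
  if (x$is_uhs) {
    cat(sprintf("valid universal hitting set for L = %d (%s oracle)\n",
                x$L, x$method))
  } else {
    cat(sprintf("NOT a universal hitting set for L = %d (%s oracle): %s avoiding string(s)\n",
                x$L, x$method, x$n_avoiding))
    if (!is.na(x$witness)) cat(sprintf("  smallest witness: %s\n", x$witness))
  }
  invisible(x)
}

#' Extend a universal hitting set to larger k
#'
#' Appends every j-mer to every member: the extension of a (k, L) set U is
#' \{w.x : w in U, x in Sigma^j\}, a (k+j, L+j) universal hitting set of
#' exactly |U| * sigma^j members (every (L+j)-long string has an L-long
#' prefix hit by some w, and the k+j window starting there is w.x for some
#' x). Useful when k+j is beyond the reach of direct computation; the
#' price is a larger approximation factor.
#'
#' @param set a [kmer_set()] trusted or verified as a (k, L) UHS.
#' @param j number of characters to append (>= 1).
#' @return a [kmer_set()] in the (k + j)-mer space, provenance inherited.
#' @export
extend_uhs <- function(set, j) {
  if (!inherits(set, "kmer_set"))
    stop("`set` must be a kmer_set", call. = FALSE)
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L)
    stop("j must be a positive integer", call. = FALSE)
  space <- set$space
  newspace <- kmer_space(space$k + j, space$chars)
  sj <- space$sigma^j
  base <- set$codes * sj
  codes <- as.integer(outer(0:(sj - 1L), base, `+`))
  prov <- rep(set$provenance, each = sj)
  kmer_set(codes, newspace, provenance = prov)
}

#' Approximation factor relative to the decycling lower bound
#'
#' The ratio of the set size to the conjugacy-class count C(sigma, k),
#' which lower-bounds every universal hitting set. Returned as a numeric
#' scalar carrying the exact reduced fraction in attributes `numerator`
#' and `denominator`.
#'
#' @param set a [kmer_set()] or [docks()]-style `uhs_result`.
#' @return numeric scalar >= 1 for any valid UHS (1 for the decycling set).
#' @export
approximation_factor <- function(set) {
  if (inherits(set, "uhs_result")) set <- set$set
  if (!inherits(set, "kmer_set"))
    stop("`set` must be a kmer_set or uhs_result", call. = FALSE)
  num <- length(set$codes)
  den <- num_conjugacy_classes(set$space$sigma, set$space$k)
  g <- gcd_int(as.integer(num), as.integer(den))
  if (g == 0L) g <- 1L
  structure(num / den, numerator = num / g, denominator = den / g)
}

#' Read and write plain-text k-mer set files
#'
#' The interchange format is one k-mer per line, uppercase, uniform
#' length; blank lines are ignored. `read_kmer_set()` infers k from the
#' file (a declared `k` that disagrees is an error, not a warning);
#' `write_kmer_set()` writes members sorted by encoding, so write/read
#' round-trips are identities.
#'
#' @param path file path.
#' @param alphabet alphabet of the set file (default DNA).
#' @param k optional declared word length to validate against.
#' @param set a [kmer_set()].
#' @return `read_kmer_set()` returns a [kmer_set()] (provenance
#'   `"user"`); `write_kmer_set()` returns `path` invisibly.
#' @export
read_kmer_set <- function(path, alphabet = "ACGT", k = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- trimws(lines)
  if (length(lines) == 0L)
    stop("no k-mers found in file", call. = FALSE)
  lens <- unique(nchar(lines))
  if (length(lens) != 1L)
    stop(sprintf("ragged k-mer lengths in file: %s",
                 paste(sort(lens), collapse = ", ")), call. = FALSE)
  if (!is.null(k) && as.integer(k) != lens)
    stop(sprintf("file contains %d-mers but k = %d was declared",
                 lens, as.integer(k)), call. = FALSE)
  space <- kmer_space(lens, alphabet)
  kmer_set(kmer_encode(lines, space), space, provenance = "user")
}

#' @rdname read_kmer_set
#' @export
write_kmer_set <- function(set, path) {
  if (!inherits(set, "kmer_set"))
    stop("`set` must be a kmer_set", call. = FALSE)
  writeLines(kmer_decode(set$codes, set$space), path)
  invisible(path)
}
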