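#' k-mer space: an alphabet together with a word length
#'
#' A `kmer_space` fixes an ordered alphabet and a word length `k`, and with
#' them a bijective integer encoding of all sigma^k k-mers: the first
#' character is the most significant base-sigma digit, so integer order
#' equals lexicographic order. Codes are 0-based; code 0 is the
#' lexicographically smallest k-mer and sigma^k - 1 the largest. The
#' complete de Bruijn graph of order k (one vertex per k-mer, one edge per
#' (k+1)-mer) is implicit in the encoding: neighbours are computed
#' arithmetically and no adjacency structure is ever materialized.
#'
#' @param k word length, a positive integer.
#' @param alphabet the ordered alphabet, either a single string
#'   (e.g. `"ACGT"`, the default) or a character vector of single
#'   characters. Symbol order defines both lexicographic order and the
#'   digit values 0..sigma-1.
#' @return An object of class `kmer_space` with fields `chars`, `sigma`,
#'   `k` and `n_kmers`.
#' @examples
#' sp <- kmer_space(3)
#' kmer_encode("ACG", sp)   # 6
#' kmer_decode(6L, sp)      # "ACG"
#' @export
kmer_space <- function(k, alphabet = "ACGT") {
  if (length(alphabet) == 1L && nchar(alphabet) > 1L)
    alphabet <- strsplit(alphabet, "", fixed = TRUE)[[1L]]
  alphabet <- as.character(alphabet)
  if (any(nchar(alphabet) != 1L))
    stop("alphabet symbols must be single characters", call. = FALSE)
  if (anyDuplicated(alphabet))
    stop("alphabet symbols must be unique", call. = FALSE)
  sigma <- length(alphabet)
  if (sigma < 2L)
    stop("alphabet must have at least 2 symbols", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a positive integer", call. = FALSE)
  if (sigma^k > .Machine$integer.max)
    stop("sigma^k exceeds the supported range", call. = FALSE)
  structure(
    list(chars = alphabet, sigma = sigma, k = k,
         n_kmers = as.integer(sigma^k)),
    class = "kmer_space"
  )
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("k-mer space: k = %d over {%s} (%d k-mers)\n",
              x$k, paste(x$chars, collapse = ","), x$n_kmers))
  invisible(x)
}

stopifnot_space <- function(space) {
  if (!inherits(space, "kmer_space"))
    stop("`space` must be a kmer_space object", call. = FALSE)
}

check_codes <- function(codes, space) {
  codes <- as.integer(codes)
  if (any(is.na(codes)) || any(codes < 0L) || any(codes >= space$n_kmers))
    stop("k-mer codes must lie in [0, sigma^k)", call. = FALSE)
  codes
}

#' Encode k-mers as integers
#'
#' Maps words to their 0-based integer codes (first character most
#' significant), the inverse of [kmer_decode()]. Encoding is
#' order-preserving: code order equals lexicographic word order.
#'
#' @param words character vector of words, each of length `space$k`.
#' @param space a [kmer_space()].
#' @return integer vector of codes in `[0, sigma^k)`.
#' @export
kmer_encode <- function(words, space) {
  stopifnot_space(space)
  words <- as.character(words)
  if (length(words) == 0L) return(integer(0))
  if (any(nchar(words) != space$k))
    stop(sprintf("words must have length k = %d", space$k), call. = FALSE)
  chars <- matrix(unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE),
                  nrow = space$k)
  digits <- match(chars, space$chars) - 1L
  if (any(is.na(digits))) {
    bad <- unique(chars[is.na(match(chars, space$chars))])
    stop(sprintf("invalid symbol(s): %s", paste(bad, collapse = " ")),
         call. = FALSE)
  }
  dim(digits) <- dim(chars)
  pow <- space$sigma^((space$k - 1L):0L)
  as.integer(colSums(digits * pow))
}

#' Decode integer codes back to k-mers
#'
#' @param codes integer vector of codes in `[0, sigma^k)`.
#' @inheritParams kmer_encode
#' @return character vector of words.
#' @export
kmer_decode <- function(codes, space) {
  stopifnot_space(space)
  codes <- check_codes(codes, space)
  if (length(codes) == 0L) return(character(0))
  out <- matrix("", nrow = space$k, ncol = length(codes))
  for (j in seq_len(space$k)) {
    pow <- space$sigma^(space$k - j)
    out[j, ] <- space$chars[(codes %/% pow) %% space$sigma + 1L]
  }
  apply(out, 2L, paste, collapse = "")
}

kmer_digits <- function(codes, space) {
  # k x length(codes) matrix of digit values, first character in row 1
  d <- matrix(0L, nrow = space$k, ncol = length(codes))
  for (j in seq_len(space$k)) {
    pow <- space$sigma^(space$k - j)
    d[j, ] <- (codes %/% pow) %% space$sigma
  }
  d
}

#' Successors and predecessors in the complete de Bruijn graph
#'
#' The successors of k-mer w are the sigma words w_2..w_k c for each
#' alphabet character c (in alphabet order); predecessors are defined
#' symmetrically as c w_1..w_(k-1). Every vertex of the complete graph has
#' out- and in-degree sigma; constant words carry a self-loop.
#'
#' @param codes integer vector of k-mer codes.
#' @inheritParams kmer_encode
#' @return an integer matrix with `length(codes)` rows and `sigma` columns;
#'   row i holds the neighbour codes of `codes[i]` in alphabet order.
#' @export
kmer_successors <- function(codes, space) {
  stopifnot_space(space)
  codes <- check_codes(codes, space)
  powkm1 <- space$sigma^(space$k - 1L)
  base <- (codes %% powkm1) * space$sigma
  outer(base, 0L:(space$sigma - 1L), `+`)
}

#' @rdname kmer_successors
#' @export
kmer_predecessors <- function(codes, space) {
  stopifnot_space(space)
  codes <- check_codes(codes, space)
  powkm1 <- space$sigma^(space$k - 1L)
  base <- codes %/% space$sigma
  outer(rep(0L, length(codes)), 0L:(space$sigma - 1L) * powkm1, `+`) + base
}

rotate_codes <- function(codes, space) {
  # left rotation: w_1 w_2..w_k -> w_2..w_k w_1
  powkm1 <- space$sigma^(space$k - 1L)
  (codes %% powkm1) * space$sigma + codes %/% powkm1
}

#' Spell the string represented by a path
#'
#' A path of n edges through the de Bruijn graph spells a string of n + k
#' characters in which the label of the i-th vertex occurs at position i.
#' Consecutive vertices must overlap in k - 1 characters (i.e. be joined by
#' an edge); otherwise an invalid-path error is raised.
#'
#' @param codes integer vector of vertex codes along the path (length >= 1).
#' @inheritParams kmer_encode
#' @return a single string of length `length(codes) - 1 + k`.
#' @export
spell_path <- function(codes, space) {
  stopifnot_space(space)
  codes <- check_codes(codes, space)
  if (length(codes) == 0L)
    stop("path must contain at least one vertex", call. = FALSE)
  if (length(codes) > 1L) {
    powkm1 <- space$sigma^(space$k - 1L)
    from <- codes[-length(codes)]
    to <- codes[-1L]
    ok <- (to %/% space$sigma) == (from %% powkm1)
    if (!all(ok))
      stop(sprintf("vertices %d and %d are not joined by an edge",
                   which(!ok)[1L] - 1L, which(!ok)[1L]), call. = FALSE)
  }
  first <- kmer_decode(codes[1L], space)
  if (length(codes) == 1L) return(first)
  tail_chars <- space$chars[codes[-1L] %% space$sigma + 1L]
  paste0(first, paste(tail_chars, collapse = ""))
}

#' Conjugacy class (rotation class) of a k-mer
#'
#' The conjugacy class of w is the set of k-mers obtained by rotating w;
#' classes partition the k-mers, the class size divides k, and each class
#' is a cycle of the complete de Bruijn graph (the "pure rotation" cycle).
#'
#' @param code a single k-mer code.
#' @inheritParams kmer_encode
#' @return sorted integer vector of the distinct rotation codes.
#' @export
conjugacy_class <- function(code, space) {
  stopifnot_space(space)
  code <- check_codes(code, space)
  if (length(code) != 1L)
    stop("`code` must be a single k-mer", call. = FALSE)
  out <- integer(space$k)
  v <- code
  for (i in seq_len(space$k)) {
    out[i] <- v
    v <- rotate_codes(v, space)
  }
  sort(unique(out))
}

#' Number of conjugacy classes
#'
#' Evaluates the necklace-counting formula
#' C(sigma, k) = (1/k) * sum over i = 1..k of sigma^gcd(i, k),
#' the number of rotation classes of length-k words over a sigma-letter
#' alphabet. This is also the cardinality of a minimum decycling set of the
#' complete de Bruijn graph (Golomb's conjecture, proved by Mykkeltveit),
#' and therefore a lower bound on the size of any universal hitting set.
#'
#' @param sigma alphabet size (>= 2).
#' @param k word length (>= 1).
#' @return the exact count as a numeric scalar.
#' @examples
#' num_conjugacy_classes(4, 6)  # 700
#' @export
num_conjugacy_classes <- function(sigma, k) {
  sigma <- as.integer(sigma); k <- as.integer(k)
  if (sigma < 2L || k < 1L) stop("need sigma >= 2 and k >= 1", call. = FALSE)
  g <- vapply(seq_len(k), function(i) gcd_int(i, k), integer(1))
  total <- sum(as.numeric(sigma)^g)
  if (total / k > 2^53)
    stop("count exceeds exact double range", call. = FALSE)
  cls <- total / k
  stopifnot(cls == round(cls))
  cls
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' k-mer set container
#'
#' A set of k-mers from one [kmer_space()], stored as sorted unique codes
#' with an optional per-member provenance tag recording which phase
#' contributed the member (`"decycling"`, `"additional"` or `"user"`).
#'
#' @param codes integer vector of member codes (or character vector of
#'   words, which are encoded first).
#' @param space a [kmer_space()].
#' @param provenance a single tag or a vector parallel to `codes`.
#' @return an object of class `kmer_set`.
#' @export
kmer_set <- function(codes, space, provenance = "user") {
  stopifnot_space(space)
  if (is.character(codes)) codes <- kmer_encode(codes, space)
  codes <- check_codes(codes, space)
  if (length(provenance) == 1L)
    provenance <- rep(provenance, length(codes))
  if (length(provenance) != length(codes))
    stop("provenance must be scalar or parallel to codes", call. = FALSE)
  keep <- !duplicated(codes)
  codes <- codes[keep]; provenance <- provenance[keep]
  ord <- order(codes)
  structure(
    list(space = space, codes = codes[ord],
         provenance = as.character(provenance)[ord]),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("k-mer set: %d of %d %d-mers (%s)\n",
              length(x$codes), x$space$n_kmers, x$space$k,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$codes)

#' @export
as.character.kmer_set <- function(x, ...) kmer_decode(x$codes, x$space)

set_membership <- function(set) {
  # logical mask over all sigma^k codes
  m <- logical(set$space$n_kmers)
  m[set$codes + 1L] <- TRUE
  m
}
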