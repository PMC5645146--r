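#' Complex embedding of a k-mer
#'
#' The order-0 embedding of w = w_0 w_1 ... w_(k-1) is
#' sum_j d_j * u^j with u = exp(2*pi*i/k) and d_j the digit value of
#' character j. Left rotation of the word multiplies the order-0 embedding
#' by u^(-1), so the embeddings of a conjugacy class form the orbit of one
#' point under rotation by -2*pi/k; this is the geometry behind
#' Mykkeltveit's minimum decycling set. All words of period smaller than k
#' (in particular the constant words) embed to 0. Higher orders t weight
#' digit j by j^t; they are exposed for diagnostics and for asserting the
#' rotation identity, and are not used by the selection rule.
#'
#' @param codes integer vector of k-mer codes.
#' @param space a [kmer_space()].
#' @param t moment order, a non-negative integer (default 0).
#' @return complex vector of embeddings.
#' @export
embedding <- function(codes, space, t = 0L) {
  stopifnot_space(space)
  codes <- check_codes(codes, space)
  t <- as.integer(t)
  if (t < 0L) stop("t must be >= 0", call. = FALSE)
  k <- space$k
  u <- exp(2i * pi / k)
  j <- 0:(k - 1)
  wj <- if (t == 0L) rep(1, k) else j^t
  d <- kmer_digits(codes, space) # k x m
  as.vector(crossprod(d, wj * u^j))
}

#' Mykkeltveit minimum decycling set
#'
#' Computes a minimum-size set of k-mers whose removal leaves the complete
#' de Bruijn graph acyclic (equivalently, a minimum unavoidable set of
#' constant length: every infinite sequence, and hence every sufficiently
#' long finite one, contains a member). The set has exactly one member per
#' conjugacy class, hence cardinality [num_conjugacy_classes()], which is
#' the proven minimum.
#'
#' Selection follows the embedding geometry (see [embedding()]): the
#' conjugacy-class orbit of a word with nonzero embedding visits k equally
#' spaced angles, so any half-open sector of width 2*pi/k contains exactly
#' one member. This implementation selects, in each nonzero class, the
#' member whose embedding argument lies in the sector starting at the ray
#' at angle pi - 2*pi/k and ending (exclusively) at the negative real
#' axis; members exactly on the starting ray are included. In each
#' zero-embedding class (all words of period < k, plus the aperiodic words
#' whose digit sums cancel) the lexicographically smallest rotation is
#' selected, and the constant words (singleton classes carrying
#' self-loops) are always included. These conventions reproduce the
#' residual longest-path lengths of the reference decycling sets for DNA
#' across k = 3..10; the construction verifies one-per-class membership,
#' minimality and acyclicity of the residual graph before returning and
#' fails loudly otherwise.
#'
#' @param space a [kmer_space()].
#' @param max_vertices resource guard: refuse spaces with more than this
#'   many k-mers (default 4^12).
#' @return a [kmer_set()] with provenance `"decycling"`.
#' @examples
#' length(mykkeltveit_set(kmer_space(6)))  # 700
#' @export
mykkeltveit_set <- function(space, max_vertices = 4^12) {
  stopifnot_space(space)
  if (space$n_kmers > max_vertices)
    stop("sigma^k exceeds max_vertices; raise the cap to proceed",
         call. = FALSE)
  k <- space$k
  n <- space$n_kmers
  sigma <- space$sigma
  codes <- 0:(n - 1L)

  # constant words are their own class and always belong to the set
  const_codes <- as.integer(round((0:(sigma - 1L)) * (n - 1) / (sigma - 1)))
  if (k == 1L)
    return(kmer_set(codes, space, provenance = "decycling"))

  # class representative = minimum over rotations
  r <- codes
  rep_ <- codes
  for (i in seq_len(k - 1L)) {
    r <- rotate_codes(r, space)
    rep_ <- pmin(rep_, r)
  }

  tol <- 1e-9 * k
  P <- embedding(codes, space, 0L)
  nz <- Mod(P) > tol

  # angular position past the selection ray, snapped so that members
  # exactly on the ray sort first (floating noise cannot flip a boundary
  # member to position ~2*pi)
  ray <- pi - 2 * pi / k
  pos <- (Arg(P) - ray) %% (2 * pi)
  on_ray <- pmin(pos, 2 * pi - pos) < 1e-9
  pos[on_ray] <- 0

  nz_codes <- codes[nz]
  ord <- order(rep_[nz_codes + 1L], pos[nz_codes + 1L], nz_codes)
  nz_sorted <- nz_codes[ord]
  sel_nz <- nz_sorted[!duplicated(rep_[nz_sorted + 1L])]

  zero_mask <- !nz
  zero_mask[const_codes + 1L] <- FALSE
  sel_zero <- integer(0)
  if (any(zero_mask)) {
    zc <- codes[zero_mask]
    sel_zero <- as.integer(vapply(split(zc, rep_[zc + 1L]), min, numeric(1)))
  }

  selected <- c(sel_nz, const_codes, sel_zero)

  # loud validation: one per class, minimal cardinality, acyclic residual
  sel_reps <- rep_[selected + 1L]
  if (anyDuplicated(sel_reps) ||
      length(selected) != num_conjugacy_classes(sigma, k))
    stop("internal error: decycling selection is not one-per-class",
         call. = FALSE)
  alive <- rep(TRUE, n)
  alive[selected + 1L] <- FALSE
  if (!cpp_is_acyclic(sigma, k, alive))
    stop("internal error: residual graph is not acyclic", call. = FALSE)

  kmer_set(sort(selected), space, provenance = "decycling")
}

#' Length of the longest sequence avoiding a k-mer set
#'
#' After removing `removed` from the complete de Bruijn graph the residual
#' graph must be acyclic; the longest surviving directed path of n edges
#' spells the longest avoiding sequence, of n + k characters. Returns
#' k - 1 when no vertex survives (even single k-mers are hit); raises an
#' error when the residual graph still contains a cycle (i.e. `removed`
#' is not a decycling set, so arbitrarily long avoiding sequences exist).
#'
#' @param space a [kmer_space()].
#' @param removed a [kmer_set()] of removed k-mers.
#' @return integer sequence length.
#' @export
longest_avoiding_sequence_length <- function(space, removed) {
  stopifnot_space(space)
  if (!inherits(removed, "kmer_set"))
    stop("`removed` must be a kmer_set", call. = FALSE)
  alive <- !set_membership(removed)
  cpp_longest_path(space$sigma, space$k, alive) + space$k
}
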