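#' Greedy universal hitting set heuristics
#'
#' All heuristics share the two-phase structure: remove a minimum decycling
#' set (phase one, solved optimally by [mykkeltveit_set()]), then remove
#' further vertices from the residual DAG until no path of l = L - k edges
#' survives, so that every L-long string must contain a member.
#'
#' * `docks()` scores each vertex by its hitting number T(v, l), the exact
#'   number of l-edge paths through it, recomputed after every removal;
#'   the vertex with the largest score is removed (ties broken by the
#'   lexicographically smallest k-mer).
#' * `docks_any()` scores vertices by the length-free T(v) = F(v) * D(v),
#'   the number of paths of any length through v. The removal order is
#'   then independent of L: L only determines the stopping point, so the
#'   removal log for a larger L is a prefix of the log for a smaller L.
#' * `docks_any_x()` accelerates `docks_any()` by removing the `X`
#'   highest-scoring vertices per iteration (X = 1 is bit-for-bit
#'   identical to `docks_any()`).
#' * `greedy_baseline()` skips the decycling phase entirely and greedily
#'   removes maximum-hitting-number vertices from the full cyclic graph,
#'   scoring by l-edge walk counts, until no l-edge walk remains. It is a
#'   reference point, not a recommended method: it is far slower and
#'   usually produces larger sets.
#'
#' @param space a [kmer_space()].
#' @param L window length; must exceed k.
#' @param X batch size per iteration for `docks_any_x()`.
#' @param max_vertices resource guard passed to the decycling phase
#'   (`greedy_baseline()` applies it to sigma^k directly).
#' @param progress_every if positive, report progress to standard error
#'   every this many removals.
#' @return an object of class `uhs_result`: a list with the `set` (a
#'   [kmer_set()] tagging decycling and additional members), `params`,
#'   an `iterations` data frame logging each removal (code, k-mer and
#'   exact score as a decimal string, in removal order) and the
#'   conjugacy-class `lower_bound`.
#' @examples
#' res <- docks(kmer_space(3), L = 8)
#' res$size
#' @name docks_heuristics
NULL

check_L <- function(space, L) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L <= space$k)
    stop("L must be a single integer greater than k", call. = FALSE)
  L
}

uhs_result <- function(space, L, method, decycling, additional, scores,
                       X = NA_integer_) {
  codes <- c(decycling$codes, additional)
  prov <- c(rep("decycling", length(decycling$codes)),
            rep("additional", length(additional)))
  set <- kmer_set(codes, space, provenance = prov)
  structure(list(
    set = set,
    size = length(set),
    params = list(sigma = space$sigma, k = space$k, L = L,
                  ell = L - space$k, method = method, X = X),
    iterations = data.frame(
      iter = seq_along(additional),
      code = as.integer(additional),
      kmer = if (length(additional)) kmer_decode(additional, space) else character(0),
      score = as.character(scores),
      stringsAsFactors = FALSE),
    lower_bound = num_conjugacy_classes(space$sigma, space$k)
  ), class = "uhs_result")
}

#' @export
print.uhs_result <- function(x, ...) {
  cat(sprintf("universal hitting set: k = %d, L = %d, method = %s\n",
              x$params$k, x$params$L, x$params$method))
  cat(sprintf("  size %d = %d decycling + %d additional (lower bound %d, factor %.3f)\n",
              x$size, sum(x$set$provenance == "decycling"),
              sum(x$set$provenance == "additional"), x$lower_bound,
              x$size / x$lower_bound))
  invisible(x)
}

#' @rdname docks_heuristics
#' @export
docks <- function(space, L, max_vertices = 4^12, progress_every = 0L) {
  stopifnot_space(space)
  L <- check_L(space, L)
  dec <- mykkeltveit_set(space, max_vertices = max_vertices)
  alive <- !set_membership(dec)
  run <- cpp_docks_run(space$sigma, space$k, alive, L - space$k,
                       as.integer(progress_every))
  uhs_result(space, L, "docks", dec, run$removed, run$scores)
}

#' @rdname docks_heuristics
#' @export
docks_any <- function(space, L, max_vertices = 4^12, progress_every = 0L) {
  res <- docks_any_x(space, L, X = 1L, max_vertices = max_vertices,
                     progress_every = progress_every)
  res$params$method <- "docksany"
  res$params$X <- NA_integer_
  res
}

#' @rdname docks_heuristics
#' @export
docks_any_x <- function(space, L, X, max_vertices = 4^12,
                        progress_every = 0L) {
  stopifnot_space(space)
  L <- check_L(space, L)
  X <- as.integer(X)
  if (length(X) != 1L || is.na(X) || X < 1L)
    stop("X must be a positive integer", call. = FALSE)
  dec <- mykkeltveit_set(space, max_vertices = max_vertices)
  alive <- !set_membership(dec)
  run <- cpp_docksany_run(space$sigma, space$k, alive, L - space$k, X,
                          as.integer(progress_every))
  uhs_result(space, L, "docksanyX", dec, run$removed, run$scores, X = X)
}

#' @rdname docks_heuristics
#' @export
greedy_baseline <- function(space, L, max_vertices = 4^8,
                            progress_every = 0L) {
  stopifnot_space(space)
  L <- check_L(space, L)
  if (space$n_kmers > max_vertices)
    stop("sigma^k exceeds max_vertices; raise the cap to proceed",
         call. = FALSE)
  run <- cpp_greedy_baseline_run(space$sigma, space$k, L - space$k,
                                 as.integer(progress_every))
  empty_dec <- kmer_set(integer(0), space, provenance = "decycling")
  res <- uhs_result(space, L, "greedy-baseline", empty_dec,
                    run$removed, run$scores)
  # the removed set must break every cycle, or arbitrarily long walks remain
  if (!cpp_is_acyclic(space$sigma, space$k, !set_membership(res$set)))
    stop("internal error: greedy baseline left a cycle unhit", call. = FALSE)
  res
}
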