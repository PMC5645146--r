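#' Residual graph after vertex removal
#'
#' The complete de Bruijn graph of order k restricted to the k-mers not in
#' `removed`. The graph is implicit (neighbours are computed
#' arithmetically); this object only records which vertices survive.
#'
#' @param space a [kmer_space()].
#' @param removed a [kmer_set()], or an integer vector of removed codes.
#' @return an object of class `residual_graph`.
#' @export
residual_graph <- function(space, removed) {
  stopifnot_space(space)
  if (inherits(removed, "kmer_set")) {
    if (!identical(removed$space$chars, space$chars) ||
        removed$space$k != space$k)
      stop("`removed` comes from a different k-mer space", call. = FALSE)
    removed <- removed$codes
  }
  removed <- check_codes(removed, space)
  alive <- rep(TRUE, space$n_kmers)
  alive[removed + 1L] <- FALSE
  structure(list(space = space, alive = alive),
            class = "residual_graph")
}

#' @export
print.residual_graph <- function(x, ...) {
  cat(sprintf("residual de Bruijn graph: %d of %d %d-mers alive\n",
              sum(x$alive), x$space$n_kmers, x$space$k))
  invisible(x)
}

stopifnot_graph <- function(g) {
  if (!inherits(g, "residual_graph"))
    stop("expected a residual_graph object", call. = FALSE)
}

#' Longest directed path in the residual DAG
#'
#' Number of edges in the longest directed path. Raises a not-a-DAG error
#' when the residual graph still contains a cycle. Returns -1 when no
#' vertex is alive and 0 when vertices survive but no edge does.
#'
#' @param g a [residual_graph()].
#' @return integer edge count.
#' @export
longest_path_edges <- function(g) {
  stopifnot_graph(g)
  cpp_longest_path(g$space$sigma, g$space$k, g$alive)
}

#' l-bounded path-count tables
#'
#' Computes the dynamic-programming tables D(v, i) (the exact number of
#' i-edge paths starting at v) and F(v, i) (ending at v) for 0 <= i <= l,
#' via D(v, 0) = F(v, 0) = 1 and
#' D(v, i) = sum of D(u, i-1) over edges (v, u),
#' F(v, i) = sum of F(u, i-1) over edges (u, v).
#' Counts are exact arbitrary-precision integers, returned as decimal
#' character matrices (they overflow doubles well inside the supported
#' parameter range); `as.numeric()` converts small entries.
#'
#' @param g a [residual_graph()] (must be acyclic).
#' @param ell maximum path length in edges (l = L - k).
#' @return an object of class `path_count_tables`: a list with character
#'   matrices `D` and `F` (rows = vertices in code order, columns =
#'   lengths 0..l) and the scalar `ell`.
#' @export
bounded_tables <- function(g, ell) {
  stopifnot_graph(g)
  ell <- as.integer(ell)
  if (ell < 0L) stop("ell must be >= 0", call. = FALSE)
  if (!cpp_is_acyclic(g$space$sigma, g$space$k, g$alive))
    stop("residual graph contains a directed cycle", call. = FALSE)
  tabs <- cpp_bounded_counts(g$space$sigma, g$space$k, g$alive, ell)
  structure(list(D = tabs$D, F = tabs$F, ell = ell, space = g$space,
                 alive = g$alive),
            class = "path_count_tables")
}

#' Hitting numbers from bounded tables
#'
#' The hitting number T(v, l) is the exact number of l-edge paths through
#' v, assembled from the bounded tables by splitting each path at v:
#' T(v, l) = sum over i of F(v, i) * D(v, l - i).
#'
#' @param tables a [bounded_tables()] result.
#' @return character vector of exact counts, one per vertex code.
#' @export
hitting_numbers <- function(tables) {
  if (!inherits(tables, "path_count_tables"))
    stop("expected a path_count_tables object", call. = FALSE)
  cpp_hitting_bounded(tables$space$sigma, tables$space$k, tables$alive,
                      tables$ell)
}

#' Length-free path-count tables
#'
#' Counts paths of every length: F(v) = 1 + sum of F(u) over edges (u, v)
#' in topological order, D(v) symmetrically in reverse order, and
#' T(v) = F(v) * D(v), the number of paths (of any length) through v.
#' These are the scores of the L-free heuristic: cheaper than the bounded
#' tables by a factor of l, at the price of scoring long paths more.
#'
#' @param g a [residual_graph()] (must be acyclic).
#' @return a list with exact decimal character vectors `F`, `D`, `T`
#'   (one entry per vertex code; dead vertices report 0).
#' @export
unbounded_tables <- function(g) {
  stopifnot_graph(g)
  cpp_unbounded_counts(g$space$sigma, g$space$k, g$alive)
}
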