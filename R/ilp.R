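#' Exact minimum universal hitting set as an integer linear program
#'
#' `build_ilp()` encodes the minimum (k, L) universal hitting set problem
#' exactly. There is one binary selection variable x_v per k-mer and one
#' bounded path variable L_v per k-mer representing an upper bound on the
#' number of edges in the longest surviving path ending at v, with
#' 0 <= L_v <= l - 1 (l = L - k). For every edge (u, v) of the complete
#' de Bruijn graph (all sigma^(k+1) of them) the constraint
#' L_v >= 1 + L_u - l * x_v holds: selecting v (x_v = 1) relaxes the
#' constraint entirely, while an unselected v must sit strictly deeper
#' than every unselected predecessor -- which is impossible beyond depth
#' l - 1, so every l-edge path (and every cycle) must contain a selected
#' vertex. The objective minimizes the number of selected k-mers.
#'
#' The model is solver-neutral; [solve_ilp()] binds it to the installed
#' mixed-integer solver backend (HiGHS through a bundled SciPy bridge) and
#' [write_lp()] exports LP format for external solvers.
#'
#' @param space a [kmer_space()].
#' @param L window length; l = L - k must be >= 1.
#' @param max_vertices resource guard (default 4^7: the model has
#'   2 sigma^k variables and sigma^(k+1) constraints and becomes
#'   impractical quickly).
#' @return an object of class `uhs_ilp_model`.
#' @examples
#' m <- build_ilp(kmer_space(2), L = 4)
#' m$n_constraints  # sigma^(k+1) = 64
#' @export
build_ilp <- function(space, L, max_vertices = 4^7) {
  stopifnot_space(space)
  L <- check_L(space, L)
  ell <- L - space$k
  if (space$n_kmers > max_vertices)
    stop("sigma^k exceeds max_vertices; raise the cap to proceed",
         call. = FALSE)
  n <- space$n_kmers
  # edges enumerated from every vertex u to its sigma successors
  from <- rep(0:(n - 1L), each = space$sigma)
  to <- as.integer(t(kmer_successors(0:(n - 1L), space)))
  structure(list(
    space = space, L = L, ell = ell,
    n_vars = 2L * n, n_constraints = length(from),
    edge_from = from, edge_to = to
  ), class = "uhs_ilp_model")
}

#' @export
print.uhs_ilp_model <- function(x, ...) {
  cat(sprintf("UHS ILP: k = %d, L = %d; %d binary + %d integer variables, %d edge constraints\n",
              x$space$k, x$L, x$space$n_kmers, x$space$n_kmers,
              x$n_constraints))
  invisible(x)
}

milp_backend_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter with SciPy found on the PATH; ",
         "the ILP solver backend is unavailable", call. = FALSE)
  py
}

#' Solve the universal hitting set ILP
#'
#' Solves the minimum UHS problem encoded by [build_ilp()] exactly. Two
#' strategies are available:
#'
#' * `"threshold"` (the default) exploits an exact reformulation: a
#'   removed set is valid precisely when the surviving vertices admit a
#'   strictly increasing level assignment with at most l levels, and
#'   because the in/out neighbourhoods of every (k-1)-mer form a complete
#'   bipartite gadget this collapses to choosing one integer threshold
#'   p(s) in 0..l per (k-1)-mer: the removed k-mers are exactly the edges
#'   (s, t) of the order-(k-1) de Bruijn graph with p(s) >= p(t). The
#'   minimum UHS size therefore equals the minimum number of such
#'   backward edges -- a far smaller integer program over sigma^(k-1)
#'   threshold variables. A deterministic seeded annealing search supplies
#'   a strong verified incumbent, and the mixed-integer solver then
#'   attempts to find a better assignment or prove none exists within the
#'   time limit.
#' * `"direct"` hands the textbook big-M model to the solver unchanged;
#'   practical only for small instances, and kept as an independent
#'   cross-check of the reformulation.
#'
#' A warm start, when given, must itself be a valid UHS (checked with the
#' walk oracle); its size bounds the objective, and the warm start is
#' returned unchanged if nothing better is found. Every returned set is
#' re-verified with the walk oracle. `proven_optimal` is only `TRUE` when
#' the solver certified optimality (or infeasibility of any smaller
#' size); otherwise the result is the best verified set found.
#'
#' @param model a [build_ilp()] model.
#' @param warm_start optional [kmer_set()] or `uhs_result` providing a
#'   feasible solution.
#' @param time_limit solver time limit in seconds (default 300).
#' @param strategy `"threshold"` or `"direct"`.
#' @param search_effort restarts of the seeded incumbent search
#'   (threshold strategy only).
#' @return a list with `set` (a [kmer_set()]), `size`, `status`
#'   (`"optimal"` or `"feasible"`) and `proven_optimal`.
#' @examples
#' \donttest{
#' sp <- kmer_space(3, "01")
#' sol <- solve_ilp(build_ilp(sp, L = 8))
#' sol$size
#' }
#' @export
solve_ilp <- function(model, warm_start = NULL, time_limit = 300,
                      strategy = c("threshold", "direct"),
                      search_effort = 80L) {
  if (!inherits(model, "uhs_ilp_model"))
    stop("`model` must come from build_ilp()", call. = FALSE)
  strategy <- match.arg(strategy)
  space <- model$space
  n <- space$n_kmers
  warm_codes <- NULL
  if (!is.null(warm_start)) {
    if (inherits(warm_start, "uhs_result")) warm_start <- warm_start$set
    if (!inherits(warm_start, "kmer_set"))
      stop("`warm_start` must be a kmer_set or uhs_result", call. = FALSE)
    chk <- verify_uhs(warm_start, model$L, method = "walk")
    if (!chk$is_uhs)
      stop("warm start is not a valid universal hitting set for this L",
           call. = FALSE)
    warm_codes <- warm_start$codes
  }
  if (strategy == "threshold")
    return(solve_ilp_threshold(model, warm_codes, time_limit,
                               search_effort))

  # variables: z = (x_0..x_{n-1}, L_0..L_{n-1})
  m <- model$n_constraints
  rows <- rep(seq_len(m) - 1L, times = 3L)
  cols <- c(model$edge_to + n,        # +1 * L_v
            model$edge_from + n,      # -1 * L_u
            model$edge_to)            # +l * x_v
  vals <- c(rep(1, m), rep(-1, m), rep(model$ell, m))
  con_lb <- rep(1, m)
  con_ub <- rep(Inf, m)
  nvar <- 2L * n
  ncon <- m
  if (!is.null(warm_codes)) {       # incumbent bound: sum x <= |warm start|
    rows <- c(rows, rep(ncon, n))
    cols <- c(cols, 0:(n - 1L))
    vals <- c(vals, rep(1, n))
    con_lb <- c(con_lb, 0)
    con_ub <- c(con_ub, length(warm_codes))
    ncon <- ncon + 1L
  }
  prob <- list(
    nvar = nvar, ncon = ncon,
    obj = c(rep(1, n), rep(0, n)),
    a_row = rows, a_col = cols, a_val = vals,
    con_lb = con_lb, con_ub = con_ub,
    var_lb = rep(0, nvar),
    var_ub = c(rep(1, n), rep(model$ell - 1, n)),
    integrality = rep(1L, nvar),
    time_limit = time_limit
  )

  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(prob, fin, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "uhskit")
  status <- system2(milp_backend_python(), c(script, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  res <- if (status == 0 && file.exists(fout) && file.size(fout) > 0)
    jsonlite::read_json(fout, simplifyVector = TRUE) else NULL

  if (is.null(res) || is.null(res$x)) {
    if (!is.null(warm_codes))
      return(list(set = kmer_set(warm_codes, space), size = length(warm_codes),
                  status = "feasible", proven_optimal = FALSE))
    stop("ILP solver produced no solution within the time limit",
         call. = FALSE)
  }
  sel <- which(res$x[seq_len(n)] > 0.5) - 1L
  out_set <- kmer_set(as.integer(sel), space)
  chk <- verify_uhs(out_set, model$L, method = "walk")
  if (!chk$is_uhs)
    stop("internal error: solver output fails verification", call. = FALSE)
  proven <- isTRUE(res$status == 0) ||
    (!is.null(res$mip_gap) && !is.na(res$mip_gap) && res$mip_gap == 0)
  list(set = out_set, size = length(out_set),
       status = if (proven) "optimal" else "feasible",
       proven_optimal = proven)
}

# removed k-mer codes implied by a threshold assignment p over the
# (k-1)-mers: edges (s, t) of the order-(k-1) graph with p(s) >= p(t)
threshold_removed <- function(space, p) {
  sigma <- space$sigma
  m <- as.integer(sigma^(space$k - 1L))
  powkm2 <- if (space$k >= 2L) as.integer(sigma^(space$k - 2L)) else 1L
  s <- rep(0:(m - 1L), each = sigma)
  c <- rep(0:(sigma - 1L), times = m)
  t <- (s %% powkm2) * sigma + c
  code <- s * sigma + c
  code[p[s + 1L] >= p[t + 1L]]
}

# rotation-class cover cuts over the k-mer codes (each conjugacy class is a
# cycle, so at least one member must be removed); returned as a list of
# integer code vectors
class_cuts <- function(space) {
  codes <- 0:(space$n_kmers - 1L)
  r <- codes
  rep_ <- codes
  if (space$k > 1L) {
    for (i in seq_len(space$k - 1L)) {
      r <- rotate_codes(r, space)
      rep_ <- pmin(rep_, r)
    }
  }
  unname(split(codes, rep_))
}

run_milp_bridge <- function(prob) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(prob, fin, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "uhskit")
  status <- system2(milp_backend_python(), c(script, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout) || file.size(fout) == 0)
    return(NULL)
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

solve_ilp_threshold <- function(model, warm_codes, time_limit,
                                search_effort) {
  space <- model$space
  sigma <- space$sigma
  k <- space$k
  ell <- model$ell
  if (k < 2L)
    stop("the threshold strategy needs k >= 2", call. = FALSE)
  m <- as.integer(sigma^(k - 1L))
  search <- cpp_threshold_search(sigma, k, ell,
                                 as.integer(search_effort), 400000L,
                                 20260930L)
  removed <- threshold_removed(space, search$p)
  incumbent <- kmer_set(removed, space)
  if (!is.null(warm_codes) && length(warm_codes) < length(incumbent))
    incumbent <- kmer_set(warm_codes, space)
  chk <- verify_uhs(incumbent, model$L, method = "walk")
  if (!chk$is_uhs)
    stop("internal error: threshold incumbent fails verification",
         call. = FALSE)
  lower <- num_conjugacy_classes(sigma, k)
  if (length(incumbent) == lower)
    return(list(set = incumbent, size = length(incumbent),
                status = "optimal", proven_optimal = TRUE))

  # ask the solver for anything strictly better, or a proof none exists:
  # integer thresholds p_s in 0..l, binary z_e per k-mer (edge of the
  # order-(k-1) graph), (l+1) z_e - p_s + p_t >= 1, plus rotation-class
  # cover cuts and the bound sum z <= incumbent - 1
  powkm2 <- if (k >= 2L) as.integer(sigma^(k - 2L)) else 1L
  s <- rep(0:(m - 1L), each = sigma)
  cc <- rep(0:(sigma - 1L), times = m)
  tt <- (s %% powkm2) * sigma + cc
  e <- s * sigma + cc
  ncon <- length(e)
  rows <- rep(0:(ncon - 1L), times = 3L)
  cols <- c(m + e, s, tt)
  vals <- c(rep(ell + 1, ncon), rep(-1, ncon), rep(1, ncon))
  con_lb <- rep(1, ncon)
  con_ub <- rep(Inf, ncon)
  for (cut in class_cuts(space)) {
    rows <- c(rows, rep(ncon, length(cut)))
    cols <- c(cols, m + cut)
    vals <- c(vals, rep(1, length(cut)))
    con_lb <- c(con_lb, 1)
    con_ub <- c(con_ub, Inf)
    ncon <- ncon + 1L
  }
  nz <- space$n_kmers
  rows <- c(rows, rep(ncon, nz))
  cols <- c(cols, m + 0:(nz - 1L))
  vals <- c(vals, rep(1, nz))
  con_lb <- c(con_lb, lower)
  con_ub <- c(con_ub, length(incumbent) - 1)
  ncon <- ncon + 1L
  prob <- list(
    nvar = m + nz, ncon = ncon,
    obj = c(rep(0, m), rep(1, nz)),
    a_row = rows, a_col = cols, a_val = vals,
    con_lb = con_lb, con_ub = con_ub,
    var_lb = rep(0, m + nz),
    var_ub = c(rep(ell, m), rep(1, nz)),
    integrality = rep(1L, m + nz),
    time_limit = time_limit
  )
  res <- run_milp_bridge(prob)
  proven <- FALSE
  if (!is.null(res)) {
    if (!is.null(res$x)) {
      p2 <- round(res$x[seq_len(m)])
      cand <- kmer_set(threshold_removed(space, p2), space)
      if (length(cand) < length(incumbent) &&
          verify_uhs(cand, model$L, method = "walk")$is_uhs) {
        incumbent <- cand
        proven <- isTRUE(res$status == 0)
      }
    } else if (isTRUE(res$status == 2)) {
      proven <- TRUE # nothing smaller than the incumbent exists
    }
  }
  list(set = incumbent, size = length(incumbent),
       status = if (proven) "optimal" else "feasible",
       proven_optimal = proven)
}

#' Export the ILP in LP file format
#'
#' Writes the model in CPLEX LP format for use with external solvers.
#'
#' @param model a [build_ilp()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  if (!inherits(model, "uhs_ilp_model"))
    stop("`model` must come from build_ilp()", call. = FALSE)
  n <- model$space$n_kmers
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("Minimize", con)
  writeLines(paste(" obj:", paste(sprintf("x%d", 0:(n - 1L)),
                                  collapse = " + ")), con)
  writeLines("Subject To", con)
  for (i in seq_len(model$n_constraints)) {
    u <- model$edge_from[i]
    v <- model$edge_to[i]
    # L_v - L_u + l x_v >= 1 (self-loops reduce to l x_v >= 1)
    lhs <- if (u == v) sprintf("%d x%d", model$ell, v)
           else sprintf("p%d - p%d + %d x%d", v, u, model$ell, v)
    writeLines(sprintf(" e%d: %s >= 1", i - 1L, lhs), con)
  }
  writeLines("Bounds", con)
  for (v in 0:(n - 1L))
    writeLines(sprintf(" 0 <= p%d <= %d", v, model$ell - 1L), con)
  writeLines("Binary", con)
  writeLines(paste("", paste(sprintf("x%d", 0:(n - 1L)), collapse = " ")),
             con)
  writeLines("General", con)
  writeLines(paste("", paste(sprintf("p%d", 0:(n - 1L)), collapse = " ")),
             con)
  writeLines("End", con)
  invisible(path)
}
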