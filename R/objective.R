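#' Poisson log-likelihood of bin counts
#'
#' Full log-likelihood `sum_v [-delta_v + y_v log(delta_v) - log(y_v!)]` of
#' independent Poisson bin counts, including the `log(y!)` constants (they are
#' dropped inside the optimisation but belong in reported likelihoods and
#' BIC). The convention `0 * log(0) = 0` applies; a positive count under zero
#' intensity yields `-Inf`.
#'
#' @param counts Non-negative integer vector of bin counts `y_v`.
#' @param intensities Non-negative vector of Poisson intensities `delta_v`.
#' @return Log-likelihood value (possibly `-Inf`).
#' @export
poisson_loglik <- function(counts, intensities) {
  if (length(counts) != length(intensities)) abort("length mismatch")
  if (any(intensities < 0)) abort("intensities must be non-negative")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts > 0 & intensities == 0)) return(-Inf)
  pos <- counts > 0
  sum(-intensities) + sum(counts[pos] * log(intensities[pos])) -
    sum(lgamma(counts + 1))
}

#' Penalised objective in path (isoform) coordinates
#'
#' The minimisation-form objective `sum_i [delta_i - y_i log(delta_i)] +
#' lambda * sum_j theta_j` with `delta_i = l_i * sum_j U[j, i] theta_j`,
#' i.e. the negative Poisson log-likelihood without its `log(y!)` constants
#' plus an l1 penalty on isoform abundances (non-negative, so the penalty is
#' the plain sum). Used by the brute-force oracle; the solver works on the
#' equivalent [flow_objective()].
#'
#' @param design Binary `m x q` incidence matrix `U` (`U[j, i] = 1` when bin
#'   `i` belongs to candidate isoform `j`).
#' @param theta Non-negative abundance vector of length `m` (reads per base).
#' @param counts Count vector `y` of length `q`.
#' @param eff_len Effective-length vector `l` of length `q`.
#' @param lambda Non-negative penalty weight.
#' @return Objective value (smaller is better; `+Inf` when a positive count
#'   has zero intensity).
#' @export
path_objective <- function(design, theta, counts, eff_len, lambda) {
  design <- as.matrix(design)
  if (nrow(design) != length(theta) || ncol(design) != length(counts) ||
      length(counts) != length(eff_len)) {
    abort("dimension mismatch between design, theta, counts and eff_len")
  }
  if (any(theta < 0)) abort("theta must be non-negative")
  delta <- eff_len * as.vector(crossprod(design, theta))
  if (any(counts > 0 & delta == 0)) return(Inf)
  pos <- counts > 0
  sum(delta) - sum(counts[pos] * log(delta[pos])) + lambda * sum(theta)
}

#' Penalised objective in flow coordinates
#'
#' Evaluates `sum_v [l_v f_v - y_v log(l_v f_v)] + lambda * F` where `f_v` is
#' the flow entering bin vertex `v` and `F` the total flow into the sink.
#' By the flow decomposition theorem this equals [path_objective()] at any
#' path-weight vector superposing to the flow. Conservation is checked first.
#'
#' @param graph A [build_bin_graph()] result.
#' @param flow Numeric vector of arc flows, aligned with `graph$arcs` rows.
#' @param counts Per-vertex count vector (length `nrow(graph$vertices)`, in
#'   vertex-id order), or a bin-counts tibble (see [counts_vector()]).
#' @param lambda Non-negative penalty weight.
#' @param tol_cons Relative conservation tolerance.
#' @return Objective value (`+Inf` when a positive count receives zero flow).
#' @export
flow_objective <- function(graph, flow, counts, lambda, tol_cons = 1e-8) {
  y <- counts_vector(graph, counts)
  check_conservation(graph, flow, tol_cons)
  fv <- vertex_inflow(graph, flow)
  l <- graph$vertices$eff_len
  dv <- l * fv[graph$vertices$id]
  if (any(y > 0 & dv == 0)) return(Inf)
  pos <- y > 0
  sum(dv) - sum(y[pos] * log(dv[pos])) + lambda * fv[graph$t]
}

# flow entering each vertex (for s: flow leaving it) -------------------------
vertex_inflow <- function(graph, flow) {
  fv <- numeric(graph$t)
  inc <- tapply(flow, graph$arcs$to, sum)
  fv[as.integer(names(inc))] <- inc
  fv[graph$s] <- sum(flow[graph$arcs$from == graph$s])
  fv
}

check_conservation <- function(graph, flow, tol_cons = 1e-8) {
  if (length(flow) != nrow(graph$arcs)) abort("flow/arc length mismatch")
  if (any(flow < 0)) abort("flow values must be non-negative")
  total <- sum(flow[graph$arcs$to == graph$t])
  inn <- tapply(flow, graph$arcs$to, sum)
  out <- tapply(flow, graph$arcs$from, sum)
  imbalance <- numeric(graph$t)
  imbalance[as.integer(names(inn))] <- inn
  imbalance[as.integer(names(out))] <-
    imbalance[as.integer(names(out))] - out
  internal <- seq_len(nrow(graph$vertices))
  if (any(abs(imbalance[internal]) > tol_cons * max(1, total))) {
    abort("flow violates conservation at an internal vertex")
  }
  invisible(total)
}

#' Superpose path flows
#'
#' Builds the arc flow obtained by sending `weights[j]` units along each path
#' `paths[[j]]` — the superposition that links isoform abundances to flows.
#'
#' @param graph A [build_bin_graph()] result.
#' @param paths List of (s,t)-paths (integer vertex-id vectors; `s`/`t` may be
#'   omitted).
#' @param weights Non-negative numeric vector, one weight per path.
#' @return Numeric arc-flow vector aligned with `graph$arcs` rows.
#' @export
superpose_paths <- function(graph, paths, weights) {
  if (length(paths) != length(weights)) abort("one weight per path required")
  if (any(weights < 0)) abort("path weights must be non-negative")
  arc_key <- paste(graph$arcs$from, graph$arcs$to)
  flow <- numeric(nrow(graph$arcs))
  for (j in seq_along(paths)) {
    p <- as.integer(paths[[j]])
    p <- p[!(p %in% c(graph$s, graph$t))]
    full <- c(graph$s, p, graph$t)
    step <- paste(full[-length(full)], full[-1])
    idx <- match(step, arc_key)
    if (anyNA(idx)) abort("path uses an arc absent from the graph")
    flow[idx] <- flow[idx] + weights[j]
  }
  flow
}

#' Align a bin-counts table with graph vertices
#'
#' Turns a bin-counts tibble (columns `key` — comma-joined 1-based exon
#' indices — and `count`) into a per-vertex count vector in vertex-id order.
#' Counts on bins absent from the graph (pruned or never enumerated) are
#' dropped with a warning and attached as attribute `dropped`.
#'
#' @param graph A [build_bin_graph()] result.
#' @param counts Bin-counts tibble, or an already-aligned numeric vector of
#'   length `nrow(graph$vertices)` (returned unchanged).
#' @return Numeric vector of per-vertex counts.
#' @export
counts_vector <- function(graph, counts) {
  if (is.numeric(counts)) {
    if (length(counts) != nrow(graph$vertices)) {
      abort("numeric counts must have one entry per graph vertex")
    }
    return(counts)
  }
  if (!all(c("key", "count") %in% names(counts))) {
    abort("`counts` must have columns `key` and `count`")
  }
  y <- numeric(nrow(graph$vertices))
  idx <- match(counts$key, graph$vertices$key)
  miss <- is.na(idx)
  if (any(miss & counts$count > 0)) {
    warn(sprintf(
      "%d reads on %d bins outside the graph were dropped (see attr 'dropped')",
      sum(counts$count[miss]), sum(miss & counts$count > 0)
    ))
  }
  agg <- tapply(counts$count[!miss], idx[!miss], sum)
  y[as.integer(names(agg))] <- agg
  attr(y, "dropped") <- counts[miss & counts$count > 0, , drop = FALSE]
  y
}
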