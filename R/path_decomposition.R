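#' Maximum-bottleneck source-to-sink path of a flow
#'
#' Finds the (s,t)-path carrying the maximum amount of flow — the path whose
#' minimum arc flow (bottleneck) is largest — by dynamic programming over the
#' topological order, the same recursion as a DAG shortest path. Ties are
#' broken towards fewer vertices, then the lexicographically smallest vertex
#' sequence, so extraction is deterministic.
#'
#' @param graph A [build_bin_graph()] result.
#' @param flow Arc-flow vector aligned with `graph$arcs` (must conserve and
#'   carry positive total flow).
#' @return List with `path` (vertex ids from `s` to `t`) and `bottleneck`.
#' @export
max_flow_path <- function(graph, flow) {
  check_conservation(graph, flow)
  if (sum(flow[graph$arcs$to == graph$t]) <= 0) {
    abort("flow is zero; nothing to extract")
  }
  pos <- integer(graph$t)
  pos[graph$topo] <- seq_along(graph$topo)
  use <- flow > 0
  arcs <- graph$arcs[use, , drop = FALSE]
  fval <- flow[use]
  preds <- split(seq_len(nrow(arcs)), arcs$to)

  # state per vertex: best bottleneck, path length, path (small graphs)
  best_b <- rep(-Inf, graph$t)
  best_path <- vector("list", graph$t)
  best_b[graph$s] <- Inf
  best_path[[graph$s]] <- graph$s
  better <- function(b1, p1, b2, p2) {
    # is candidate 1 preferred over candidate 2?
    if (b1 != b2) return(b1 > b2)
    if (length(p1) != length(p2)) return(length(p1) < length(p2))
    cmp <- pos[p1] - pos[p2]
    nz <- which(cmp != 0)
    if (length(nz) == 0) return(FALSE)
    cmp[nz[1]] < 0
  }
  for (v in graph$topo[-1]) {
    for (i in preds[[as.character(v)]]) {
      u <- arcs$from[i]
      if (is.null(best_path[[u]])) next
      cand_b <- min(best_b[u], fval[i])
      cand_p <- c(best_path[[u]], v)
      if (is.null(best_path[[v]]) ||
          better(cand_b, cand_p, best_b[v], best_path[[v]])) {
        best_b[v] <- cand_b
        best_path[[v]] <- cand_p
      }
    }
  }
  if (is.null(best_path[[graph$t]])) abort("no positive-flow (s,t)-path")
  list(path = best_path[[graph$t]], bottleneck = best_b[graph$t])
}

#' Decompose a flow into isoforms with abundances
#'
#' Implements the greedy flow decomposition used to decode transcripts from
#' the optimal flow: repeatedly extract the maximum-bottleneck (s,t)-path,
#' record the decoded isoform with abundance equal to the bottleneck value,
#' subtract that path flow, and stop once the remaining flow into the sink
#' falls below `min_frac` of the original. By the flow decomposition theorem
#' at most one path per arc is extracted, and the superposition of extracted
#' path flows reproduces the input flow up to the stopping residual. The
#' decomposition of an optimal flow is one (not necessarily unique) solution
#' of the penalised estimator.
#'
#' @param graph A [build_bin_graph()] result.
#' @param flow Arc-flow vector aligned with `graph$arcs`.
#' @param min_frac Stop when remaining total flow drops below this fraction
#'   of the initial total flow.
#' @return Tibble with list-columns `exons` and `path`, plus `key` and
#'   `abundance`, one row per extracted isoform in extraction order
#'   (abundances non-increasing). Attribute `residual` carries the remaining
#'   arc flow. Zero input flow decomposes into zero isoforms.
#' @examples
#' g <- gene_model(data.frame(start = c(0, 300), end = c(200, 500)))
#' bg <- build_bin_graph(g, cbind(1, 2), read_length = 100)
#' p <- enumerate_paths(bg)
#' fl <- superpose_paths(bg, p[1], 2.5)
#' decompose_flow(bg, fl)
#' @export
decompose_flow <- function(graph, flow, min_frac = 1e-8) {
  check_conservation(graph, flow)
  total0 <- sum(flow[graph$arcs$to == graph$t])
  arc_key <- paste(graph$arcs$from, graph$arcs$to)
  out_path <- list()
  out_ab <- numeric(0)
  remaining <- flow
  max_extract <- nrow(graph$arcs)
  while (total0 > 0 &&
         sum(remaining[graph$arcs$to == graph$t]) >= min_frac * total0 &&
         length(out_path) < max_extract) {
    ex <- max_flow_path(graph, remaining)
    step <- paste(ex$path[-length(ex$path)], ex$path[-1])
    idx <- match(step, arc_key)
    remaining[idx] <- pmax(0, remaining[idx] - ex$bottleneck)
    out_path[[length(out_path) + 1L]] <- ex$path
    out_ab <- c(out_ab, ex$bottleneck)
  }
  exons <- lapply(out_path, function(p) path_to_isoform(graph, p))
  res <- tibble(
    exons = exons,
    path = out_path,
    key = vapply(exons, bin_key, character(1)),
    abundance = out_ab
  )
  attr(res, "residual") <- remaining
  res
}
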