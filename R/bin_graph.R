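#' Build the bin graph of a gene
#'
#' Constructs the DAG whose vertices are all read bins with positive effective
#' length that are consistent with the supplied junctions, plus a source `s`
#' and sink `t`. An arc connects bin `u` to bin `v` when two reads starting at
#' successive positions in some candidate isoform fall in `u` and `v`: sliding
#' one base either drops the bin's first exon, appends a junction-consistent
#' next exon, or does both at once when geometry forces it. `s` connects to
#' every starting bin and every stopping bin connects to `t`; no restriction
#' is placed on transcription start or polyadenylation sites. Source-to-sink
#' paths are then in bijection with candidate isoforms ([path_to_isoform()]).
#'
#' Only bins whose internal length is at most `read_length - 2` can have
#' positive effective length, so the vertex count is polynomial in the number
#' of exons for a fixed read length. Vertices not on any (s,t)-path are
#' pruned; counts observed on pruned bins are reported by the solver as
#' diagnostics rather than silently dropped.
#'
#' @param gene A [gene_model()].
#' @param junctions Two-column matrix or data frame of exon-index pairs
#'   `(from, to)` with `from < to` (1-based indices into `gene`), e.g. as
#'   harvested from split reads by [sam_to_bin_counts()]. `NULL` or an empty
#'   set yields a graph of isolated single-exon paths.
#' @param read_length Read length in bases.
#' @return A `bin_graph` object: list with `vertices` (tibble: `id`, `key`,
#'   list-column `exons`, `eff_len`, `starting`, `stopping`), `arcs` (tibble
#'   `from`, `to` of vertex ids), `s`, `t` (ids), `topo` (topological order of
#'   all ids), `gene`, `read_length`, and `pruned` (keys of bins dropped
#'   because they lie on no (s,t)-path).
#' @examples
#' g <- gene_model(data.frame(start = c(0, 300, 700), end = c(200, 500, 900)))
#' bg <- build_bin_graph(g, junctions = cbind(c(1, 2), c(2, 3)), read_length = 150)
#' bg
#' @export
build_bin_graph <- function(gene, junctions, read_length) {
  L <- read_length
  if (L < 1) abort("`read_length` must be >= 1")
  jn <- normalize_junctions(junctions, gene$n)
  lens_all <- exon_lengths(gene)
  succ_exon <- lapply(seq_len(gene$n), function(e) sort(jn$to[jn$from == e]))

  bins <- enumerate_bins(lens_all, succ_exon, L)
  if (length(bins) == 0) {
    abort("no bin has positive effective length; reads longer than every isoform?")
  }
  keys <- vapply(bins, bin_key, character(1))
  eff <- vapply(bins, function(b) effective_length(lens_all[b], L), numeric(1))

  starting <- starting_bins(gene, bins, L)
  stopping <- stopping_bins(gene, bins, L)

  # arcs between bins: one-position read slide --------------------------------
  key_id <- setNames(seq_along(bins), keys)
  arc_from <- integer(0)
  arc_to <- integer(0)
  for (i in seq_along(bins)) {
    for (tk in bin_slide_targets(bins[[i]], lens_all, succ_exon, L)) {
      j <- key_id[[tk]]
      if (!is.null(j)) {
        arc_from <- c(arc_from, i)
        arc_to <- c(arc_to, j)
      }
    }
  }

  q <- length(bins)
  s_id <- q + 1L
  t_id <- q + 2L
  arc_from <- c(arc_from, rep(s_id, sum(starting)), which(stopping))
  arc_to <- c(arc_to, which(starting), rep(t_id, sum(stopping)))

  # prune vertices not on any (s,t)-path --------------------------------------
  fwd <- reachable_from(s_id, arc_from, arc_to, t_id + 0L)
  bwd <- reachable_from(t_id, arc_to, arc_from, t_id + 0L)
  keep <- fwd & bwd
  keep[c(s_id, t_id)] <- TRUE
  pruned_keys <- keys[!keep[seq_len(q)]]

  old_ids <- which(keep[seq_len(q)])
  new_id <- integer(t_id)
  new_id[old_ids] <- seq_along(old_ids)
  new_id[s_id] <- length(old_ids) + 1L
  new_id[t_id] <- length(old_ids) + 2L
  keep_arc <- keep[arc_from] & keep[arc_to]

  vertices <- tibble(
    id = seq_along(old_ids),
    key = keys[old_ids],
    exons = bins[old_ids],
    eff_len = eff[old_ids],
    starting = starting[old_ids],
    stopping = stopping[old_ids]
  )
  arcs <- tibble(
    from = new_id[arc_from[keep_arc]],
    to = new_id[arc_to[keep_arc]]
  )
  arcs <- dplyr::distinct(arcs)

  graph <- structure(
    list(
      vertices = vertices,
      arcs = arcs,
      s = length(old_ids) + 1L,
      t = length(old_ids) + 2L,
      topo = integer(0),
      gene = gene,
      read_length = L,
      pruned = pruned_keys
    ),
    class = "bin_graph"
  )
  graph$topo <- topological_order(graph)
  graph
}

#' @export
print.bin_graph <- function(x, ...) {
  cat(sprintf(
    "<bin_graph> %s: %d bins, %d arcs (L = %d)%s\n",
    x$gene$gene_id, nrow(x$vertices), nrow(x$arcs), x$read_length,
    if (length(x$pruned)) sprintf(", %d bins pruned", length(x$pruned)) else ""
  ))
  print(select(x$vertices, -"exons"), ...)
  invisible(x)
}

normalize_junctions <- function(junctions, n) {
  if (is.null(junctions) || (is.data.frame(junctions) && nrow(junctions) == 0) ||
      (is.matrix(junctions) && nrow(junctions) == 0) || length(junctions) == 0) {
    return(list(from = integer(0), to = integer(0)))
  }
  jm <- as.matrix(as.data.frame(junctions))
  if (ncol(jm) < 2) abort("`junctions` must have two columns (from, to)")
  from <- as.integer(jm[, 1])
  to <- as.integer(jm[, 2])
  if (any(from >= to)) {
    abort("junctions must be forward exon pairs (from < to); cyclic input")
  }
  if (any(from < 1 | to > n)) abort("junction exon indices out of range")
  dup <- duplicated(paste(from, to))
  list(from = from[!dup], to = to[!dup])
}

# all junction-consistent exon chains with l_int <= L - 2 and eff_len > 0 ----
enumerate_bins <- function(lens_all, succ_exon, L) {
  out <- list()
  grow <- function(chain, l_int) {
    if (effective_length(lens_all[chain], L) > 0) {
      out[[length(out) + 1L]] <<- chain
    }
    last <- chain[length(chain)]
    new_int <- if (length(chain) >= 2) l_int + lens_all[last] else 0
    if (new_int <= L - 2) {
      for (f in succ_exon[[last]]) grow(c(chain, f), new_int)
    }
  }
  for (e in seq_along(lens_all)) grow(e, 0)
  out
}

# bins reachable from a read one position later in some isoform --------------
bin_slide_targets <- function(b, lens_all, succ_exon, L) {
  lens <- lens_all[b]
  cumB <- sum(lens)
  s_star <- min(lens[1], cumB - L + 1)
  if (s_star < 1) return(character(0))
  need_end <- s_star + L # = (s_star + 1) + L - 1
  targets <- character(0)
  explore <- function(ext, cum_total) {
    if (cum_total >= need_end) {
      full <- c(b, ext)
      brk <- c(0, cumsum(lens_all[full]))
      i1 <- findInterval(s_star + 1 - 0.5, brk)
      i2 <- findInterval(need_end - 0.5, brk)
      targets <<- c(targets, bin_key(full[i1:i2]))
      return()
    }
    last <- if (length(ext)) ext[length(ext)] else b[length(b)]
    for (f in succ_exon[[last]]) explore(c(ext, f), cum_total + lens_all[f])
  }
  explore(integer(0), cumB)
  unique(targets)
}

#' Starting and stopping bins
#'
#' A bin is *starting* when a read of length `read_length` placed at the first
#' base of an isoform beginning with the bin's first exon overlaps exactly the
#' bin's exons; *stopping* is the mirror condition at the last base of an
#' isoform ending with the bin's last exon. In the graph, the source connects
#' to all starting bins and all stopping bins connect to the sink; every exon
#' may start or end an isoform.
#'
#' @param gene A [gene_model()].
#' @param bins List of integer vectors of exon indices.
#' @param read_length Read length in bases.
#' @return Logical vector, one element per bin.
#' @export
starting_bins <- function(gene, bins, read_length) {
  lens_all <- exon_lengths(gene)
  vapply(bins, function(b) {
    lens <- lens_all[b]
    if (length(b) == 1) {
      read_length <= lens[1]
    } else {
      tot <- sum(lens)
      tot - lens[length(lens)] < read_length && read_length <= tot
    }
  }, logical(1))
}

#' @rdname starting_bins
#' @export
stopping_bins <- function(gene, bins, read_length) {
  lens_all <- exon_lengths(gene)
  vapply(bins, function(b) {
    lens <- lens_all[b]
    if (length(b) == 1) {
      read_length <= lens[1]
    } else {
      tot <- sum(lens)
      tot - lens[1] < read_length && read_length <= tot
    }
  }, logical(1))
}

# order ids so every arc goes forward: bins by (last exon, first exon, key) --
topological_order <- function(graph) {
  v <- graph$vertices
  last_e <- vapply(v$exons, function(b) b[length(b)], numeric(1))
  first_e <- vapply(v$exons, function(b) b[1], numeric(1))
  ord <- v$id[order(last_e, first_e, v$key)]
  topo <- c(graph$s, ord, graph$t)
  pos <- integer(graph$t)
  pos[topo] <- seq_along(topo)
  bad <- pos[graph$arcs$from] >= pos[graph$arcs$to]
  if (any(bad)) abort("internal error: bin graph is not acyclic under slide order")
  topo
}

#' Decode a source-to-sink path into an isoform
#'
#' Inverts the bijection between (s,t)-paths of a bin graph and candidate
#' isoforms: the isoform is the union of exon indices over the path's bins.
#'
#' @param graph A [build_bin_graph()] result.
#' @param path Integer vector of vertex ids forming an (s,t)-path (the `s`
#'   and `t` endpoints may be included or omitted).
#' @return Strictly increasing integer vector of exon indices.
#' @export
path_to_isoform <- function(graph, path) {
  path <- as.integer(path)
  path <- path[!(path %in% c(graph$s, graph$t))]
  if (length(path) == 0) abort("path contains no bin vertices")
  if (any(path < 1 | path > nrow(graph$vertices))) abort("path vertex not in graph")
  full <- c(graph$s, path, graph$t)
  arc_key <- paste(graph$arcs$from, graph$arcs$to)
  step <- paste(full[-length(full)], full[-1])
  if (!all(step %in% arc_key)) abort("not a valid (s,t)-path in this graph")
  sort(unique(unlist(graph$vertices$exons[path])))
}

#' Enumerate all source-to-sink paths of a bin graph
#'
#' Exhaustive depth-first enumeration in lexicographic topological order.
#' Intended for small graphs: it powers brute-force comparisons against the
#' flow solver, whose whole point is to avoid this enumeration.
#'
#' @param graph A [build_bin_graph()] result.
#' @param max_paths Truncate after this many paths; the result then carries
#'   attribute `overflow = TRUE`.
#' @return List of integer vectors (vertex ids including `s` and `t`).
#' @export
enumerate_paths <- function(graph, max_paths = Inf) {
  pos <- integer(graph$t)
  pos[graph$topo] <- seq_along(graph$topo)
  succ <- split(graph$arcs$to, graph$arcs$from)
  succ <- lapply(succ, function(v) v[order(pos[v])])
  paths <- list()
  overflow <- FALSE
  dfs <- function(path) {
    if (overflow) return()
    v <- path[length(path)]
    if (v == graph$t) {
      if (length(paths) >= max_paths) {
        overflow <<- TRUE
      } else {
        paths[[length(paths) + 1L]] <<- path
      }
      return()
    }
    for (w in succ[[as.character(v)]]) dfs(c(path, w))
  }
  dfs(graph$s)
  attr(paths, "overflow") <- overflow
  paths
}

reachable_from <- function(start, arc_from, arc_to, n_vertices) {
  seen <- logical(n_vertices)
  seen[start] <- TRUE
  frontier <- start
  adj <- split(arc_to, arc_from)
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & !seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}
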