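#' Construct a gene model from ordered exon intervals
#'
#' A gene model is the universe over which read bins are defined: the ordered,
#' non-overlapping exons of one gene on one strand. Coordinates are 0-based,
#' half-open throughout the package; conversion from 1-based annotation
#' formats happens in [read_annotation()]. Exons carrying alternative
#' 5'-donor or 3'-acceptor sites are expected to be pre-split into separate
#' abutting exons (done automatically when loading annotation).
#'
#' @param exons Data frame with columns `start` and `end` (0-based half-open),
#'   one row per exon, sorted by `start`, non-overlapping. Abutting exons
#'   (`end[i] == start[i+1]`) are allowed: they arise from alternative
#'   splice-site splitting.
#' @param gene_id Identifier for the gene.
#' @param seqname Reference sequence (chromosome) name.
#' @param strand `"+"`, `"-"` or `"*"`; used only for annotation round-trips.
#' @return An object of class `gene_model`: list with `exons` (a tibble with
#'   `index`, `start`, `end`, `length`), `n` (number of exons), `gene_id`,
#'   `seqname`, `strand`.
#' @examples
#' g <- gene_model(data.frame(start = c(0, 300, 700), end = c(200, 500, 900)))
#' g
#' @export
gene_model <- function(exons, gene_id = "gene", seqname = "ref", strand = "+") {
  exons <- as_tibble(exons)
  if (!all(c("start", "end") %in% names(exons)) || nrow(exons) == 0) {
    abort("`exons` must be a non-empty data frame with columns `start`, `end`")
  }
  exons <- arrange(exons, .data$start)
  if (any(exons$end <= exons$start)) {
    abort("every exon must satisfy end > start (0-based half-open)")
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping; split alternative boundaries first")
  }
  structure(
    list(
      exons = tibble(
        index = seq_len(nrow(exons)),
        start = as.numeric(exons$start),
        end = as.numeric(exons$end),
        length = as.numeric(exons$end - exons$start)
      ),
      n = nrow(exons),
      gene_id = gene_id,
      seqname = seqname,
      strand = strand
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s (%s:%s) %d exon%s, %d bp exonic\n",
    x$gene_id, x$seqname, x$strand, x$n, if (x$n == 1) "" else "s",
    sum(x$exons$length)
  ))
  print(x$exons, ...)
  invisible(x)
}

exon_lengths <- function(gene) gene$exons$length

#' Effective length of a bin
#'
#' The effective length of a bin is the number of positions at which a read
#' of length `read_length` can start so that it overlaps exactly the exons of
#' the bin, in any isoform containing those exons consecutively. It does not
#' depend on the containing isoform. For a single exon of length `l_e` it is
#' `l_e - L + 1`; for a multi-exon bin with leftmost/rightmost exon lengths
#' `l_left`/`l_right` and total internal length `l_int` it is
#' `min(l_left, L - l_int - 1) + min(l_right, L - l_int - 1) - L + l_int + 1`.
#' Negative values are clamped to zero (such bins are dropped from the graph).
#'
#' @param bin_exon_lengths Numeric vector of the bin's exon lengths, in order.
#' @param read_length Read length `L` in bases (>= 1).
#' @return Non-negative integer count of admissible read-start positions.
#' @examples
#' effective_length(200, 100)        # single exon: 101
#' effective_length(c(100, 150), 100) # junction bin: 99
#' @export
effective_length <- function(bin_exon_lengths, read_length) {
  if (length(bin_exon_lengths) == 0) abort("bin must contain at least one exon")
  if (read_length < 1) abort("`read_length` must be >= 1")
  if (any(bin_exon_lengths < 1)) abort("exon lengths must be >= 1")
  k <- length(bin_exon_lengths)
  if (k == 1) {
    val <- bin_exon_lengths - read_length + 1
  } else {
    l_left <- bin_exon_lengths[1]
    l_right <- bin_exon_lengths[k]
    l_int <- if (k > 2) sum(bin_exon_lengths[-c(1, k)]) else 0
    val <- min(l_left, read_length - l_int - 1) +
      min(l_right, read_length - l_int - 1) -
      read_length + l_int + 1
  }
  max(0, val)
}

# canonical string key for a bin: 1-based exon indices joined by "," ----
bin_key <- function(exon_idx) paste(exon_idx, collapse = ",")

parse_bin_key <- function(key) lapply(strsplit(key, ",", fixed = TRUE), as.integer)

#' Bin sequence of an isoform
#'
#' Slides a read of length `read_length` along the concatenated exons of an
#' isoform and records the distinct ordered sets of exons (bins) the read
#' successively overlaps, in order of first occurrence. Every returned bin has
#' positive effective length, and their effective lengths partition the
#' `M - L + 1` admissible read starts of an isoform of total length `M`.
#'
#' @param gene A [gene_model()].
#' @param isoform_exons Strictly increasing integer vector of exon indices.
#' @param read_length Read length in bases.
#' @return Tibble with list-column `exons`, string `key`, and
#'   `effective_length`, one row per bin in slide order. If the isoform is
#'   shorter than the read, an empty tibble is returned with a warning and
#'   attribute `too_short = TRUE`.
#' @examples
#' g <- gene_model(data.frame(start = c(0, 300, 700), end = c(200, 500, 900)))
#' isoform_bins(g, c(1, 3), read_length = 150)
#' @export
isoform_bins <- function(gene, isoform_exons, read_length) {
  isoform_exons <- as.integer(isoform_exons)
  if (length(isoform_exons) == 0) abort("isoform must contain at least one exon")
  if (is.unsorted(isoform_exons, strictly = TRUE)) {
    abort("isoform exon indices must be strictly increasing")
  }
  if (any(isoform_exons < 1 | isoform_exons > gene$n)) {
    abort("isoform exon indices out of range for this gene")
  }
  lens <- exon_lengths(gene)[isoform_exons]
  cum <- cumsum(lens)
  M <- cum[length(cum)]
  if (M < read_length) {
    warn(sprintf(
      "isoform (%s) of length %d is shorter than the read length %d; no bins",
      bin_key(isoform_exons), M, read_length
    ))
    out <- tibble(exons = list(), key = character(), effective_length = numeric())
    attr(out, "too_short") <- TRUE
    return(out)
  }
  starts <- seq_len(M - read_length + 1)
  brk <- c(0, cum)
  i1 <- findInterval(starts - 0.5, brk)
  i2 <- findInterval(starts + read_length - 1 - 0.5, brk)
  run_id <- cumsum(c(1L, (diff(i1) != 0) | (diff(i2) != 0)))
  firsts <- !duplicated(run_id)
  bins <- purrr::map2(i1[firsts], i2[firsts], function(a, b) isoform_exons[a:b])
  tibble(
    exons = bins,
    key = vapply(bins, bin_key, character(1)),
    effective_length = vapply(
      bins,
      function(b) effective_length(exon_lengths(gene)[b], read_length),
      numeric(1)
    )
  )
}
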