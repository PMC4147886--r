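# normalise an isoform set argument to tibble(exons = list, abundance) ------
normalize_isoforms <- function(isoforms) {
  if (is.data.frame(isoforms)) {
    if (!all(c("exons", "abundance") %in% names(isoforms))) {
      abort("isoform table needs columns `exons` (list) and `abundance`")
    }
    return(tibble(
      exons = lapply(isoforms$exons, as.integer),
      abundance = as.numeric(isoforms$abundance)
    ))
  }
  tibble(
    exons = lapply(isoforms, function(x) as.integer(x$exons)),
    abundance = vapply(isoforms, function(x) as.numeric(x$abundance), numeric(1))
  )
}

#' Simulate Poisson bin counts from known isoforms
#'
#' Draws one count per bin of the union of the isoforms' bin sequences, from
#' `Poisson(delta_v)` with `delta_v = l_v * sum_j U[j, v] theta_j` — exactly
#' the generative model the estimator fits. Bins whose draw is zero are kept
#' (they are observed bins with count zero).
#'
#' @param gene A [gene_model()].
#' @param isoforms Isoform set: tibble with list-column `exons` and
#'   `abundance`, or a list of `list(exons=, abundance=)`.
#' @param read_length Read length in bases.
#' @param seed Integer seed (deterministic output for a given seed).
#' @return Bin-counts tibble: `gene_id`, list-column `exons`, `key`, `count`;
#'   attribute `delta` carries the true intensities.
#' @export
simulate_counts <- function(gene, isoforms, read_length, seed) {
  iso <- normalize_isoforms(isoforms)
  if (any(iso$abundance < 0)) abort("abundances must be non-negative")
  delta <- list()
  info <- list()
  for (j in seq_len(nrow(iso))) {
    b <- isoform_bins(gene, iso$exons[[j]], read_length)
    for (i in seq_len(nrow(b))) {
      k <- b$key[i]
      delta[[k]] <- (delta[[k]] %||% 0) + b$effective_length[i] * iso$abundance[j]
      info[[k]] <- b$exons[[i]]
    }
  }
  keys <- names(delta)
  dl <- unlist(delta, use.names = FALSE) %||% numeric(0)
  y <- withr::with_seed(seed, rpois(length(dl), dl))
  out <- tibble(
    gene_id = gene$gene_id,
    exons = unname(info[keys]) %||% list(),
    key = keys %||% character(0),
    count = y
  )
  attr(out, "delta") <- setNames(dl, keys)
  out
}

#' Simulate error-free single-end reads from known isoforms
#'
#' Each read picks an isoform with probability proportional to
#' `theta_j * (M_j - L + 1)` (abundance times admissible start positions) and
#' a start position uniform over those positions, matching the Poisson count
#' model conditionally on the total. Reads are perfectly mapped and
#' error-free: the simulator's job is to satisfy the model's own assumptions
#' for recovery tests, not to emulate sequencing biases.
#'
#' @inheritParams simulate_counts
#' @param n_reads Number of reads to draw.
#' @return Tibble with one row per read: `qname`, `gene_id`, `isoform`
#'   (index into the isoform set), `tstart` (1-based transcript coordinate),
#'   `pos` (1-based genomic POS), `cigar` (M/N over introns). Write with
#'   [write_sam()].
#' @export
simulate_reads <- function(gene, isoforms, read_length, n_reads, seed) {
  iso <- normalize_isoforms(isoforms)
  lens_all <- exon_lengths(gene)
  M <- vapply(iso$exons, function(e) sum(lens_all[e]), numeric(1))
  if (any(M < read_length)) abort("every isoform must be at least one read long")
  w <- iso$abundance * (M - read_length + 1)
  if (n_reads > 0 && sum(w) <= 0) abort("all isoform sampling weights are zero")
  draws <- withr::with_seed(seed, {
    j <- if (n_reads > 0) {
      sample.int(nrow(iso), n_reads, replace = TRUE, prob = w)
    } else {
      integer(0)
    }
    s <- if (n_reads > 0) {
      1L + floor(runif(n_reads) * (M[j] - read_length + 1))
    } else {
      numeric(0)
    }
    list(j = j, s = as.integer(pmin(s, M[j] - read_length + 1)))
  })
  proj <- purrr::map2(draws$j, draws$s, function(j, s) {
    transcript_to_genomic(gene, iso$exons[[j]], s, read_length)
  })
  tibble(
    qname = sprintf("%s_r%06d", gene$gene_id, seq_len(n_reads)),
    gene_id = gene$gene_id,
    isoform = draws$j,
    tstart = draws$s,
    pos = vapply(proj, function(p) p$pos, numeric(1)) %||% numeric(0),
    cigar = vapply(proj, function(p) p$cigar, character(1)) %||% character(0)
  )
}

# project transcript interval [s, s+L-1] onto the genome ---------------------
# returns 1-based POS and an M/N cigar; abutting exons merge into one M block
transcript_to_genomic <- function(gene, iso_exons, s, L) {
  ex <- gene$exons[iso_exons, ]
  lens <- ex$length
  cum <- cumsum(lens)
  brk <- c(0, cum)
  i1 <- findInterval(s - 0.5, brk)
  i2 <- findInterval(s + L - 1 - 0.5, brk)
  starts <- numeric(0)
  ends <- numeric(0)
  for (i in i1:i2) {
    off_start <- if (i == i1) s - brk[i] - 1 else 0 # 0-based offset in exon
    off_end <- if (i == i2) s + L - 1 - brk[i] else lens[i] # 1-based end offset
    starts <- c(starts, ex$start[i] + off_start)
    ends <- c(ends, ex$start[i] + off_end)
  }
  # merge genomically abutting blocks (split exons)
  keep <- c(TRUE, starts[-1] != ends[-length(ends)])
  grp <- cumsum(keep)
  bs <- tapply(starts, grp, min)
  be <- tapply(ends, grp, max)
  m <- be - bs
  gaps <- if (length(bs) > 1) bs[-1] - be[-length(be)] else numeric(0)
  cigar <- paste0(m[1], "M")
  if (length(gaps)) {
    cigar <- paste0(cigar, paste0(gaps, "N", m[-1], "M", collapse = ""))
  }
  list(pos = bs[1] + 1, cigar = cigar)
}

#' Write simulated reads as a SAM file
#'
#' Minimal valid single-end SAM: `@HD`/`@SQ` header (one reference per
#' seqname, length covering every gene plus margin) and one mapped record per
#' read with an M/N cigar, placeholder sequence and `*` quality.
#'
#' @param reads Tibble from [simulate_reads()] (rows from several genes may
#'   be concatenated with `dplyr::bind_rows()`).
#' @param genes A [gene_model()] or list of them (for header lengths).
#' @param file Output path.
#' @param read_length Read length (for the placeholder SEQ field).
#' @return `file`, invisibly.
#' @export
write_sam <- function(reads, genes, file, read_length) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  seqs <- vapply(genes, function(g) g$seqname, character(1))
  maxend <- vapply(genes, function(g) max(g$exons$end), numeric(1))
  sq <- tapply(maxend, seqs, max) + 1000
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq))
  )
  seqname_of <- setNames(seqs, vapply(genes, function(g) g$gene_id, character(1)))
  body <- if (nrow(reads)) {
    sprintf(
      "%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
      reads$qname, seqname_of[reads$gene_id], as.integer(reads$pos),
      reads$cigar, strrep("A", read_length)
    )
  } else {
    character(0)
  }
  writeLines(c(header, body), file)
  invisible(file)
}
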