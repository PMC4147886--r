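#' Read a transcript annotation (GTF or BED12)
#'
#' Loads transcript models, groups them into genes and builds one
#' [gene_model()] per gene. Exons carrying alternative 5'-donor/3'-acceptor
#' sites are split at every boundary observed in the gene (via range
#' disjoining), so the gene model's exons are disjoint (possibly abutting)
#' segments and every annotated transcript maps to a chain of segment
#' indices. GTF coordinates (1-based inclusive) are converted to the
#' package-internal 0-based half-open convention here; BED12 is already
#' 0-based half-open.
#'
#' @param file Path to a `.gtf` (exon features with `gene_id` and
#'   `transcript_id` attributes) or `.bed` (BED12, one transcript per line,
#'   genes formed from overlapping transcripts).
#' @return An `annotation` object: list with `genes` (named list of
#'   [gene_model()]) and `transcripts` (tibble: `gene_id`, `transcript_id`,
#'   list-column `exon_parts` of segment indices).
#' @export
read_annotation <- function(file) {
  if (!file.exists(file)) abort(sprintf("annotation file not found: %s", file))
  is_bed <- grepl("\\.bed$", file, ignore.case = TRUE)
  if (is_bed) {
    tx <- rtracklayer::import(file, format = "bed")
    bl <- rtracklayer::blocks(tx)
    ex <- unlist(bl)
    tx_ids <- rep(
      tx$name %||% paste0("tx", seq_along(tx)),
      S4Vectors::elementNROWS(bl)
    )
    ex_tbl <- tibble(
      seqname = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex) - 1,
      end = GenomicRanges::end(ex),
      strand = as.character(GenomicRanges::strand(ex)),
      transcript_id = tx_ids
    )
    # genes = connected components of overlapping transcripts
    red <- GenomicRanges::reduce(tx, ignore.strand = FALSE)
    hit <- GenomicRanges::findOverlaps(tx, red)
    gene_of_tx <- setNames(
      paste0("gene", S4Vectors::subjectHits(hit)),
      (tx$name %||% paste0("tx", seq_along(tx)))[S4Vectors::queryHits(hit)]
    )
    ex_tbl$gene_id <- gene_of_tx[ex_tbl$transcript_id]
  } else {
    gr <- rtracklayer::import(file, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) abort("no exon features in GTF")
    ex_tbl <- tibble(
      seqname = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      transcript_id = gr$transcript_id,
      gene_id = gr$gene_id
    )
  }
  build_annotation(ex_tbl)
}

build_annotation <- function(ex_tbl) {
  genes <- list()
  tx_rows <- list()
  for (gid in unique(ex_tbl$gene_id)) {
    sub <- ex_tbl[ex_tbl$gene_id == gid, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1, end = sub$end)
    parts <- IRanges::disjoin(ir)
    parts <- parts[order(IRanges::start(parts))]
    gm <- gene_model(
      data.frame(
        start = IRanges::start(parts) - 1,
        end = IRanges::end(parts)
      ),
      gene_id = gid, seqname = sub$seqname[1], strand = sub$strand[1]
    )
    genes[[gid]] <- gm
    for (tid in unique(sub$transcript_id)) {
      txex <- sub[sub$transcript_id == tid, , drop = FALSE]
      tir <- IRanges::IRanges(start = txex$start + 1, end = txex$end)
      hit <- IRanges::findOverlaps(parts, tir)
      chain <- sort(unique(S4Vectors::queryHits(hit)))
      tx_rows[[length(tx_rows) + 1L]] <- tibble(
        gene_id = gid, transcript_id = tid, exon_parts = list(as.integer(chain))
      )
    }
  }
  structure(
    list(genes = genes, transcripts = bind_rows(tx_rows)),
    class = "annotation"
  )
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf(
    "<annotation> %d gene%s, %d transcript%s\n",
    length(x$genes), if (length(x$genes) == 1) "" else "s",
    nrow(x$transcripts), if (nrow(x$transcripts) == 1) "" else "s"
  ))
  invisible(x)
}

#' Transcript table with genomic coordinates
#'
#' Converts isoforms expressed as chains of gene-model exon indices into a
#' coordinate table, merging genomically abutting segments (re-joining exons
#' that were split at alternative boundaries) into single exon intervals.
#'
#' @param gene A [gene_model()].
#' @param isoforms List of integer exon-index vectors, or a tibble with
#'   list-column `exons` (optionally `refit_abundance`/`abundance`).
#' @param transcript_id Optional character vector of ids.
#' @param total_reads Total mapped reads used for the FPKM conversion
#'   `FPKM = abundance * 1e9 / total_reads`; `NA` leaves FPKM as `NA`.
#' @return Tibble: `gene_id`, `transcript_id`, `seqname`, `strand`,
#'   list-column `blocks` (matrix with columns `start`, `end`, 0-based
#'   half-open merged exon intervals), `abundance`, `fpkm`.
#' @export
transcripts_table <- function(gene, isoforms, transcript_id = NULL,
                              total_reads = NA) {
  if (is.data.frame(isoforms)) {
    ab <- isoforms$refit_abundance %||% isoforms$abundance %||%
      rep(NA_real_, nrow(isoforms))
    chains <- isoforms$exons
  } else {
    chains <- isoforms
    ab <- rep(NA_real_, length(chains))
  }
  if (is.null(transcript_id)) {
    transcript_id <- paste0(gene$gene_id, ".", seq_along(chains))
  }
  blocks <- lapply(chains, function(ch) {
    ex <- gene$exons[sort(as.integer(ch)), , drop = FALSE]
    merge_blocks(ex$start, ex$end)
  })
  tibble(
    gene_id = gene$gene_id,
    transcript_id = transcript_id,
    seqname = gene$seqname,
    strand = gene$strand,
    blocks = blocks,
    abundance = as.numeric(ab),
    fpkm = as.numeric(ab) * 1e9 / total_reads
  )
}

merge_blocks <- function(starts, ends) {
  keep <- c(TRUE, starts[-1] != ends[-length(ends)])
  grp <- cumsum(keep)
  cbind(
    start = as.numeric(tapply(starts, grp, min)),
    end = as.numeric(tapply(ends, grp, max))
  )
}

#' Write a transcript table as GTF
#'
#' One `transcript` record plus per-exon `exon` records per transcript, with
#' `gene_id`, `transcript_id`, `abundance` (reads per base) and `FPKM`
#' attributes. An empty table produces a header-only file.
#'
#' @param transcripts A [transcripts_table()] (tables for several genes may
#'   be row-bound).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(transcripts, file) {
  if (nrow(transcripts) == 0) {
    writeLines("#gtf", file)
    return(invisible(file))
  }
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    b <- tr$blocks[[1]]
    rows[[length(rows) + 1L]] <- tibble(
      seqname = tr$seqname,
      start = min(b[, "start"]) + 1,
      end = max(b[, "end"]),
      strand = tr$strand,
      type = "transcript",
      gene_id = tr$gene_id,
      transcript_id = tr$transcript_id,
      abundance = tr$abundance,
      fpkm = tr$fpkm
    )
    rows[[length(rows) + 1L]] <- tibble(
      seqname = tr$seqname,
      start = b[, "start"] + 1,
      end = b[, "end"],
      strand = tr$strand,
      type = "exon",
      gene_id = tr$gene_id,
      transcript_id = tr$transcript_id,
      abundance = tr$abundance,
      fpkm = tr$fpkm
    )
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
  gr$type <- df$type
  gr$source <- "isoflow"
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$abundance <- df$abundance
  gr$FPKM <- df$fpkm
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read transcripts from a GTF into a coordinate table
#'
#' The inverse of [write_gtf()] for evaluation purposes: exon records are
#' grouped by `transcript_id` into block matrices.
#'
#' @param file GTF path.
#' @return Tibble in the [transcripts_table()] layout.
#' @export
read_transcripts_gtf <- function(file) {
  if (!file.exists(file)) abort(sprintf("GTF file not found: %s", file))
  empty <- tibble(
    gene_id = character(), transcript_id = character(),
    seqname = character(), strand = character(), blocks = list(),
    abundance = numeric(), fpkm = numeric()
  )
  body <- grep("^[^#]", readLines(file), value = TRUE)
  if (length(body) == 0) return(empty)
  gr <- tryCatch(
    rtracklayer::import(file, format = "gtf"),
    error = function(e) abort(sprintf("malformed GTF %s: %s", file, conditionMessage(e)))
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(empty)
  df <- tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    abundance = suppressWarnings(as.numeric(gr$abundance %||% NA)),
    fpkm = suppressWarnings(as.numeric(gr$FPKM %||% NA))
  )
  df <- arrange(df, .data$transcript_id, .data$start)
  out <- df |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = dplyr::first(.data$gene_id),
      seqname = dplyr::first(.data$seqname),
      strand = dplyr::first(.data$strand),
      blocks = list(cbind(start = .data$start, end = .data$end)),
      abundance = dplyr::first(.data$abundance),
      fpkm = dplyr::first(.data$fpkm),
      .groups = "drop"
    )
  select(
    out, "gene_id", "transcript_id", "seqname", "strand",
    "blocks", "abundance", "fpkm"
  )
}

#' Read and write the bin-counts TSV dialect
#'
#' Plain-text exchange format for bin counts: a counts TSV with header
#' `gene_id`, `exon_ids` (comma-joined 0-based exon indices) and `count`,
#' plus a sidecar TSV with the gene's exon coordinates and the read length
#' (`gene_id`, `exon_index` 0-based, `start`, `end`, `read_length`).
#' Internally exon indices are 1-based; conversion happens here only.
#'
#' @param counts Bin-counts tibble (columns `gene_id`, `key`, `count`).
#' @param gene A [gene_model()].
#' @param read_length Read length recorded in the sidecar.
#' @param counts_file,sidecar_file Output/input paths.
#' @return `write_bin_counts()`: invisibly, the counts file path.
#'   `read_bin_counts()`: list with `counts` (bin-counts tibble), `gene` and
#'   `read_length`.
#' @export
write_bin_counts <- function(counts, gene, read_length, counts_file,
                             sidecar_file) {
  ex0 <- vapply(
    parse_bin_key(counts$key),
    function(b) paste(b - 1L, collapse = ","),
    character(1)
  )
  utils::write.table(
    data.frame(gene_id = counts$gene_id, exon_ids = ex0, count = counts$count),
    counts_file,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      gene_id = gene$gene_id,
      exon_index = gene$exons$index - 1L,
      start = gene$exons$start,
      end = gene$exons$end,
      read_length = read_length
    ),
    sidecar_file,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(counts_file)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(counts_file, sidecar_file) {
  ct <- utils::read.delim(counts_file, colClasses = c(exon_ids = "character"))
  if (!all(c("gene_id", "exon_ids", "count") %in% names(ct))) {
    abort("counts TSV must have columns gene_id, exon_ids, count")
  }
  sc <- utils::read.delim(sidecar_file)
  sc <- sc[order(sc$start), ]
  gene <- gene_model(
    data.frame(start = sc$start, end = sc$end),
    gene_id = sc$gene_id[1]
  )
  exons <- lapply(parse_bin_key(ct$exon_ids), function(b) b + 1L)
  counts <- tibble(
    gene_id = ct$gene_id,
    exons = exons,
    key = vapply(exons, bin_key, character(1)),
    count = ct$count
  )
  list(counts = counts, gene = gene, read_length = sc$read_length[1])
}
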