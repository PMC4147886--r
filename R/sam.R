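#' Summarise SAM alignments into bin counts
#'
#' Assigns each mapped single-end read to the bin given by the exact set of
#' gene-model exons it overlaps, and harvests junctions as the consecutive
#' exon pairs spanned by reads (covering both `N`-gapped junctions and
#' pass-through of abutting split exons). Reads whose aligned blocks fall
#' outside the gene's exons, or overhang an exon boundary without a
#' matching junction, are discarded and reported in the diagnostics —
#' never silently dropped. Insertions/deletions are tolerated by projecting
#' the alignment onto the reference.
#'
#' @param sam_file Path to a SAM (or BAM) file.
#' @param gene A [gene_model()]; only reads on its seqname overlapping its
#'   span are considered.
#' @param read_length Read length; `NULL` infers the most common aligned
#'   read width from the first reads (logged via message).
#' @return List with `counts` (bin-counts tibble), `junctions` (two-column
#'   matrix of exon-index pairs), `read_length`, and `diagnostics`
#'   (`n_considered`, `n_assigned`, `n_outside_exons`).
#' @export
sam_to_bin_counts <- function(sam_file, gene, read_length = NULL) {
  if (!file.exists(sam_file)) abort(sprintf("SAM file not found: %s", sam_file))
  ga <- read_alignments(sam_file)
  ga <- ga[as.character(GenomicAlignments::seqnames(ga)) == gene$seqname]
  span <- IRanges::IRanges(min(gene$exons$start) + 1, max(gene$exons$end))
  rd_rng <- IRanges::IRanges(
    GenomicAlignments::start(ga),
    GenomicAlignments::end(ga)
  )
  ga <- ga[IRanges::overlapsAny(rd_rng, span)]
  n_considered <- length(ga)

  if (is.null(read_length)) {
    w <- GenomicAlignments::qwidth(head(ga, 1000))
    read_length <- if (length(w)) as.integer(names(sort(table(w), decreasing = TRUE))[1]) else
      abort("cannot infer read length from an empty alignment set")
    message(sprintf("inferred read length %d from alignments", read_length))
  }

  if (n_considered == 0) {
    return(list(
      counts = tibble(
        gene_id = character(0), exons = list(), key = character(0),
        count = integer(0)
      ),
      junctions = matrix(integer(0), ncol = 2),
      read_length = read_length,
      diagnostics = list(n_considered = 0L, n_assigned = 0L, n_outside_exons = 0L)
    ))
  }

  blocks <- GenomicAlignments::grglist(ga) # split at N; D projected into blocks
  fb <- unlist(blocks)
  rd_idx <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  bl_ir <- IRanges::IRanges(GenomicRanges::start(fb), GenomicRanges::end(fb))
  ex_ir <- IRanges::IRanges(gene$exons$start + 1, gene$exons$end)

  ov <- IRanges::findOverlaps(bl_ir, ex_ir)
  covered <- numeric(length(bl_ir))
  inter_w <- IRanges::width(IRanges::pintersect(
    bl_ir[S4Vectors::queryHits(ov)], ex_ir[S4Vectors::subjectHits(ov)]
  ))
  cw <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
  covered[as.integer(names(cw))] <- cw
  block_ok <- covered == IRanges::width(bl_ir)
  read_ok <- tapply(block_ok, rd_idx, all)
  read_ok_vec <- logical(length(blocks))
  read_ok_vec[as.integer(names(read_ok))] <- unlist(read_ok)

  exon_hits <- tibble(
    read = rd_idx[S4Vectors::queryHits(ov)],
    exon = S4Vectors::subjectHits(ov)
  )
  chains <- lapply(
    split(exon_hits$exon, exon_hits$read),
    function(e) sort(unique(e))
  )
  chain_read <- as.integer(names(chains))
  keep <- read_ok_vec[chain_read]
  chains <- chains[keep]

  n_assigned <- length(chains)
  keys <- vapply(chains, bin_key, character(1))
  tab <- table(keys)
  uniq_keys <- names(tab)
  exons <- parse_bin_key(uniq_keys)
  jn <- unique(do.call(rbind, lapply(unname(chains), function(b) {
    if (length(b) < 2) return(NULL)
    cbind(b[-length(b)], b[-1])
  })))
  if (is.null(jn)) jn <- matrix(integer(0), ncol = 2)

  list(
    counts = tibble(
      gene_id = gene$gene_id,
      exons = exons,
      key = uniq_keys,
      count = as.integer(tab)
    ),
    junctions = jn,
    read_length = read_length,
    diagnostics = list(
      n_considered = n_considered,
      n_assigned = n_assigned,
      n_outside_exons = n_considered - n_assigned
    )
  )
}

read_alignments <- function(sam_file) {
  path <- sam_file
  if (grepl("\\.sam$", sam_file, ignore.case = TRUE)) {
    validate_sam(sam_file)
    dest <- tempfile(fileext = "")
    path <- tryCatch(
      Rsamtools::asBam(sam_file, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) {
        abort(sprintf("malformed SAM %s: %s", sam_file, conditionMessage(e)))
      }
    )
  }
  GenomicAlignments::readGAlignments(path)
}

# structural check ahead of htslib, which skips bad records silently ---------
validate_sam <- function(sam_file) {
  lines <- readLines(sam_file)
  body <- which(!startsWith(lines, "@"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11 || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[4])))) {
      abort(sprintf("malformed SAM record at line %d of %s", i, sam_file))
    }
  }
  invisible(TRUE)
}

#' Quantify isoforms from a SAM file and an annotation
#'
#' The full pipeline: for every gene of the annotation, summarise its reads
#' into bin counts ([sam_to_bin_counts()]), build the bin graph from the
#' junctions observed in the data, fit the regularisation path and select
#' the transcript set by BIC ([fit_isoforms()]). Genes are processed
#' independently.
#'
#' @param sam_file Path to SAM/BAM alignments.
#' @param annotation An [read_annotation()] object or a path to a GTF/BED
#'   annotation (used for exon boundaries only; junctions come from reads).
#' @param read_length Read length; `NULL` infers it per gene.
#' @param config A [fit_config()].
#' @param min_abundance Predictions below this abundance (reads per base)
#'   are filtered out.
#' @return List with `transcripts` (row-bound [transcripts_table()] across
#'   genes, FPKM computed against the total of assigned reads), `fits`
#'   (named list of `isoflow_fit`), `diagnostics` tibble.
#' @export
quantify_sam <- function(sam_file, annotation, read_length = NULL,
                         config = fit_config(), min_abundance = 0) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  per_gene <- list()
  fits <- list()
  diags <- list()
  for (gid in names(annotation$genes)) {
    gene <- annotation$genes[[gid]]
    bc <- sam_to_bin_counts(sam_file, gene, read_length)
    diags[[gid]] <- tibble(
      gene_id = gid,
      n_considered = bc$diagnostics$n_considered,
      n_assigned = bc$diagnostics$n_assigned,
      n_outside_exons = bc$diagnostics$n_outside_exons
    )
    if (sum(bc$counts$count) == 0) next
    fit <- fit_isoforms(
      bc$counts, gene, bc$read_length,
      junctions = bc$junctions, config = config
    )
    fits[[gid]] <- fit
    iso <- fit$isoforms
    floor_ab <- config$abundance_floor_frac *
      max(sum(iso$refit_abundance), 1e-300)
    iso <- iso[iso$refit_abundance > pmax(floor_ab, min_abundance), , drop = FALSE]
    if (nrow(iso)) per_gene[[gid]] <- iso
  }
  total_reads <- sum(vapply(diags, function(d) d$n_assigned, numeric(1)))
  tx <- purrr::imap(per_gene, function(iso, gid) {
    transcripts_table(
      annotation$genes[[gid]],
      tibble(exons = iso$exons, refit_abundance = iso$refit_abundance),
      total_reads = total_reads
    )
  })
  tx <- if (length(tx)) bind_rows(tx) else transcripts_table(
    gene_model(data.frame(start = 0, end = 1)), list()
  )[0, ]
  list(
    transcripts = tx,
    fits = fits,
    diagnostics = bind_rows(diags)
  )
}
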