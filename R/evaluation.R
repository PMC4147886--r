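#' Match predicted transcripts against a reference set
#'
#' A reference transcript counts as detected when some prediction (i) has
#' the same exon chain and (ii) identical internal boundary coordinates —
#' every exon coordinate except the start of the first exon and the end of
#' the last exon. Matching is greedy one-to-one: each prediction consumes at
#' most one reference transcript. Since outer boundaries are free, the rule
#' is complemented by requiring the same seqname and overlapping spans so
#' that single-exon transcripts of unrelated loci cannot match.
#'
#' @param predicted,truth Transcript tables in the [transcripts_table()] /
#'   [read_transcripts_gtf()] layout.
#' @return List of class `transcript_matching`: `truth` with columns
#'   `detected` and `matched_by`; `predicted` with `matched` and
#'   `matches_tx`; both keep `n_exons` and gene ids.
#' @export
match_transcripts <- function(predicted, truth) {
  sig <- function(tbl) {
    vapply(seq_len(nrow(tbl)), function(i) {
      b <- tbl$blocks[[i]]
      k <- nrow(b)
      internal <- if (k == 1) {
        ""
      } else {
        paste(c(b[1, "end"], t(b[-c(1, k), , drop = FALSE]), b[k, "start"]),
          collapse = ","
        )
      }
      paste(tbl$seqname[i], k, internal, sep = "|")
    }, character(1))
  }
  span <- function(tbl) {
    cbind(
      vapply(tbl$blocks, function(b) min(b[, "start"]), numeric(1)),
      vapply(tbl$blocks, function(b) max(b[, "end"]), numeric(1))
    )
  }
  p_sig <- sig(predicted)
  t_sig <- sig(truth)
  p_span <- span(predicted)
  t_span <- span(truth)

  detected <- logical(nrow(truth))
  matched_by <- rep(NA_character_, nrow(truth))
  matched <- logical(nrow(predicted))
  matches_tx <- rep(NA_character_, nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    cand <- which(
      !detected & t_sig == p_sig[i] &
        t_span[, 1] < p_span[i, 2] & p_span[i, 1] < t_span[, 2]
    )
    if (length(cand)) {
      j <- cand[1]
      detected[j] <- TRUE
      matched_by[j] <- predicted$transcript_id[i]
      matched[i] <- TRUE
      matches_tx[i] <- truth$transcript_id[j]
    }
  }
  structure(
    list(
      truth = mutate(truth,
        n_exons = vapply(.data$blocks, nrow, integer(1)),
        detected = detected, matched_by = matched_by
      ),
      predicted = mutate(predicted,
        n_exons = vapply(.data$blocks, nrow, integer(1)),
        matched = matched, matches_tx = matches_tx
      )
    ),
    class = "transcript_matching"
  )
}

#' Precision and recall, stratified by gene complexity
#'
#' Precision is the fraction of predictions matching a reference transcript;
#' recall the fraction of reference transcripts detected. Results are
#' stratified by the reference gene's transcript count (or exon count of the
#' transcript), since deconvolution difficulty grows with the number of
#' expressed transcripts. A pooled row (`stratum = "all"`) is included.
#' Predictions are assigned to strata through their matched reference
#' transcript, or by span overlap with a reference gene when unmatched;
#' unassignable predictions count only in the pooled precision. Empty
#' strata report `NA`.
#'
#' @param matching A [match_transcripts()] result.
#' @param stratify_by `"transcripts"` (reference transcripts per gene) or
#'   `"exons"` (exons per reference transcript).
#' @return Tibble: `stratum`, `n_truth`, `n_predicted`, `n_detected`,
#'   `n_matched`, `precision`, `recall`.
#' @export
precision_recall <- function(matching,
                             stratify_by = c("transcripts", "exons")) {
  stratify_by <- match.arg(stratify_by)
  tr <- matching$truth
  pr <- matching$predicted
  if (stratify_by == "transcripts") {
    gene_n <- tr |>
      group_by(.data$gene_id) |>
      summarise(stratum_val = dplyr::n(), .groups = "drop")
    tr <- left_join(tr, gene_n, by = "gene_id")
  } else {
    tr <- mutate(tr, stratum_val = .data$n_exons)
  }
  # assign predictions: via match, else by span overlap with a truth gene
  t_span <- tr |>
    mutate(
      lo = vapply(.data$blocks, function(b) min(b[, "start"]), numeric(1)),
      hi = vapply(.data$blocks, function(b) max(b[, "end"]), numeric(1))
    )
  pred_val <- rep(NA_real_, nrow(pr))
  for (i in seq_len(nrow(pr))) {
    if (!is.na(pr$matches_tx[i])) {
      pred_val[i] <- t_span$stratum_val[match(pr$matches_tx[i], t_span$transcript_id)]
      if (stratify_by == "exons") pred_val[i] <- pr$n_exons[i]
      next
    }
    if (stratify_by == "exons") {
      pred_val[i] <- pr$n_exons[i]
      next
    }
    b <- pr$blocks[[i]]
    lo <- min(b[, "start"])
    hi <- max(b[, "end"])
    hitg <- t_span$gene_id[
      t_span$seqname == pr$seqname[i] & t_span$lo < hi & lo < t_span$hi
    ]
    if (length(hitg)) {
      pred_val[i] <- t_span$stratum_val[match(hitg[1], t_span$gene_id)]
    }
  }
  strata <- sort(unique(tr$stratum_val))
  per <- lapply(strata, function(sv) {
    tt <- tr[tr$stratum_val == sv, , drop = FALSE]
    pp <- pr[!is.na(pred_val) & pred_val == sv, , drop = FALSE]
    tibble(
      stratum = as.character(sv),
      n_truth = nrow(tt), n_predicted = nrow(pp),
      n_detected = sum(tt$detected), n_matched = sum(pp$matched),
      precision = if (nrow(pp)) sum(pp$matched) / nrow(pp) else NA_real_,
      recall = if (nrow(tt)) sum(tt$detected) / nrow(tt) else NA_real_
    )
  })
  pooled <- tibble(
    stratum = "all",
    n_truth = nrow(tr), n_predicted = nrow(pr),
    n_detected = sum(tr$detected), n_matched = sum(pr$matched),
    precision = if (nrow(pr)) sum(pr$matched) / nrow(pr) else NA_real_,
    recall = if (nrow(tr)) sum(tr$detected) / nrow(tr) else NA_real_
  )
  bind_rows(per, pooled)
}

#' Evaluate predictions in GTF form against a reference GTF
#'
#' Convenience wrapper: read both files, [match_transcripts()], then
#' [precision_recall()].
#'
#' @param pred_file,truth_file GTF paths.
#' @param stratify_by See [precision_recall()].
#' @param min_abundance Drop predictions below this `abundance` attribute
#'   before matching (when present).
#' @return The [precision_recall()] tibble.
#' @export
evaluate_gtf <- function(pred_file, truth_file,
                         stratify_by = "transcripts", min_abundance = 0) {
  pred <- read_transcripts_gtf(pred_file)
  if (min_abundance > 0 && nrow(pred)) {
    pred <- pred[is.na(pred$abundance) | pred$abundance >= min_abundance, ,
      drop = FALSE
    ]
  }
  truth <- read_transcripts_gtf(truth_file)
  precision_recall(match_transcripts(pred, truth), stratify_by = stratify_by)
}
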