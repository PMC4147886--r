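#' Configuration for a regularisation-path fit
#'
#' @param lambda_grid Strictly decreasing positive penalty values. Default
#'   (`NULL`): 20 log-spaced values from the total read count down to
#'   `1e-4` times it — Poisson gradients scale with counts, so the top of
#'   this grid yields the empty model and the bottom a near-unpenalised fit.
#' @param tol Solver optimality tolerance (see [solve_min_cost_flow()]).
#' @param min_frac Flow-decomposition stopping fraction.
#' @param bic_refit Refit maximum likelihood on each support before BIC
#'   scoring (removes l1 shrinkage so models are compared on genuine
#'   likelihoods).
#' @param abundance_floor_frac An isoform counts towards model size `k` only
#'   when its refit abundance exceeds this fraction of the total (numerical
#'   zeros are not parameters).
#' @param seed Optional integer seed recorded in the config.
#' @return A `fit_config` list.
#' @export
fit_config <- function(lambda_grid = NULL, tol = 1e-6, min_frac = 1e-8,
                       bic_refit = TRUE, abundance_floor_frac = 1e-6,
                       seed = NULL) {
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) && !all(lambda_grid[-length(lambda_grid)] > 0)) {
      abort("lambda_grid must be positive (a terminal 0 is allowed)")
    }
    if (is.unsorted(rev(lambda_grid), strictly = TRUE)) {
      abort("lambda_grid must be strictly decreasing")
    }
  }
  structure(
    list(
      lambda_grid = lambda_grid, tol = tol, min_frac = min_frac,
      bic_refit = bic_refit, abundance_floor_frac = abundance_floor_frac,
      seed = seed
    ),
    class = "fit_config"
  )
}

default_lambda_grid <- function(total_count, n = 20, decades = 4) {
  hi <- max(total_count, 1)
  exp(seq(log(hi), log(hi * 10^(-decades)), length.out = n))
}

#' Maximum-likelihood refit on a fixed isoform support
#'
#' Maximises the unpenalised Poisson log-likelihood (including `log(y!)`
#' constants) over the abundances of a given set of isoforms — a convex,
#' low-dimensional problem. Used to de-bias the l1 solution before BIC
#' scoring. An empty support scores the all-zero-intensity model.
#'
#' @param graph A [build_bin_graph()] result.
#' @param support List of isoforms (integer exon-index vectors).
#' @param counts Bin-counts tibble or per-vertex vector.
#' @return List with `abundance` (per isoform) and `loglik`.
#' @export
refit_ml <- function(graph, support, counts) {
  y <- as.numeric(counts_vector(graph, counts))
  l <- graph$vertices$eff_len
  if (length(support) == 0) {
    return(list(abundance = numeric(0), loglik = poisson_loglik(y, rep(0, length(y)))))
  }
  nv <- nrow(graph$vertices)
  A <- matrix(0, nv, length(support))
  for (j in seq_along(support)) {
    b <- isoform_bins(graph$gene, support[[j]], graph$read_length)
    idx <- match(b$key, graph$vertices$key)
    if (anyNA(idx)) abort("support isoform uses bins absent from the graph")
    A[idx, j] <- 1
  }
  th0 <- rep(sum(y) / (sum(l) + 1) / length(support) + 1e-3, length(support))
  rf <- refit_weights(A, y, l, lambda = 0, theta0 = th0)
  delta <- l * as.vector(A %*% rf$theta)
  list(abundance = rf$theta, loglik = poisson_loglik(y, delta))
}

#' Fit the regularisation path
#'
#' Solves the penalised flow problem for each value of a decreasing lambda
#' grid (warm-starting each solve from the previous active set), decomposes
#' each optimal flow into isoforms, and records the unpenalised refit
#' log-likelihood of each support. Larger penalties select fewer isoforms;
#' as lambda decreases the support typically grows (logged, not guaranteed).
#'
#' @param graph A [build_bin_graph()] result.
#' @param counts Bin-counts tibble or per-vertex vector.
#' @param config A [fit_config()].
#' @return Tibble with one row per lambda: `lambda`, list-column `isoforms`
#'   (tibble `exons`/`key`/`abundance` from the decomposition, with refit
#'   abundances in `refit_abundance`), `n_isoforms` (above the abundance
#'   floor), `loglik` (refit), `bic`, and `error` (message, or `NA`).
#' @export
fit_path <- function(graph, counts, config = fit_config()) {
  y <- as.numeric(counts_vector(graph, counts))
  grid <- config$lambda_grid %||% default_lambda_grid(sum(y))
  n_obs <- sum(y)
  warm <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    lam <- grid[i]
    rows[[i]] <- tryCatch(
      {
        fit <- solve_min_cost_flow(graph, y, lam,
          tol = config$tol, warm_paths = warm
        )
        warm <- fit$theta$path
        dec <- decompose_flow(graph, fit$flow, config$min_frac)
        support <- dec$exons[!duplicated(dec$key)]
        rf <- if (config$bic_refit) {
          refit_ml(graph, support, y)
        } else {
          list(
            abundance = dec$abundance[!duplicated(dec$key)],
            loglik = poisson_loglik(y, l_times(graph, support, dec$abundance[!duplicated(dec$key)]))
          )
        }
        iso <- tibble(
          exons = support,
          key = vapply(support, bin_key, character(1)),
          refit_abundance = rf$abundance
        )
        iso <- left_join(iso, select(dec[!duplicated(dec$key), ], "key", "abundance"), by = "key")
        k <- sum(rf$abundance > config$abundance_floor_frac * max(sum(rf$abundance), 1e-300))
        tibble(
          lambda = lam, isoforms = list(iso), n_isoforms = k,
          loglik = rf$loglik,
          bic = bic_score(rf$loglik, k, n_obs),
          error = NA_character_
        )
      },
      error = function(e) {
        tibble(
          lambda = lam, isoforms = list(tibble()), n_isoforms = NA_integer_,
          loglik = NA_real_, bic = NA_real_, error = conditionMessage(e)
        )
      }
    )
  }
  bind_rows(rows)
}

# intensities for un-refit scoring -------------------------------------------
l_times <- function(graph, support, abundance) {
  nv <- nrow(graph$vertices)
  u <- numeric(nv)
  for (j in seq_along(support)) {
    b <- isoform_bins(graph$gene, support[[j]], graph$read_length)
    idx <- match(b$key, graph$vertices$key)
    u[idx] <- u[idx] + abundance[j]
  }
  graph$vertices$eff_len * u
}

# Schwarz-type criterion, maximisation form. The sample size is the total
# number of assigned reads: each read is one observation of the isoform
# mixture, and the information about abundances grows with coverage, not
# with the number of bins the reads are aggregated into. A per-bin sample
# size makes the penalty O(log q) while the chance log-likelihood gain of
# the best spurious isoform grows with the candidate set, and overfits.
bic_score <- function(loglik, k, n_obs) {
  loglik - (k / 2) * log(max(n_obs, 1))
}

#' Select the final model by BIC
#'
#' Picks the regularisation-path fit maximising `loglik - (k/2) log(n)`,
#' where `k` is the number of isoforms above the abundance floor and `n` the
#' total number of assigned reads. Ties go to fewer isoforms, then to
#' the larger penalty.
#'
#' @param path_fits Output of [fit_path()].
#' @return The selected row of `path_fits` (one-row tibble).
#' @export
bic_select <- function(path_fits) {
  ok <- path_fits[is.na(path_fits$error) & is.finite(path_fits$bic), , drop = FALSE]
  if (nrow(ok) == 0) {
    ok <- path_fits[is.na(path_fits$error), , drop = FALSE]
    if (nrow(ok) == 0) abort("no usable fit on the regularisation path")
    # all-(-Inf) likelihoods: fall back to fewest isoforms, largest lambda
    return(ok[order(ok$n_isoforms, -ok$lambda)[1], , drop = FALSE])
  }
  ok[order(-ok$bic, ok$n_isoforms, -ok$lambda)[1], , drop = FALSE]
}

#' Identify and quantify isoforms from bin counts
#'
#' End-to-end estimation for one gene: build (or accept) the bin graph, fit
#' the full regularisation path, and select the transcript set by BIC.
#'
#' @param counts Bin-counts tibble (columns `key`, `count`), e.g. from
#'   [simulate_counts()] or [sam_to_bin_counts()].
#' @param gene A [gene_model()].
#' @param junctions Exon-junction pairs for the graph; default derives them
#'   from consecutive exon pairs present in the observed bins.
#' @param read_length Read length in bases.
#' @param config A [fit_config()].
#' @param graph Optionally a pre-built [build_bin_graph()] (overrides
#'   `junctions`).
#' @return An `isoflow_fit` object; see [tidy.isoflow_fit()],
#'   [glance.isoflow_fit()], [autoplot.isoflow_fit()].
#' @export
fit_isoforms <- function(counts, gene, read_length, junctions = NULL,
                         config = fit_config(), graph = NULL) {
  if (is.null(graph)) {
    if (is.null(junctions)) junctions <- junctions_from_counts(counts)
    graph <- build_bin_graph(gene, junctions, read_length)
  }
  fits <- fit_path(graph, counts, config)
  sel <- bic_select(fits)
  structure(
    list(
      gene = gene, graph = graph, config = config,
      path = fits, selected = sel,
      isoforms = sel$isoforms[[1]],
      lambda = sel$lambda, loglik = sel$loglik, bic = sel$bic,
      counts = counts
    ),
    class = "isoflow_fit"
  )
}

# consecutive exon pairs observed within any counted bin ---------------------
junctions_from_counts <- function(counts) {
  ex <- parse_bin_key(counts$key[counts$count > 0])
  prs <- unique(do.call(rbind, lapply(ex, function(b) {
    if (length(b) < 2) return(NULL)
    cbind(b[-length(b)], b[-1])
  })))
  prs
}

#' @export
print.isoflow_fit <- function(x, ...) {
  cat(sprintf(
    "<isoflow_fit> %s: %d isoform%s at lambda = %.4g (BIC %.4g, loglik %.4g)\n",
    x$gene$gene_id, x$selected$n_isoforms,
    if (x$selected$n_isoforms == 1) "" else "s", x$lambda, x$bic, x$loglik
  ))
  if (nrow(x$isoforms)) print(select(x$isoforms, "key", "refit_abundance"), ...)
  invisible(x)
}

#' Tidy the selected isoforms of a fit
#'
#' @param x An `isoflow_fit`.
#' @param ... Unused.
#' @return Tibble with one row per selected isoform: `gene_id`,
#'   `transcript_id`, `exons` (comma-joined 1-based indices), `n_exons`,
#'   `abundance` (refit, reads per base) and `length` (exonic bases).
#' @method tidy isoflow_fit
#' @export
tidy.isoflow_fit <- function(x, ...) {
  iso <- x$isoforms
  if (nrow(iso) == 0) {
    return(tibble(
      gene_id = character(), transcript_id = character(), exons = character(),
      n_exons = integer(), abundance = numeric(), length = numeric()
    ))
  }
  tibble(
    gene_id = x$gene$gene_id,
    transcript_id = paste0(x$gene$gene_id, ".", seq_len(nrow(iso))),
    exons = iso$key,
    n_exons = vapply(iso$exons, length, integer(1)),
    abundance = iso$refit_abundance,
    length = vapply(iso$exons, function(b) sum(exon_lengths(x$gene)[b]), numeric(1))
  )
}

#' One-row summary of a fit
#'
#' @param x An `isoflow_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_isoforms`, `lambda`, `loglik`, `bic`,
#'   `n_bins_observed`, `total_count`.
#' @method glance isoflow_fit
#' @export
glance.isoflow_fit <- function(x, ...) {
  y <- as.numeric(counts_vector(x$graph, x$counts))
  tibble(
    n_isoforms = x$selected$n_isoforms,
    lambda = x$lambda,
    loglik = x$loglik,
    bic = x$bic,
    n_bins_observed = sum(y > 0),
    total_count = sum(y)
  )
}

#' Plot the regularisation path of a fit
#'
#' Shows BIC and the number of selected isoforms against the penalty, with
#' the BIC-selected model marked.
#'
#' @param object An `isoflow_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isoflow_fit
#' @export
autoplot.isoflow_fit <- function(object, ...) {
  df <- object$path
  df <- df[is.na(df$error), , drop = FALSE]
  long <- tidyr::pivot_longer(
    select(df, "lambda", "bic", "n_isoforms"),
    c("bic", "n_isoforms"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = expression(lambda), y = NULL,
      title = "Regularisation path",
      subtitle = "dashed line: BIC-selected model"
    ) +
    ggplot2::theme_minimal()
}
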