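test_that("maximum-likelihood refit solves the single-bin case exactly", {
  # one exon of 2 bases, reads of 1 base: a single bin with effective length 2
  g <- gene_model(data.frame(start = 0, end = 2))
  bg <- build_bin_graph(g, NULL, 1)
  expect_equal(bg$vertices$eff_len, 2)
  rf <- refit_ml(bg, list(1L), tibble::tibble(key = "1", count = 4))
  expect_equal(rf$abundance, 2, tolerance = 1e-6) # theta-hat = y / l
  expect_equal(rf$loglik, dpois(4, 4, log = TRUE), tolerance = 1e-8)
})

test_that("refit on the true support of noiseless counts recovers the truth", {
  mex <- mex_instance()
  bg <- build_bin_graph(mex$gene, mex$junctions, mex$L)
  # noiseless data: counts equal to their Poisson means
  sim <- simulate_counts(mex$gene, mex$isoforms, mex$L, seed = 1)
  noiseless <- sim
  noiseless$count <- attr(sim, "delta")[noiseless$key]
  rf <- refit_ml(bg, lapply(mex$isoforms, `[[`, "exons"), noiseless)
  expect_equal(rf$abundance,
    vapply(mex$isoforms, `[[`, numeric(1), "abundance"),
    tolerance = 1e-4
  )
})

test_that("an extra isoform never decreases the refit log-likelihood", {
  set.seed(71)
  mex <- mex_instance()
  bg <- build_bin_graph(mex$gene, mex$junctions, mex$L)
  counts <- simulate_counts(mex$gene, mex$isoforms, mex$L, seed = 3)
  support <- lapply(mex$isoforms, `[[`, "exons")
  base <- refit_ml(bg, support, counts)
  paths <- enumerate_paths(bg)
  for (p in paths[sample(length(paths), 4)]) {
    extra <- c(support, list(path_to_isoform(bg, p)))
    expect_gte(refit_ml(bg, extra, counts)$loglik, base$loglik - 1e-6)
  }
})

test_that("empty support scores the all-zero-intensity model", {
  g <- fig_gene()
  bg <- build_bin_graph(g, fig_junctions(), 100)
  expect_equal(refit_ml(bg, list(), numeric(nrow(bg$vertices)))$loglik, 0)
  y <- numeric(nrow(bg$vertices))
  y[2] <- 3
  expect_identical(refit_ml(bg, list(), y)$loglik, -Inf)
})

test_that("BIC prefers the smaller model on equal likelihoods", {
  fits <- tibble::tibble(
    lambda = c(2, 1),
    isoforms = list(tibble::tibble(), tibble::tibble()),
    n_isoforms = c(1L, 2L),
    loglik = c(-10, -10),
    bic = c(-10 - 0.5 * log(100), -10 - 1 * log(100)),
    error = NA_character_
  )
  expect_equal(bic_select(fits)$n_isoforms, 1L)
  expect_equal(bic_select(fits[2, ])$n_isoforms, 2L) # single fit: that fit
})

test_that("all-zero counts yield an empty model along the whole path", {
  g <- fig_gene()
  bg <- build_bin_graph(g, fig_junctions(), 100)
  fits <- fit_path(bg, numeric(nrow(bg$vertices)))
  expect_true(all(fits$n_isoforms == 0))
  expect_true(all(vapply(fits$isoforms, nrow, integer(1)) == 0))
})

test_that("noiseless single-isoform data is recovered along the path", {
  g <- fig_gene()
  bg <- build_bin_graph(g, fig_junctions(), 100)
  b <- isoform_bins(g, c(1L, 4L, 5L), 100)
  counts <- tibble::tibble(key = b$key, count = round(b$effective_length * 5))
  fit <- fit_isoforms(counts, g, 100, graph = bg)
  expect_equal(fit$isoforms$key, "1,4,5")
  expect_equal(fit$isoforms$refit_abundance, 5, tolerance = 0.01)
})

test_that("as the penalty vanishes the refit approaches the unpenalised optimum", {
  set.seed(73)
  inst <- random_gene_instance(n_exons = 4)
  bg <- build_bin_graph(inst$gene, inst$junctions, inst$L)
  isos <- chain_isoforms(inst$gene, inst$junctions, inst$L)
  sim <- lapply(
    isos[sample(length(isos), 2)],
    function(e) list(exons = e, abundance = runif(1, 1, 4))
  )
  counts <- simulate_counts(inst$gene, sim, inst$L, seed = 9)
  cfg <- fit_config(lambda_grid = c(100, 1, 0.01))
  fits <- fit_path(bg, counts, cfg)
  # oracle: unpenalised maximum over the full candidate set, plus constants
  orc <- oracle_solve(bg, counts, lambda = 0)
  y <- as.numeric(counts_vector(bg, counts))
  loglik_max <- -orc$value - sum(lgamma(y + 1))
  expect_lte(abs(fits$loglik[3] - loglik_max), 1e-3 * max(1, abs(loglik_max)))
})

test_that("BIC selects the true two-isoform model in seeded replicates", {
  mex <- mex_instance(n_reads = 1e5)
  bg <- build_bin_graph(mex$gene, mex$junctions, mex$L)
  hits <- 0
  for (r in 1:10) {
    counts <- simulate_counts(mex$gene, mex$isoforms, mex$L, seed = 500 + r)
    fit <- fit_isoforms(counts, mex$gene, mex$L, graph = bg)
    hits <- hits + (fit$selected$n_isoforms == 2)
  }
  expect_gte(hits, 9)
})

test_that("fit configuration validates its grid", {
  expect_error(fit_config(lambda_grid = c(1, 2)), "decreasing")
  expect_silent(fit_config(lambda_grid = c(10, 1, 0.1)))
})

test_that("tidy, glance and autoplot summarise a fit", {
  mex <- mex_instance()
  counts <- simulate_counts(mex$gene, mex$isoforms, mex$L, seed = 2)
  fit <- fit_isoforms(counts, mex$gene, mex$L, junctions = mex$junctions)
  td <- tidy(fit)
  expect_true(all(c("transcript_id", "exons", "abundance", "length") %in% names(td)))
  expect_equal(nrow(td), nrow(fit$isoforms))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total_count, sum(counts$count))
  expect_s3_class(autoplot(fit), "ggplot")
})
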