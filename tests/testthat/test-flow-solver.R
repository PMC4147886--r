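test_that("node splitting reduces vertex costs to arc costs with the right shape", {
  g <- fig_gene()
  bg <- build_bin_graph(g, fig_junctions(), 100)
  y <- numeric(nrow(bg$vertices))
  y[1] <- 4
  tr <- node_split_transform(bg, y, lambda = 2)
  nv <- nrow(bg$vertices)
  expect_equal(nrow(tr$nodes), 2 * nv + 3) # v_in/v_out per bin + s + pre-sink + sink
  expect_equal(nrow(tr$arcs), nv + nrow(bg$arcs) + 1)
  expect_equal(sum(tr$arcs$type == "split"), nv)
  # zero-count vertex cost is linear in f
  j <- which(tr$arcs$type == "split" & tr$arcs$count == 0)[1]
  lj <- tr$arcs$eff_len[j]
  expect_equal(tr$arc_cost(j, 3), 3 * lj)
  expect_equal(tr$arc_cost(which(tr$arcs$type == "structural")[1], 5), 0)
  expect_equal(tr$arc_cost(which(tr$arcs$type == "penalty"), 3), 6)

  # split-arc cost on a one-bin graph with l = 2 and y = 4, at f = 2:
  # l f - y log(l f) = 4 - 4 log 4
  g2 <- gene_model(data.frame(start = 0, end = 2))
  bg2 <- build_bin_graph(g2, NULL, 1)
  tr2 <- node_split_transform(bg2, 4, lambda = 0)
  i <- which(tr2$arcs$type == "split")
  expect_equal(tr2$arcs$eff_len[i], 2)
  expect_equal(tr2$arc_cost(i, 2), 4 - 4 * log(4))
  # a positive count with zero flow is impossible: infinite cost
  expect_identical(tr2$arc_cost(i, 0), Inf)
})

test_that("a single-bin problem attains the closed-form abundance y/(l+lambda)", {
  for (le in c(150, 300, 1000)) {
    g <- gene_model(data.frame(start = 0, end = le))
    bg <- build_bin_graph(g, NULL, 100)
    l <- bg$vertices$eff_len
    for (y in c(3, 40, 500)) {
      for (lam in c(0.1, 1, 10, 100)) {
        fit <- solve_min_cost_flow(bg, tibble::tibble(key = "1", count = y), lam)
        expect_equal(fit$theta$weight, y / (l + lam), tolerance = 1e-6)
      }
    }
  }
})

test_that("with no penalty and disjoint paths the fit saturates each bin", {
  # no junctions: every bin lies on exactly one (s,t)-path
  g <- fig_gene()
  bg <- build_bin_graph(g, NULL, 100)
  y <- c(12, 300, 7, 0, 55)[match(bg$vertices$key, as.character(1:5))]
  fit <- solve_min_cost_flow(bg, y, lambda = 0)
  fv <- isoflow:::vertex_inflow(bg, fit$flow)
  delta <- bg$vertices$eff_len * fv[bg$vertices$id]
  expect_equal(delta, y, tolerance = 1e-6)
})

test_that("the solver matches the brute-force path oracle on random instances", {
  set.seed(41)
  for (i in 1:15) {
    inst <- random_gene_instance()
    bg <- build_bin_graph(inst$gene, inst$junctions, inst$L)
    isos <- chain_isoforms(inst$gene, inst$junctions, inst$L)
    pick <- sample(length(isos), min(2, length(isos)))
    sim <- lapply(pick, function(k) list(exons = isos[[k]], abundance = runif(1, 0.5, 3)))
    counts <- simulate_counts(inst$gene, sim, inst$L, seed = 1000 + i)
    for (lam in c(0.1, 1, 10)) {
      fit <- solve_min_cost_flow(bg, counts, lam)
      orc <- oracle_solve(bg, counts, lam)
      expect_equal(fit$objective, orc$value,
        tolerance = 1e-4,
        info = sprintf("instance %d lambda %g", i, lam)
      )
    }
  }
})

test_that("total delivered flow shrinks as the l1 penalty grows", {
  set.seed(43)
  for (i in 1:5) {
    inst <- random_gene_instance()
    bg <- build_bin_graph(inst$gene, inst$junctions, inst$L)
    y <- rpois(nrow(bg$vertices), 20)
    lams <- c(0.1, 1, 10, 100, 1000)
    tot <- vapply(lams, function(lam) {
      fit <- solve_min_cost_flow(bg, y, lam)
      sum(fit$flow[bg$arcs$to == bg$t])
    }, numeric(1))
    expect_true(all(diff(tot) <= 1e-6 * max(tot, 1)))
  }
})

test_that("returned flows conserve mass at every internal vertex", {
  set.seed(47)
  inst <- random_gene_instance(n_exons = 5)
  bg <- build_bin_graph(inst$gene, inst$junctions, inst$L)
  y <- rpois(nrow(bg$vertices), 15)
  fit <- solve_min_cost_flow(bg, y, 1)
  inn <- tapply(fit$flow, bg$arcs$to, sum)
  out <- tapply(fit$flow, bg$arcs$from, sum)
  total <- sum(fit$flow[bg$arcs$to == bg$t])
  for (v in as.character(bg$vertices$id)) {
    i <- if (v %in% names(inn)) inn[[v]] else 0
    o <- if (v %in% names(out)) out[[v]] else 0
    expect_lte(abs(i - o), 1e-8 * max(total, 1))
  }
})

test_that("the optimum is no worse than any single-path fit", {
  set.seed(53)
  inst <- random_gene_instance(n_exons = 4)
  bg <- build_bin_graph(inst$gene, inst$junctions, inst$L)
  # counts supported on one path so that single-path fits are feasible
  p0 <- enumerate_paths(bg)[[1]]
  y <- numeric(nrow(bg$vertices))
  v0 <- setdiff(p0, c(bg$s, bg$t))
  y[v0] <- rpois(length(v0), 15)
  lam <- 1
  fit <- solve_min_cost_flow(bg, y, lam)
  paths <- enumerate_paths(bg)
  l <- bg$vertices$eff_len
  for (p in paths) {
    v <- setdiff(p, c(bg$s, bg$t))
    if (any(y[-v] > 0)) next # single-path fit cannot explain those counts
    one <- function(th) {
      d <- numeric(length(y))
      d[v] <- l[v] * th
      pos <- y > 0
      sum(d) - sum(y[pos] * log(d[pos])) + lam * th
    }
    best <- optimize(one, c(1e-9, sum(y) + 1))$objective
    expect_lte(fit$objective, best + 1e-6 * abs(best))
  }
})
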