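# small helper building a transcript table from raw block coordinates
tx_table <- function(ids, blocks, gene_id = "g", seqname = "chr1") {
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = ids,
    seqname = seqname,
    strand = "+",
    blocks = lapply(blocks, function(b) {
      cbind(start = b[, 1], end = b[, 2])
    }),
    abundance = NA_real_,
    fpkm = NA_real_
  )
}

truth_two <- function() {
  tx_table(
    c("t1", "t2"),
    list(
      rbind(c(100, 200), c(500, 700), c(900, 1100)),
      rbind(c(100, 200), c(900, 1100))
    )
  )
}

test_that("outer boundaries are free but internal boundaries must match", {
  truth <- truth_two()
  # same internal structure as t1; different outer start and outer end
  pred <- tx_table("p1", list(rbind(c(130, 200), c(500, 700), c(900, 1050))))
  m <- match_transcripts(pred, truth)
  expect_true(m$truth$detected[1])
  expect_false(m$truth$detected[2])
  expect_true(m$predicted$matched[1])

  # a shifted internal boundary breaks the match
  pred2 <- tx_table("p2", list(rbind(c(100, 200), c(500, 690), c(900, 1100))))
  expect_false(any(match_transcripts(pred2, truth)$truth$detected))

  # a missing internal exon breaks the match
  pred3 <- tx_table("p3", list(rbind(c(100, 200), c(900, 1100))))
  m3 <- match_transcripts(pred3, truth)
  expect_false(m3$truth$detected[1])
  expect_true(m3$truth$detected[2]) # it is exactly t2
})

test_that("matching is one-to-one and empty predictions detect nothing", {
  truth <- truth_two()
  m0 <- match_transcripts(truth[0, ], truth)
  expect_false(any(m0$truth$detected))
  # two identical predictions can only consume one truth transcript
  pred <- tx_table(c("pa", "pb"), list(
    rbind(c(100, 200), c(900, 1100)),
    rbind(c(100, 200), c(900, 1100))
  ))
  m <- match_transcripts(pred, truth)
  expect_equal(sum(m$predicted$matched), 1)
})

test_that("single-exon transcripts from unrelated loci do not match", {
  truth <- tx_table("t1", list(rbind(c(100, 300))))
  pred_far <- tx_table("p1", list(rbind(c(9000, 9300))))
  expect_false(any(match_transcripts(pred_far, truth)$truth$detected))
  pred_near <- tx_table("p2", list(rbind(c(150, 400))))
  expect_true(any(match_transcripts(pred_near, truth)$truth$detected))
})

test_that("precision and recall are the matched fractions", {
  truth <- tx_table(
    paste0("t", 1:4),
    list(
      rbind(c(100, 200), c(500, 700)),
      rbind(c(100, 200), c(800, 900)),
      rbind(c(2000, 2200), c(2500, 2700)),
      rbind(c(4000, 4200), c(4500, 4700))
    ),
    gene_id = c("g1", "g1", "g2", "g3")
  )
  pred <- tx_table(
    paste0("p", 1:3),
    list(
      rbind(c(120, 200), c(510, 700)), # shifted junction: no match
      rbind(c(90, 200), c(800, 920)), # matches t2
      rbind(c(2000, 2200), c(2500, 2700)) # matches t3
    )
  )
  pr <- precision_recall(match_transcripts(pred, truth))
  pooled <- pr[pr$stratum == "all", ]
  expect_equal(pooled$precision, 2 / 3)
  expect_equal(pooled$recall, 1 / 2)
})

test_that("per-stratum counts reconcile with the pooled row", {
  truth <- truth_two()
  pred <- tx_table(c("p1", "p2"), list(
    rbind(c(100, 200), c(500, 700), c(900, 1100)),
    rbind(c(100, 250), c(600, 800))
  ))
  pr <- precision_recall(match_transcripts(pred, truth))
  strat <- pr[pr$stratum != "all", ]
  pooled <- pr[pr$stratum == "all", ]
  expect_equal(sum(strat$n_truth), pooled$n_truth)
  expect_equal(sum(strat$n_detected), pooled$n_detected)
  expect_equal(sum(strat$n_matched), pooled$n_matched)
  # exon-count stratification also reconciles
  pre <- precision_recall(match_transcripts(pred, truth), stratify_by = "exons")
  expect_equal(
    sum(pre$n_truth[pre$stratum != "all"]),
    pre$n_truth[pre$stratum == "all"]
  )
})

test_that("matching is invariant under translation of the whole locus", {
  truth <- truth_two()
  pred <- tx_table("p1", list(rbind(c(130, 200), c(500, 700), c(900, 1050))))
  shift <- function(tbl, by) {
    tbl$blocks <- lapply(tbl$blocks, function(b) b + by)
    tbl
  }
  m0 <- precision_recall(match_transcripts(pred, truth))
  m1 <- precision_recall(match_transcripts(shift(pred, 1e6), shift(truth, 1e6)))
  expect_equal(m0$precision, m1$precision)
  expect_equal(m0$recall, m1$recall)
})
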