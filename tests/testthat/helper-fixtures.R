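# Independent oracles and shared fixtures for the test suite. Everything here
# deliberately avoids the package's own formulas and graph machinery wherever
# it serves as a reference: effective lengths are counted by brute-force
# sliding, candidate isoforms by direct chain enumeration over junctions, and
# optimal objectives by generic convex minimisation over the full path design.

# count read-start positions assigned to a bin by actually sliding a window
# over the concatenated exon sequence and recording which exons it touches
brute_force_effective_length <- function(bin_lens, L) {
  M <- sum(bin_lens)
  if (M < L) return(0L)
  cum <- cumsum(bin_lens)
  n_ok <- 0L
  for (s in 1:(M - L + 1)) {
    e <- s + L - 1
    first <- which(cum >= s)[1]
    last <- which(cum >= e)[1]
    if (first == 1 && last == length(bin_lens)) n_ok <- n_ok + 1L
  }
  n_ok
}

# the five-exon worked-example gene: all exons longer than the read
fig_gene <- function() {
  gene_model(
    data.frame(
      start = c(0, 400, 800, 1200, 1600),
      end = c(300, 700, 1100, 1500, 1900)
    ),
    gene_id = "fig", seqname = "chrF"
  )
}

fig_junctions <- function() {
  rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 4), c(3, 5))
}

# variant with exon 3 shorter than the read (multi-exon bins appear)
fig_gene_short3 <- function() {
  gene_model(
    data.frame(
      start = c(0, 400, 800, 900, 1300),
      end = c(300, 700, 850, 1200, 1600)
    ),
    gene_id = "figc", seqname = "chrF"
  )
}

# random small gene + junction set for property tests
random_gene_instance <- function(n_exons = NULL, L = 50, p_junction = 0.6,
                                 min_len = 20, max_len = 3 * 50) {
  n <- if (is.null(n_exons)) sample(2:6, 1) else n_exons
  lens <- sample(min_len:max_len, n, replace = TRUE)
  gaps <- sample(30:120, n, replace = TRUE)
  starts <- cumsum(c(0, head(lens, -1) + head(gaps, -1)))
  gene <- gene_model(data.frame(start = starts, end = starts + lens))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_junction
  jn <- pairs[keep, , drop = FALSE]
  adjacent <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  jn <- unique(rbind(jn[, c(1, 2), drop = FALSE], adjacent))
  list(gene = gene, junctions = jn, L = L)
}

# all junction-consistent exon chains of length >= one read: the candidate
# isoforms, enumerated directly (independently of the bin graph)
chain_isoforms <- function(gene, junctions, L) {
  n <- gene$n
  lens <- gene$exons$length
  succ <- lapply(seq_len(n), function(e) sort(junctions[junctions[, 1] == e, 2]))
  out <- list()
  grow <- function(chain) {
    if (sum(lens[chain]) >= L) out[[length(out) + 1L]] <<- chain
    for (f in succ[[chain[length(chain)]]]) grow(c(chain, f))
  }
  for (e in seq_len(n)) grow(e)
  out
}

# brute-force solution of the penalised problem over the full path design
oracle_solve <- function(graph, counts, lambda, n_starts = 2) {
  paths <- enumerate_paths(graph)
  stopifnot(!attr(paths, "overflow"))
  nv <- nrow(graph$vertices)
  U <- t(vapply(paths, function(p) {
    v <- numeric(nv)
    v[setdiff(p, c(graph$s, graph$t))] <- 1
    v
  }, numeric(nv)))
  y <- as.numeric(counts_vector(graph, counts))
  l <- graph$vertices$eff_len
  fn <- function(th) {
    d <- l * as.vector(crossprod(U, th))
    sum(d - y * log(d + 1e-12)) + lambda * sum(th)
  }
  gr <- function(th) {
    d <- l * as.vector(crossprod(U, th))
    as.vector(U %*% (l * (1 - y / (d + 1e-12)))) + lambda
  }
  best <- Inf
  best_th <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- rep(c(0.1, 1)[s %% 2 + 1], nrow(U))
    o <- optim(th0, fn, gr,
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = 3000, factr = 1e2, pgtol = 1e-12)
    )
    if (o$value < best) {
      best <- o$value
      best_th <- o$par
    }
  }
  list(value = best, theta = best_th, paths = paths, design = U)
}

# mutually-exclusive-exon recovery fixture: isoforms 1-2-4 (major, 3:1) and
# 1-3-4 (minor); abundances scaled so the expected total read count is n_reads
mex_instance <- function(n_reads = 1e4, L = 100) {
  gene <- gene_model(
    data.frame(start = c(0, 300, 1300, 2300), end = c(150, 1100, 2100, 2450)),
    gene_id = "mex", seqname = "chrM"
  )
  junctions <- rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4))
  u <- n_reads / (4 * (1100 - L + 1))
  list(
    gene = gene, junctions = junctions, L = L,
    isoforms = list(
      list(exons = c(1L, 2L, 4L), abundance = 3 * u),
      list(exons = c(1L, 3L, 4L), abundance = u)
    )
  )
}

# minimal SAM writer for hand-constructed alignment records
write_test_sam <- function(file, records, seqname = "chrT", seqlen = 10000L) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", seqname, seqlen),
    records
  ), file)
  file
}

sam_record <- function(qname, pos, cigar, seqname = "chrT") {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  qlen <- sum(vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    if (grepl("[MIS=X]$", o)) n else 0L
  }, integer(1)))
  sprintf(
    "%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
    qname, seqname, pos, cigar, strrep("A", max(qlen, 1))
  )
}
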