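test_that("Pearson correlation with t-test p matches closed forms", {
  x <- 1:6
  lin <- pearsonWithP(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-12)
  expect_equal(pearsonWithP(x, -x)$r, -1)
  # r = 0.9 at n = 6: t = 0.9 * sqrt(4 / 0.19), df = 4
  # construct a vector with exactly r = 0.9 against x
  set.seed(1)
  e <- residuals(lm(rnorm(6) ~ x))
  e <- e / sqrt(sum(e^2))
  xs <- scale(x)[, 1]; xs <- xs / sqrt(sum(xs^2))
  y9 <- 0.9 * xs + sqrt(1 - 0.81) * e
  res <- pearsonWithP(x, y9)
  expect_equal(res$r, 0.9, tolerance = 1e-10)
  t_oracle <- 0.9 * sqrt((6 - 2) / (1 - 0.81))   # t = 4.129, df = 4
  p_oracle <- 2 * pt(t_oracle, df = 4, lower.tail = FALSE)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_equal(p_oracle, 0.01449, tolerance = 1e-3)
  # zero variance is flagged, not propagated
  z <- pearsonWithP(rep(1, 6), 1:6)
  expect_false(z$ok)
  expect_true(is.na(z$r))
  expect_error(pearsonWithP(1:2, 1:2), "n >= 3")
})

test_that("cis candidates use a strict 100 kb gap with overlap as distance 0", {
  ann <- toyAnnotation(data.frame(
    id = c("lnc1", "lnc2", "lnc3", "gA", "gB", "gC"),
    biotype = c("lncRNA", "lncRNA", "lncRNA", "coding", "coding", "coding"),
    start = c(1000, 500000, 800000, 90000, 600001, 790000),
    end = c(2000, 500999, 801000, 95000, 601000, 800500),
    strand = c("+", "+", "+", "+", "+", "+")))
  cand <- findCisCandidates(ann, c("lnc1", "lnc2", "lnc3"),
                            c("gA", "gB", "gC"))
  key <- paste(cand$lnc_id, cand$gene_id)
  # lnc1 -> gA: gap 90000 - 2000 - 1 = 87999 < 100000
  expect_true("lnc1 gA" %in% key)
  expect_identical(cand$distance_bp[key == "lnc1 gA"], 87999L)
  # lnc2 -> gB: gap = 600001 - 500999 - 1 = 99001 < 1e5; to gC gap > 1e5
  expect_true("lnc2 gB" %in% key)
  expect_false("lnc2 gC" %in% key)
  # lnc3 overlaps gC: distance 0
  expect_identical(cand$distance_bp[key == "lnc3 gC"], 0L)
  # a gap of exactly 100000 is excluded (strict less-than)
  ann2 <- toyAnnotation(data.frame(
    id = c("lncX", "gX"), biotype = c("lncRNA", "coding"),
    start = c(1, 100101), end = c(100, 100200), strand = c("+", "+")))
  expect_identical(nrow(findCisCandidates(ann2, "lncX", "gX")), 0L)
  ann3 <- toyAnnotation(data.frame(
    id = c("lncX", "gX"), biotype = c("lncRNA", "coding"),
    start = c(1, 100100), end = c(100, 100200), strand = c("+", "+")))
  expect_identical(findCisCandidates(ann3, "lncX", "gX")$distance_bp, 99999L)
})

test_that("interval distance agrees with a per-bp scan on random pairs", {
  set.seed(31)
  for (i in 1:200) {
    s1 <- sample(1:2000, 1); e1 <- s1 + sample(0:500, 1)
    s2 <- sample(1:2000, 1); e2 <- s2 + sample(0:500, 1)
    ann <- toyAnnotation(data.frame(
      id = c("l", "g"), biotype = c("lncRNA", "coding"),
      start = c(s1, s2), end = c(e1, e2), strand = c("+", "-")))
    d <- GenomicRanges::distance(ann["l"], ann["g"], ignore.strand = TRUE)
    expect_identical(as.integer(d), as.integer(gapByBpScan(s1, e1, s2, e2)))
  }
})

test_that("antisense candidates require overlap and opposite strand", {
  ann <- toyAnnotation(data.frame(
    id = c("l1", "l2", "l3", "g1", "g2", "g3"),
    biotype = rep(c("lncRNA", "coding"), each = 3),
    start = c(100, 1000, 5000, 300, 1100, 6000),
    end = c(500, 1500, 5400, 900, 1600, 6500),
    strand = c("-", "+", "-", "+", "+", "+")))
  cand <- findAntisenseCandidates(ann, c("l1", "l2", "l3"),
                                  c("g1", "g2", "g3"))
  key <- paste(cand$lnc_id, cand$gene_id)
  expect_true("l1 g1" %in% key)       # overlap + opposite strand
  expect_false("l2 g2" %in% key)      # same strand overlap
  expect_false("l3 g3" %in% key)      # opposite strand, disjoint
})

test_that("duplex score matches brute force and its closed-form minimum", {
  set.seed(37)
  mrna <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  window40 <- substr(mrna, 41, 80)
  lnc <- paste0(strrep("A", 30), revcomp(window40), strrep("A", 30))
  expect_equal(duplexScore(lnc, mrna, window = 40), -80)
  # brute-force oracle on smaller sequences / window
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
    expect_equal(duplexScore(a, b, window = 10),
                 duplexBruteForce(a, b, 10))
  }
  # unrelated random 200-mers essentially never reach a perfect duplex
  scores <- replicate(20, {
    a <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    duplexScore(a, b, window = 40)
  })
  expect_true(all(scores > -80))
  # symmetric under swapping sequences (with the reverse-complement roles)
  a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_equal(duplexScore(a, b, 20), duplexScore(b, a, 20))
  expect_error(duplexScore("ACGT", a, 40), "window")
})

test_that("target assignment gates on |r| > 0.9 with p < 0.05 and dedupes by mode", {
  ann <- toyAnnotation(data.frame(
    id = c("lncA", "lncB", "gene1", "gene2"),
    biotype = c("lncRNA", "lncRNA", "coding", "coding"),
    start = c(1000, 20000, 1200, 500000),
    end = c(1999, 21000, 2200, 501000),
    strand = c("-", "+", "+", "+")))
  base <- c(1, 2, 3, 4, 5, 6)
  expr <- rbind(
    lncA = base,
    lncB = c(1.05, 2.1, 2.9, 4.2, 4.9, 6.1),
    gene1 = base * 2 + 1,            # perfectly correlated with lncA
    gene2 = c(6, 5, 4, 3, 2, 1))     # anti-correlated with lncA
  colnames(expr) <- paste0("s", 1:6)
  pairs <- assignTargets(ann, c("lncA", "lncB"), c("gene1", "gene2"), expr)
  key <- paste(pairs$lnc_id, pairs$gene_id)
  # lncA overlaps gene1 on the opposite strand: antisense wins over cis
  expect_identical(pairs$mode[key == "lncA gene1"], "antisense")
  # negative correlation also passes the |r| gate
  expect_identical(pairs$mode[key == "lncA gene2"], "trans")
  expect_true(all(abs(pairs$r) > 0.9 & pairs$p < 0.05))
  expect_false(any(duplicated(key)))
  # weak correlation is dropped even for structural candidates
  expr2 <- expr
  expr2["gene1", ] <- c(3, 1, 4, 1, 5, 2)
  pairs2 <- assignTargets(ann, c("lncA", "lncB"), c("gene1", "gene2"), expr2)
  expect_false("lncA gene1" %in% paste(pairs2$lnc_id, pairs2$gene_id))
})

test_that("shrinking the cis window never adds cis pairs", {
  sim <- do.call(simulateExperiment, c(list(seed = 41), smallSimParams))
  lnc_ids <- names(sim$records)[sim$records$biotype == "lncRNA"]
  gene_ids <- names(sim$records)[sim$records$biotype == "coding"]
  wide <- findCisCandidates(sim$records, lnc_ids, gene_ids,
                            runConfig(cis_window_bp = 100000L))
  narrow <- findCisCandidates(sim$records, lnc_ids, gene_ids,
                              runConfig(cis_window_bp = 30000L))
  expect_true(all(paste(narrow$lnc_id, narrow$gene_id) %in%
                  paste(wide$lnc_id, wide$gene_id)))
  expect_true(all(narrow$distance_bp < 30000))
  expect_true(all(wide$distance_bp < 100000))
})

test_that("emitted pairs satisfy their mode's structural predicate", {
  sim <- do.call(simulateExperiment, c(list(seed = 43), smallSimParams))
  run <- runPipeline(sim = sim, write = FALSE, gene_sets = list())
  pairs <- run$pairs
  gr <- sim$records
  for (i in seq_len(nrow(pairs))) {
    l <- gr[pairs$lnc_id[i]]; g <- gr[pairs$gene_id[i]]
    d <- GenomicRanges::distance(l, g, ignore.strand = TRUE)
    if (pairs$mode[i] == "cis") expect_lt(d, 100000)
    if (pairs$mode[i] == "antisense") {
      expect_identical(as.integer(d), 0L)
      expect_false(as.character(GenomicRanges::strand(l)) ==
                   as.character(GenomicRanges::strand(g)))
    }
  }
})
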