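test_that("low-count filter applies the 5/2 both-group mean rule", {
  cnt <- rbind(coding_low = c(4, 5, 5, 4, 5, 5),   # means 4.67 in both groups
               coding_one = c(15, 0, 0, 0, 0, 0),  # means 5 and 0
               coding_ok = c(10, 10, 10, 10, 10, 10))
  le <- toyLayer(cnt)
  kept <- rownames(filterLowCounts(le))
  expect_identical(kept, c("coding_one", "coding_ok"))

  lnc <- toyLayer(rbind(l1 = c(2, 2, 2, 1, 1, 1),   # means 2 and 1
                        l2 = c(1, 1, 1, 1, 1, 1)), layer = "lncRNA")
  expect_identical(rownames(filterLowCounts(lnc)), "l1")
  expect_error(
    filterLowCounts(le, biotype_of = c(coding_low = "coding",
                                       coding_one = "weird",
                                       coding_ok = "coding")),
    "biotype")
})

test_that("filtering never enlarges the transcript set and keeps order", {
  set.seed(1)
  cnt <- matrix(rpois(600, 4), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  le <- toyLayer(cnt)
  kept <- filterLowCounts(le)
  expect_lte(nrow(kept), nrow(le))
  expect_identical(rownames(kept),
                   rownames(le)[rownames(le) %in% rownames(kept)])
})

test_that("TMM factors: identical columns give 1, geometric mean is 1", {
  cnt <- matrix(rep(c(10, 20, 30, 5), 6), 4, 6)
  rownames(cnt) <- paste0("g", 1:4)
  expect_equal(unname(tmmFactors(cnt)), rep(1, 6))
  set.seed(2)
  cnt2 <- matrix(rnbinom(1200, mu = 50, size = 10), 200, 6)
  rownames(cnt2) <- paste0("g", 1:200)
  f <- tmmFactors(cnt2)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_error(tmmFactors(cbind(cnt2, 0)), "all-zero")
})

test_that("TMM agrees with the edgeR reference implementation", {
  set.seed(3)
  cnt <- matrix(rnbinom(200 * 4, mu = exp(runif(200, 2, 6)), size = 5),
                200, 4)
  cnt[, 2] <- rnbinom(200, mu = 2 * rowMeans(cnt[, -2]), size = 5)
  rownames(cnt) <- paste0("g", 1:200)
  ref <- which.max(colSums(cnt))
  ours <- tmmFactors(cnt)
  theirs <- edgeR::calcNormFactors(cnt, method = "TMM", refColumn = ref)
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
  # a pure depth difference needs no composition correction
  set.seed(4)
  base <- matrix(rnbinom(200 * 2, mu = exp(runif(200, 2, 6)), size = 20),
                 200, 2)
  cnt3 <- cbind(base[, 1], rbinom(200, base[, 1], 0.5))
  rownames(cnt3) <- paste0("g", 1:200)
  f3 <- tmmFactors(cnt3)
  expect_equal(unname(f3[1] / f3[2]), 1, tolerance = 0.05)
})

test_that("exact test: balanced equal counts give p = 1, zero rows are inert", {
  cnt <- rbind(flat = c(20, 20, 20, 20, 20, 20),
               zero = c(0, 0, 0, 0, 0, 0),
               bg1 = c(50, 52, 48, 51, 49, 50),
               bg2 = c(30, 29, 31, 30, 30, 30))
  de <- nbExactTest(toyLayer(cnt), dispersion = 0.1,
                    norm_factors = setNames(rep(1, 6), colnames(toyLayer(cnt))))
  expect_equal(de$p[de$id == "flat"], 1)
  expect_equal(de$p[de$id == "zero"], 1)
  expect_equal(de$log2fc[de$id == "zero"], 0)
})

test_that("zero dispersion reduces the exact test to the binomial split", {
  # equal library sizes by construction; one 1-vs-1 comparison
  cnt <- rbind(g = c(10, 0), bg = c(95, 105))
  colnames(cnt) <- c("s1", "c1")
  de <- nbExactTest(cnt, group = c("stress", "control"), dispersion = 0,
                    norm_factors = c(s1 = 1, c1 = 1))
  oracle <- dbinom(0, 10, 0.5) + dbinom(10, 10, 0.5)
  expect_equal(de$p[de$id == "g"], oracle, tolerance = 1e-12)
})

test_that("exact test p-values agree with edgeR on a fixed-dispersion fixture", {
  set.seed(5)
  cnt <- matrix(rnbinom(300 * 6, mu = 100, size = 10), 300, 6)
  cnt[1:20, 1:3] <- rnbinom(60, mu = 400, size = 10)
  rownames(cnt) <- paste0("g", 1:300)
  colnames(cnt) <- paste0("s", 1:6)
  grp <- rep(c("stress", "control"), each = 3)
  ours <- nbExactTest(cnt, grp, dispersion = 0.1,
                      norm_factors = setNames(rep(1, 6), colnames(cnt)))
  y <- edgeR::DGEList(cnt, group = factor(grp, c("control", "stress")))
  y$samples$norm.factors <- 1
  et <- edgeR::exactTest(y, dispersion = 0.1)
  # same statistic family; different tie-handling conventions leave
  # small-p cases essentially identical
  expect_gt(cor(log10(ours$p), log10(et$table$PValue)), 0.99)
  expect_equal(cor(ours$log2fc, et$table$logFC), 1, tolerance = 1e-3)
})

test_that("common-dispersion CML recovers the simulation truth", {
  set.seed(6)
  for (phi in c(0.05, 0.2)) {
    cnt <- matrix(rnbinom(2000 * 6, mu = 80, size = 1 / phi), 2000, 6)
    est <- estimateCommonDispersion(cnt, rep(c("stress", "control"), 3))
    expect_equal(est, phi, tolerance = 0.1)
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-12)
  }
})

test_that("DE calling applies the layer-specific FDR/p rules strictly", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    log2fc = c(1.2, 1.0, -1.5, 1.2),
                    p = c(0.001, 0.0001, 0.03, 0.3),
                    fdr = c(0.04, 0.001, 0.2, 0.6))
  m <- callDE(rec, "mRNA")
  # c fails the mRNA FDR rule (fdr = 0.2) even though p = 0.03
  expect_identical(m$status, c("up", "ns", "ns", "ns"))
  # |log2FC| exactly 1 is not DE (strict inequality)
  expect_identical(m$status[m$id == "b"], "ns")
  circ <- callDE(rec, "circRNA")
  # circRNA uses the raw-p rule: c is down despite fdr = 0.2
  expect_identical(circ$status, c("up", "ns", "down", "ns"))
  mi <- callDE(rec, "miRNA")
  expect_identical(mi$status, circ$status)
  lnc <- callDE(rec, "lncRNA")
  expect_identical(lnc$status, m$status)
})

test_that("PCA separates groups under a strong planted effect", {
  sim <- simulateExperiment(
    seed = 21,
    annotation_params = list(n_coding = 200, n_lnc = 10, n_mirna = 5,
                             n_circ = 5),
    truth_params = list(n_cis_pairs = 0, n_antisense_pairs = 0,
                        n_trans_pairs = 0, n_modules_lnc = 0,
                        n_modules_circ = 0, n_modules_common = 0,
                        n_single_de = c(mRNA = 40), de_effect = 4))
  pc <- pcaSamples(sim$layers$mRNA)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  pc1 <- pc$coords[, 1]
  gap <- min(pc1[pc$group == "stress"]) > max(pc1[pc$group == "control"]) ||
         min(pc1[pc$group == "control"]) > max(pc1[pc$group == "stress"])
  expect_true(gap)
  # identical samples land on identical coordinates
  cnt <- matrix(rep(c(10, 30, 50, 5), 6), 4, 6)
  rownames(cnt) <- paste0("g", 1:4)
  pc2 <- pcaSamples(toyLayer(cnt))
  expect_equal(pc2$coords[1, ], pc2$coords[2, ], tolerance = 1e-9)
})
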