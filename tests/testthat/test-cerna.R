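test_that("seed sites are found and classified like the canonical let-7 site", {
  # let-7a: UGAGGUAGUAGGUUGUAUAGUU; nt 2-8 = GAGGUAG
  let7 <- "TGAGGTAGTAGGTTGTATAGTT"
  utr <- paste0("AAAAA", "CTACCTCA", "AAAAA")
  sites <- findSeedSites(let7, utr, "let7", "t1")
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$site_class, "8mer")
  expect_identical(sites$utr_position, 7L)  # 6mer core starts after the m8 base
  # 7mer-m8: match to nt 2-8 but no A opposite nt 1
  expect_identical(findSeedSites(let7, "AACTACCTCG")$site_class, "7mer-m8")
  # 7mer-A1: core plus A, no m8 match
  expect_identical(findSeedSites(let7, "AGTACCTCAG")$site_class, "7mer-A1")
  # bare 6mer core
  expect_identical(findSeedSites(let7, "GGTACCTCGG")$site_class, "6mer")
  # no core match
  expect_identical(nrow(findSeedSites(let7, "AAAAAAAAGGGG")), 0L)
  # tandem sites are both reported
  two <- findSeedSites(let7, strrep("CTACCTCA", 2))
  expect_identical(nrow(two), 2L)
  expect_identical(two$utr_position, c(2L, 10L))
  expect_error(findSeedSites("ACGTACG", utr), "at least 8")
})

test_that("target sets respect the site-class ordering", {
  sites <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    target_id = c("tA", "tB", "tA", "tC"),
    site_class = c("8mer", "6mer", "7mer-m8", "7mer-A1"),
    utr_position = c(1L, 5L, 9L, 2L))
  sets <- mirnaTargetSets(sites)   # default min class 7mer-m8
  expect_identical(sets$m1, "tA")  # tB only has a 6mer
  expect_identical(sets$m2, "tA")
  expect_null(sets$m3)
  all_sets <- mirnaTargetSets(sites, min_class = "6mer")
  expect_setequal(all_sets$m1, c("tA", "tB"))
  expect_length(mirnaTargetSets(sites[0, ]), 0L)
})

test_that("the miRNA co-expression gate is strict at -0.9", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_true(coexpressionGate(x, -0.95 * x + rnorm(6, 0, 1e-9))$pass)
  expect_false(coexpressionGate(x, x)$pass)          # positive r
  g <- coexpressionGate(rep(1, 6), x)
  expect_false(g$pass)
  expect_identical(g$reason, "zero variance")
  # exactly -0.9 fails the strict inequality
  set.seed(47)
  e <- residuals(lm(rnorm(6) ~ x)); e <- e / sqrt(sum(e^2))
  xs <- scale(x)[, 1]; xs <- xs / sqrt(sum(xs^2))
  y <- -0.9 * xs + sqrt(1 - 0.81) * e
  expect_equal(coexpressionGate(x, y)$r, -0.9, tolerance = 1e-12)
  expect_false(coexpressionGate(x, y)$pass)
})

test_that("hypergeometric shared-miRNA test equals exhaustive enumeration", {
  expect_equal(hypergeomSharedTest(c("m1", "m2", "m3"),
                                   c("m1", "m2", "m3", "m4"), 10),
               7 / 210, tolerance = 1e-12)
  expect_equal(hyperEnumeration(10, 3, 4, 3), 7 / 210, tolerance = 1e-12)
  # k = 0 is the certain event
  expect_equal(hypergeomSharedTest(c("a"), c("b"), 10), 1)
  # a miRNA-universal sponge is never surprising
  expect_equal(hypergeomSharedTest(paste0("m", 1:8), paste0("m", 1:3), 8), 1)
  set.seed(53)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    a <- paste0("m", sample(N, K))
    b <- paste0("m", sample(N, n))
    k <- length(intersect(a, b))
    expect_equal(hypergeomSharedTest(a, b, N),
                 hyperEnumeration(N, K, n, k), tolerance = 1e-12)
  }
  expect_error(hypergeomSharedTest(paste0("m", 1:5), paste0("m", 1:5), 3),
               "universe")
})

test_that("network construction applies every gate and the degree semantics", {
  # 5 miRNAs all hitting sponges A (mRNA) and B (lncRNA); C shares nothing
  mirs <- paste0("m", 1:5)
  tsets <- c(setNames(lapply(mirs, function(m) c("A", "B")), mirs),
             list(m9 = "C"))
  n <- 6
  base <- c(1, 2, 3, 4, 5, 6)
  expr <- rbind(
    A = base, B = base + 0.01 * c(1, -1, 1, -1, 1, -1),
    C = c(2, 1, 4, 3, 6, 5),
    do.call(rbind, setNames(lapply(seq_along(mirs), function(i)
      7 - base + 0.001 * i), mirs)),
    m9 = 7 - c(2, 1, 4, 3, 6, 5))
  rownames(expr)[4:8] <- mirs
  colnames(expr) <- paste0("s", 1:n)
  types <- c(A = "mRNA", B = "lncRNA", C = "mRNA")
  net <- buildCeRNANetwork(tsets, expr, types, universe_n = 20)
  ed <- as.data.frame(networkEdges(net))
  expect_identical(nrow(ed), 1L)
  expect_identical(sort(c(ed$node_a, ed$node_b)), c("A", "B"))
  expect_identical(ed$n_shared, 5L)
  nodes <- as.data.frame(networkNodes(net))
  expect_identical(nodes$degree[nodes$id == "A"], 5L)
  expect_identical(nodes$degree[nodes$id == "B"], 5L)
  expect_true(all(nodes$hub[nodes$id %in% c("A", "B")]))
  # degree identity: sponge degrees sum to 2x shared miRNAs over edges
  sponge <- nodes[nodes$type != "miRNA", ]
  expect_identical(sum(sponge$degree), 2L * sum(ed$n_shared))
  comp <- networkComposition(net)
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp["miRNA"]), 5 / 7)
})

test_that("edges need positive sponge correlation and a significant overlap", {
  tsets <- list(m1 = c("A", "B"))
  base <- c(1, 2, 3, 4, 5, 6)
  expr <- rbind(A = base, B = 7 - base, m1 = 7 - base + 0.01)
  colnames(expr) <- paste0("s", 1:6)
  types <- c(A = "mRNA", B = "lncRNA")
  # B anti-correlates with A -> r_ab < 0 -> no edge (m1 gates pass for A only)
  net <- buildCeRNANetwork(tsets, expr, types, universe_n = 30)
  expect_identical(nrow(networkEdges(net)), 0L)
  # universe too small -> hypergeometric p >= 0.05 -> no edge
  expr2 <- rbind(A = base, B = base + 0.001, m1 = 7 - base)
  colnames(expr2) <- paste0("s", 1:6)
  net2 <- buildCeRNANetwork(tsets, expr2, types, universe_n = 10)
  expect_identical(nrow(networkEdges(net2)), 0L)
  net3 <- buildCeRNANetwork(tsets, expr2, types, universe_n = 30)
  expect_identical(nrow(networkEdges(net3)), 1L)
  expect_lt(networkEdges(net3)$hyper_p[1], 0.05)
})

test_that("mRNA partition into lncRNA-specific and common is a partition", {
  ed <- S4Vectors::DataFrame(
    node_a = c("g1", "g1", "g2"), type_a = rep("mRNA", 3),
    node_b = c("l1", "c1", "l2"),
    type_b = c("lncRNA", "circRNA", "lncRNA"),
    shared_mirnas = "m1", n_shared = 1L, r_ab = 0.99, hyper_p = 0.01)
  nodes <- S4Vectors::DataFrame(
    id = c("g1", "g2", "l1", "l2", "c1"),
    type = c("mRNA", "mRNA", "lncRNA", "lncRNA", "circRNA"),
    degree = 1L, edge_degree = 1L, hub = FALSE)
  net <- new("CeRNANetwork", nodes = nodes, edges = ed, universe_n = 10L)
  part <- specificVsCommon(net)
  expect_identical(part$common, "g1")
  expect_identical(part$lnc_only, "g2")
  expect_length(intersect(part$common, part$lnc_only), 0L)
})

test_that("stored edge evidence re-validates against the raw inputs", {
  sim <- do.call(simulateExperiment, c(list(seed = 59), smallSimParams))
  run <- runPipeline(sim = sim, write = FALSE, gene_sets = list())
  ed <- as.data.frame(networkEdges(run$network))
  for (i in seq_len(nrow(ed))) {
    expect_equal(cor(run$expr[ed$node_a[i], ], run$expr[ed$node_b[i], ]),
                 ed$r_ab[i], tolerance = 1e-12)
    for (m in strsplit(ed$shared_mirnas[i], ",")[[1]]) {
      for (t in c(ed$node_a[i], ed$node_b[i])) {
        s <- findSeedSites(sim$sequences$mirnas[[m]],
                           sim$sequences$utrs[[t]])
        expect_true(any(s$site_class %in% c("7mer-m8", "8mer")))
        expect_lt(cor(run$expr[m, ], run$expr[t, ]), -0.9)
      }
    }
  }
})
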