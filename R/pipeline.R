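#' Generate synthetic gene-set collections for a simulated run
#'
#' Random coding-gene sets plus a few sets deliberately enriched in the
#' planted differentially expressed genes, so ORA/GSEA have signal to
#' find.
#'
#' @param records Annotation `GRanges`.
#' @param truth Ground truth from [plantTruth()].
#' @param n_random,n_enriched Set counts.
#' @param set_size Members per set.
#' @param seed RNG seed.
#' @return Named list of gene sets.
#' @export
generateGeneSets <- function(records, truth, n_random = 20L,
                             n_enriched = 3L, set_size = 30L, seed = 1L) {
  set.seed(seed + 4L)
  coding <- names(records)[records$biotype == "coding"]
  de_coding <- intersect(names(truth$planted_de), coding)
  sets <- list()
  for (i in seq_len(n_random))
    sets[[sprintf("random_%02d", i)]] <- sample(coding, set_size)
  for (i in seq_len(n_enriched))
    sets[[sprintf("stress_response_%02d", i)]] <-
      unique(c(sample(de_coding, min(set_size * 2 %/% 3, length(de_coding))),
               sample(coding, set_size %/% 3)))
  sets
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> differential expression
#' per layer -> novel lncRNA calling -> cis/trans/antisense target
#' assignment -> ceRNA network -> enrichment, writes every stage table
#' plus a JSON run manifest (config hash, seed, per-file checksums,
#' per-stage counts in the order DEM, DEMI, DEL, DEC), and returns the
#' in-memory results.
#'
#' @param config A [runConfig()].
#' @param outdir Output directory.
#' @param seed Seed for the simulation (defaults to `config$seed`).
#' @param sim A pre-built [simulateExperiment()] result; when `NULL` one
#'   is simulated with `sim_params`.
#' @param sim_params Overrides forwarded to [simulateExperiment()].
#' @param gene_sets Named list of gene sets for enrichment; synthetic
#'   sets are generated for simulated runs when `NULL`.
#' @param n_perm GSEA permutation count (pipeline default 200 keeps the
#'   stage quick; raise for final analyses).
#' @param write When `FALSE`, nothing is written and the manifest carries
#'   no checksums.
#' @return List with all stage results (`layers`, `de`, `novelty`,
#'   `pairs`, `network`, `partition`, `enrichment`, `pca`, `manifest`,
#'   `truth` when simulated).
#' @export
runPipeline <- function(config = runConfig(), outdir = NULL,
                        seed = config$seed, sim = NULL,
                        sim_params = list(), gene_sets = NULL,
                        n_perm = 200L, write = !is.null(outdir)) {
  if (is.null(sim))
    sim <- do.call(simulateExperiment, c(list(seed = seed), sim_params))
  records <- sim$records
  truth <- sim$truth
  .stageLog("simulate", "%d transcripts, %d layers",
            length(records), length(sim$layers))
  # --- differential expression per layer ---
  de <- list(); filtered <- list(); expr_rows <- list()
  for (layer in names(sim$layers)) {
    res <- runDiffExpr(sim$layers[[layer]], config)
    de[[layer]] <- res$de
    filtered[[layer]] <- res$filtered
    expr_rows[[layer]] <- logCpmMatrix(layerCounts(res$filtered),
                                       res$lib_sizes)
    .stageLog("diffexpr", "%s: %d kept, %d DE (dispersion %.3f)", layer,
              nrow(res$de), sum(res$de$status != "ns"), res$dispersion)
  }
  expr <- do.call(rbind, unname(expr_rows))
  de_ids <- lapply(de, function(d) d$id[d$status != "ns"])
  pca <- if ("mRNA" %in% names(filtered)) pcaSamples(filtered$mRNA) else NULL
  # --- novel lncRNA discovery ---
  novelty <- NULL
  lnc_density <- NULL
  if ("lncRNA" %in% names(filtered)) {
    lnc_seqs <- sim$sequences$transcripts
    lnc_seqs <- lnc_seqs[names(lnc_seqs) %in% rownames(filtered$lncRNA)]
    novelty <- callNovelty(lnc_seqs, sim$known_ids, config)
    lnc_density <- expressionDensityByClass(filtered$lncRNA, novelty,
                                            de$lncRNA)
    .stageLog("novelty", "%d novel / %d known lncRNAs",
              sum(novelty$novelty == "novel"),
              sum(novelty$novelty == "known"))
  }
  # --- lncRNA target assignment ---
  pairs <- NULL
  if (all(c("mRNA", "lncRNA") %in% names(de))) {
    pairs <- assignTargets(records, de_ids$lncRNA, de_ids$mRNA, expr,
                           config, sequences = sim$sequences$transcripts)
    .stageLog("regulation", "%d lncRNA-gene pairs (%s)", nrow(pairs),
              paste(names(table(pairs$mode)), table(pairs$mode),
                    collapse = ", ", sep = ":"))
  }
  # --- ceRNA network ---
  network <- NULL; partition <- NULL
  if (all(c("mRNA", "miRNA") %in% names(de))) {
    demi <- de_ids$miRNA
    mir_seqs <- sim$sequences$mirnas[intersect(demi,
                                               names(sim$sequences$mirnas))]
    sponge_ids <- unlist(de_ids[intersect(c("mRNA", "lncRNA", "circRNA"),
                                          names(de_ids))], use.names = FALSE)
    utrs <- sim$sequences$utrs[intersect(sponge_ids,
                                         names(sim$sequences$utrs))]
    sites <- seedSiteTable(mir_seqs, utrs)
    tsets <- mirnaTargetSets(sites, config$min_site_class)
    types <- stats::setNames(records$biotype, names(records))
    types <- types[sponge_ids]
    types[types == "coding"] <- "mRNA"
    network <- buildCeRNANetwork(tsets, expr, types, config,
                                 universe_n = max(length(demi), 1L))
    partition <- specificVsCommon(network)
    .stageLog("cerna", "%d edges, %d nodes; %d lnc-specific / %d common mRNAs",
              nrow(networkEdges(network)), nrow(networkNodes(network)),
              length(partition$lnc_only), length(partition$common))
  }
  # --- enrichment: DEMs, lncRNA targets, ceRNA-partition sets ---
  enrichment <- list()
  if ("mRNA" %in% names(de)) {
    if (is.null(gene_sets))
      gene_sets <- generateGeneSets(records, truth, seed = seed)
    universe <- de$mRNA$id
    enrichment$ora_dems <- ora(de_ids$mRNA, universe, gene_sets)
    enrichment$gsea_dems <- gseaTable(rankMetric(de$mRNA), gene_sets,
                                      n_perm = n_perm, seed = seed)
    if (!is.null(pairs) && nrow(pairs))
      enrichment$ora_lnc_targets <-
        ora(intersect(unique(pairs$gene_id), universe), universe, gene_sets)
    if (!is.null(partition)) {
      if (length(partition$lnc_only))
        enrichment$ora_lnc_specific <-
          ora(intersect(partition$lnc_only, universe), universe, gene_sets)
      if (length(partition$common))
        enrichment$ora_common <-
          ora(intersect(partition$common, universe), universe, gene_sets)
    }
    .stageLog("enrichment", "%d collections tested", length(enrichment))
  }
  # --- outputs + manifest ---
  tables <- stats::setNames(de, paste0("de_", names(de)))
  if (!is.null(novelty)) tables$novelty <- novelty
  if (!is.null(pairs)) tables$regulatory_pairs <- pairs
  for (nm in names(enrichment)) tables[[paste0("enrichment_", nm)]] <-
    enrichment[[nm]]
  stage_counts <- list(
    transcripts_in = length(records),
    filtered = vapply(filtered, nrow, 0L),
    DEM = length(de_ids$mRNA %||% character(0)),
    DEMI = length(de_ids$miRNA %||% character(0)),
    DEL = length(de_ids$lncRNA %||% character(0)),
    DEC = length(de_ids$circRNA %||% character(0)),
    regulatory_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    cerna_edges = if (is.null(network)) 0L else nrow(networkEdges(network)))
  manifest <- list(config_hash = .md5OfObject(unclass(config)),
                   seed = seed, stage_counts = stage_counts)
  if (write) {
    paths <- writeResults(tables, network, outdir,
                          summary = list(seed = seed,
                                         stage_counts = stage_counts))
    manifest$checksums <- as.list(tools::md5sum(sort(unname(paths))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(layers = sim$layers, filtered = filtered, de = de,
       de_ids = de_ids, expr = expr, novelty = novelty,
       lnc_density = lnc_density, pairs = pairs, network = network,
       partition = partition, enrichment = enrichment, pca = pca,
       manifest = manifest, truth = truth, records = records,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a pipeline run against its planted ground truth
#'
#' Computes per-structure sensitivity (and precision where a false call
#' is well defined): planted DE recovery per layer and empirical FDR,
#' cis / antisense / trans pair recovery, ceRNA edge and triplet
#' recovery with the count of unplanted (false) edges, and novelty
#' recall / precision.
#'
#' @param run Result of [runPipeline()] (or an equivalent list).
#' @param truth Ground truth; defaults to `run$truth`.
#' @return Named list of rates in `[0, 1]` plus `false_edges` (a count).
#' @export
validateAgainstTruth <- function(run, truth = run$truth) {
  if (is.null(truth)) stop("no ground truth available")
  rep <- list()
  planted <- names(truth$planted_de)
  for (layer in names(run$de)) {
    d <- run$de[[layer]]
    p_layer <- intersect(planted, d$id)
    called <- d$id[d$status != "ns"]
    rep[[paste0("de_sensitivity_", layer)]] <-
      if (length(p_layer)) length(intersect(called, p_layer)) /
        length(p_layer) else NA_real_
    rep[[paste0("de_fdr_", layer)]] <-
      if (length(called)) length(setdiff(called, planted)) /
        length(called) else 0
  }
  pairKey <- function(df, a = 1L, b = 2L) paste(df[[a]], df[[b]])
  if (!is.null(run$pairs)) {
    found <- pairKey(run$pairs[, c("lnc_id", "gene_id")])
    for (mode in c("cis", "antisense", "trans")) {
      pl <- truth[[paste0("planted_", mode, "_pairs")]]
      rep[[paste0(mode, "_recovery")]] <- if (nrow(pl))
        mean(pairKey(pl) %in% found) else NA_real_
    }
  }
  if (!is.null(run$network)) {
    ed <- as.data.frame(networkEdges(run$network))
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    found_e <- if (nrow(ed)) ekey(ed$node_a, ed$node_b) else character(0)
    exp_e <- ekey(truth$expected_edges$node_a, truth$expected_edges$node_b)
    rep$cerna_edge_recovery <- if (length(exp_e))
      mean(exp_e %in% found_e) else NA_real_
    rep$false_edges <- sum(!found_e %in% exp_e)
    tr <- truth$planted_triplets
    if (nrow(tr)) {
      hit <- vapply(seq_len(nrow(tr)), function(i) {
        k <- ekey(tr$sponge_a[i], tr$sponge_b[i])
        j <- match(k, found_e)
        !is.na(j) && tr$mirna_id[i] %in%
          strsplit(ed$shared_mirnas[j], ",", fixed = TRUE)[[1L]]
      }, TRUE)
      rep$cerna_triplet_recovery <- mean(hit)
    }
  }
  if (!is.null(run$novelty)) {
    nov_called <- run$novelty$transcript_id[run$novelty$novelty == "novel"]
    nov_true <- intersect(truth$novel_lnc_ids, run$novelty$transcript_id)
    rep$novelty_recall <- if (length(nov_true))
      mean(nov_true %in% nov_called) else NA_real_
    rep$novelty_precision <- if (length(nov_called))
      mean(nov_called %in% nov_true) else NA_real_
  }
  rep
}
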