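#' Generate a synthetic single-chromosome transcript annotation
#'
#' Lays out coding genes on a 250 kb grid along one synthetic chromosome
#' and places lncRNAs in three structural classes: a configurable
#' fraction strictly within 100 kb of a coding gene (cis candidates), a
#' fraction overlapping a coding gene on the opposite strand (antisense
#' candidates), and the remainder distal (> 100 kb from every coding
#' gene). miRNA loci and circRNA host spans are placed downstream of the
#' gene grid. A `novel_fraction` of the lncRNAs is flagged unannotated
#' (novel); every lncRNA is at least 200 nt. Deterministic under `seed`.
#'
#' @param n_coding,n_lnc,n_mirna,n_circ Transcript counts per biotype.
#' @param cis_fraction,antisense_fraction Fractions of lncRNAs placed as
#'   cis / antisense candidates (counts are rounded).
#' @param novel_fraction Fraction of lncRNAs flagged novel.
#' @param seed RNG seed.
#' @return List with `records` (annotation `GRanges`) and `skeleton`
#'   (cis/antisense candidate pair tables, distal lncRNA ids,
#'   `novel_lnc_ids`).
#' @export
generateAnnotation <- function(n_coding = 2000, n_lnc = 300,
                               n_mirna = 50, n_circ = 100,
                               cis_fraction = 0.25,
                               antisense_fraction = 0.15,
                               novel_fraction = 0.5, seed = 1L) {
  stopifnot(n_coding >= 0, n_lnc >= 0, n_mirna >= 0, n_circ >= 0)
  set.seed(seed)
  spacing <- 250000L
  rec <- list()
  addRec <- function(id, gene, biotype, start, end, strand, known) {
    rec[[length(rec) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gene, biotype = biotype,
      start = as.integer(start), end = as.integer(end), strand = strand,
      known = known, stringsAsFactors = FALSE)
  }
  gene_start <- gene_end <- integer(0)
  if (n_coding > 0) {
    gene_start <- 100000L + (seq_len(n_coding) - 1L) * spacing
    gene_len <- sample(2000:8000, n_coding, replace = TRUE)
    gene_end <- gene_start + gene_len - 1L
    gene_strand <- sample(c("+", "-"), n_coding, replace = TRUE)
    for (i in seq_len(n_coding))
      addRec(sprintf("gene%04d", i), sprintf("G%04d", i), "coding",
             gene_start[i], gene_end[i], gene_strand[i], TRUE)
  }
  n_cis <- if (n_coding > 0) round(n_lnc * cis_fraction) else 0L
  n_anti <- if (n_coding > 0) round(n_lnc * antisense_fraction) else 0L
  n_dist <- n_lnc - n_cis - n_anti
  host <- if (n_coding > 0) sample(n_coding, min(n_lnc, n_coding))
          else integer(0)
  cis_tab <- anti_tab <- data.frame(lnc_id = character(0),
                                    gene_id = character(0))
  distal_ids <- character(0)
  li <- 0L
  nextLnc <- function() { li <<- li + 1L; sprintf("lnc%04d", li) }
  for (j in seq_len(n_cis)) {
    g <- host[j]
    gap <- sample(5000:90000, 1L)
    len <- sample(300:2000, 1L)
    id <- nextLnc()
    addRec(id, paste0("G", id), "lncRNA", gene_start[g] - gap - len,
           gene_start[g] - gap - 1L, sample(c("+", "-"), 1L), TRUE)
    cis_tab <- rbind(cis_tab, data.frame(lnc_id = id,
                                         gene_id = sprintf("gene%04d", g)))
  }
  for (j in seq_len(n_anti)) {
    g <- host[n_cis + j]
    off <- sample(100:500, 1L)
    len <- sample(300:1500, 1L)
    id <- nextLnc()
    addRec(id, paste0("G", id), "lncRNA", gene_start[g] + off,
           min(gene_start[g] + off + len - 1L, gene_end[g] + 200L),
           if (gene_strand[g] == "+") "-" else "+", TRUE)
    anti_tab <- rbind(anti_tab, data.frame(lnc_id = id,
                                           gene_id = sprintf("gene%04d", g)))
  }
  for (j in seq_len(n_dist)) {
    len <- sample(300:2000, 1L)
    id <- nextLnc()
    if (n_coding > 0) {
      g <- host[min(n_cis + n_anti + j, length(host))]
      start <- gene_start[g] - 125000L
    } else start <- 100000L + (j - 1L) * spacing
    addRec(id, paste0("G", id), "lncRNA", start, start + len - 1L,
           sample(c("+", "-"), 1L), TRUE)
    distal_ids <- c(distal_ids, id)
  }
  tail_pos <- (if (n_coding > 0) max(gene_end) else 100000L) + 300000L
  for (i in seq_len(n_mirna))
    addRec(sprintf("mir%03d", i), sprintf("Gmir%03d", i), "miRNA",
           tail_pos + i * 1000L, tail_pos + i * 1000L + 21L,
           sample(c("+", "-"), 1L), TRUE)
  circ_pos <- tail_pos + (n_mirna + 10L) * 1000L
  for (i in seq_len(n_circ))
    addRec(sprintf("circ%03d", i), sprintf("Gcirc%03d", i), "circRNA",
           circ_pos + i * 2000L, circ_pos + i * 2000L + 499L,
           sample(c("+", "-"), 1L), TRUE)
  tab <- do.call(rbind, rec)
  lnc_ids <- tab$transcript_id[tab$biotype == "lncRNA"]
  novel <- sample(lnc_ids, round(length(lnc_ids) * novel_fraction))
  tab$known[tab$transcript_id %in% novel] <- FALSE
  gr <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(tab$start, tab$end), strand = tab$strand,
    transcript_id = tab$transcript_id, gene_id = tab$gene_id,
    biotype = tab$biotype, known = tab$known)
  names(gr) <- tab$transcript_id
  list(records = gr,
       skeleton = list(cis_candidates = cis_tab,
                       antisense_candidates = anti_tab,
                       distal_lnc = distal_ids,
                       novel_lnc_ids = sort(novel)))
}

#' Plant ground-truth differential expression and regulatory structure
#'
#' Chooses, from the structural candidates of [generateAnnotation()],
#' the cis / antisense / trans lncRNA-gene pairs and the ceRNA modules
#' that will actually be planted, assigns signed log2 effects (strong
#' `structure_effect` for structure members so the 0.9 correlation gate
#' is reachable at n = 6, `de_effect` for stand-alone DE transcripts,
#' within the wide fold-change range such studies report), shared
#' latent-factor
#' memberships (sponges positive, miRNAs negative), baseline means and
#' the miRNA target map. ceRNA modules come in three kinds: mRNA+lncRNA,
#' mRNA+circRNA, and common modules where one mRNA shares two miRNAs
#' with both a lncRNA and a circRNA sponge.
#'
#' @param records,skeleton Output of [generateAnnotation()].
#' @param n_cis_pairs,n_antisense_pairs,n_trans_pairs Planted pair counts.
#' @param n_modules_lnc,n_modules_circ,n_modules_common ceRNA module
#'   counts.
#' @param n_single_de Named vector: additional stand-alone DE transcripts
#'   per layer.
#' @param de_effect,structure_effect Absolute planted log2 effects.
#' @param seed RNG seed.
#' @return A ground-truth list (`planted_de`, pair tables,
#'   `planted_sites`, `planted_triplets`, `expected_edges`,
#'   `novel_lnc_ids`, `latent`, `baseline`).
#' @export
plantTruth <- function(records, skeleton,
                       n_cis_pairs = 20, n_antisense_pairs = 15,
                       n_trans_pairs = 15, n_modules_lnc = 10,
                       n_modules_circ = 6, n_modules_common = 4,
                       n_single_de = c(mRNA = 130, miRNA = 10,
                                       lncRNA = 6, circRNA = 5),
                       de_effect = 2, structure_effect = 6, seed = 1L) {
  set.seed(seed + 1L)
  bt <- stats::setNames(records$biotype, names(records))
  ids_of <- function(b) names(bt)[bt == b]
  effects <- numeric(0)
  latent <- data.frame(id = character(0), factor = character(0),
                       sign = numeric(0))
  used <- character(0)
  take <- function(pool, n) {
    pool <- setdiff(pool, used)
    if (length(pool) < n) stop("candidate pool exhausted; reduce planting")
    out <- if (length(pool) == 1L) pool else sample(pool, n)
    used <<- c(used, out)
    out
  }
  addLatent <- function(ids, fac, signs) {
    latent <<- rbind(latent, data.frame(id = ids, factor = fac,
                                        sign = signs))
  }
  plantPair <- function(lnc, gene, fac) {
    s <- sample(c(-1, 1), 1L)
    effects[c(lnc, gene)] <<- s * structure_effect
    addLatent(c(lnc, gene), fac, c(1, 1))
  }
  n_cis_pairs <- min(n_cis_pairs, nrow(skeleton$cis_candidates))
  n_antisense_pairs <- min(n_antisense_pairs,
                           nrow(skeleton$antisense_candidates))
  cis_rows <- if (n_cis_pairs)
    skeleton$cis_candidates[sample(nrow(skeleton$cis_candidates),
                                   n_cis_pairs), ] else
    skeleton$cis_candidates[0, ]
  anti_rows <- if (n_antisense_pairs)
    skeleton$antisense_candidates[sample(nrow(skeleton$antisense_candidates),
                                         n_antisense_pairs), ] else
    skeleton$antisense_candidates[0, ]
  used <- c(used, cis_rows$lnc_id, cis_rows$gene_id,
            anti_rows$lnc_id, anti_rows$gene_id)
  for (i in seq_len(nrow(cis_rows)))
    plantPair(cis_rows$lnc_id[i], cis_rows$gene_id[i], paste0("cis", i))
  for (i in seq_len(nrow(anti_rows)))
    plantPair(anti_rows$lnc_id[i], anti_rows$gene_id[i], paste0("anti", i))
  trans_lnc <- take(skeleton$distal_lnc, n_trans_pairs)
  trans_gene <- take(ids_of("coding"), n_trans_pairs)
  trans_rows <- data.frame(lnc_id = trans_lnc, gene_id = trans_gene)
  for (i in seq_len(n_trans_pairs))
    plantPair(trans_rows$lnc_id[i], trans_rows$gene_id[i], paste0("trans", i))
  # ceRNA modules
  sites <- list()
  triplets <- data.frame(mirna_id = character(0), sponge_a = character(0),
                         sponge_b = character(0))
  edges <- data.frame(node_a = character(0), node_b = character(0))
  plantModule <- function(mirnas, sponges, fac) {
    s <- sample(c(-1, 1), 1L)   # whole module direction is random
    effects[sponges] <<- s * structure_effect
    effects[mirnas] <<- -s * structure_effect
    addLatent(sponges, fac, rep(1, length(sponges)))
    addLatent(mirnas, fac, rep(-1, length(mirnas)))
    for (m in mirnas) sites[[m]] <<- sponges
  }
  mod <- 0L
  for (kind in c(rep("lnc", n_modules_lnc), rep("circ", n_modules_circ),
                 rep("common", n_modules_common))) {
    mod <- mod + 1L
    fac <- paste0("mod", mod)
    a <- take(ids_of("coding"), 1L)
    if (kind == "common") {
      m <- take(ids_of("miRNA"), 2L)
      b <- take(ids_of("lncRNA"), 1L)
      ci <- take(ids_of("circRNA"), 1L)
      plantModule(m, c(a, b, ci), fac)
      triplets <- rbind(triplets,
        data.frame(mirna_id = rep(m, 2L),
                   sponge_a = a, sponge_b = rep(c(b, ci), each = 2L)))
      edges <- rbind(edges, data.frame(node_a = a, node_b = c(b, ci)))
    } else {
      m <- take(ids_of("miRNA"), 1L)
      b <- take(ids_of(if (kind == "lnc") "lncRNA" else "circRNA"), 1L)
      plantModule(m, c(a, b), fac)
      triplets <- rbind(triplets, data.frame(mirna_id = m, sponge_a = a,
                                             sponge_b = b))
      edges <- rbind(edges, data.frame(node_a = a, node_b = b))
    }
  }
  # stand-alone DE transcripts (the layer sensitivity is measured here)
  single <- character(0)
  for (layer in names(n_single_de)) {
    pool <- ids_of(layerBiotype(layer))
    ids <- take(pool, min(n_single_de[[layer]], length(setdiff(pool, used))))
    effects[ids] <- sample(c(-1, 1), length(ids), TRUE) * de_effect
    single <- c(single, ids)
  }
  # baseline (geometric-mean) expression per transcript
  all_ids <- names(records)
  base <- stats::setNames(stats::rlnorm(length(all_ids), log(30), 1.2),
                          all_ids)
  base[bt == "miRNA"] <- stats::rlnorm(sum(bt == "miRNA"), log(200), 1)
  structural <- unique(latent$id)
  base[structural] <- stats::rlnorm(length(structural), log(400), 0.3)
  base[structural[bt[structural] == "miRNA"]] <-
    stats::rlnorm(sum(bt[structural] == "miRNA"), log(2000), 0.2)
  base[single] <- exp(stats::runif(length(single), log(100), log(1000)))
  list(planted_de = effects,
       planted_cis_pairs = cis_rows,
       planted_antisense_pairs = anti_rows,
       planted_trans_pairs = trans_rows,
       planted_sites = sites,
       planted_triplets = triplets,
       expected_edges = edges,
       single_de = single,
       novel_lnc_ids = skeleton$novel_lnc_ids,
       latent = latent,
       baseline = base)
}

#' Generate negative-binomial counts for every layer
#'
#' Per transcript and sample, counts are NB with mean
#' `mu = (lib_size_s / 5e5) * q * 2^(effect * (I(stress) - 1/2)) *
#' 2^(sign * z)`, where `q` is the transcript's baseline (geometric-mean)
#' expression, the planted effect is centred so the group-mean log2 ratio
#' equals the planted effect, and `z` is the sample value of the
#' transcript's shared latent factor (positive sign for co-expressed
#' sponges and lncRNA targets, negative for a module's miRNAs) with
#' standard deviation `latent_sd`. Dispersion 0 falls back to Poisson.
#'
#' @param records Annotation `GRanges`.
#' @param truth Ground truth from [plantTruth()].
#' @param n_per_group Replicates per group (3 vs 3 default).
#' @param dispersion NB dispersion (> 0; 0 allowed for the Poisson
#'   limit).
#' @param lib_sizes Library-size scalers, length `2 * n_per_group`;
#'   default 5e5 with +/-10% jitter.
#' @param latent_sd SD of the shared latent factor, log2 scale.
#' @param seed RNG seed.
#' @return Named list of [LayerExperiment-class] objects (one per layer
#'   present).
#' @export
generateCounts <- function(records, truth, n_per_group = 3L,
                           dispersion = 0.1, lib_sizes = NULL,
                           latent_sd = 1.5, seed = 1L) {
  stopifnot(dispersion >= 0)
  set.seed(seed + 2L)
  n <- 2L * n_per_group
  samples <- c(paste0("stress_", seq_len(n_per_group)),
               paste0("control_", seq_len(n_per_group)))
  group <- rep(c("stress", "control"), each = n_per_group)
  if (is.null(lib_sizes)) lib_sizes <- 5e5 * stats::runif(n, 0.9, 1.1)
  ids <- names(records)
  q <- truth$baseline[ids]
  eff <- truth$planted_de[ids]
  eff[is.na(eff)] <- 0
  isS <- group == "stress"
  # latent factor values per (factor, sample)
  facs <- unique(truth$latent$factor)
  z <- matrix(stats::rnorm(length(facs) * n, 0, latent_sd),
              length(facs), n, dimnames = list(facs, samples))
  lat_fac <- stats::setNames(truth$latent$factor, truth$latent$id)
  lat_sign <- stats::setNames(truth$latent$sign, truth$latent$id)
  log2mu <- matrix(log2(q), length(ids), n) +
    outer(eff, ifelse(isS, 0.5, -0.5)) +
    matrix(log2(lib_sizes / 5e5), length(ids), n, byrow = TRUE)
  has_lat <- ids %in% names(lat_fac)
  if (any(has_lat))
    log2mu[has_lat, ] <- log2mu[has_lat, , drop = FALSE] +
      lat_sign[ids[has_lat]] * z[lat_fac[ids[has_lat]], , drop = FALSE]
  mu <- 2^log2mu
  cnt <- if (dispersion > 0)
    matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
           nrow(mu), ncol(mu)) else
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  dimnames(cnt) <- list(ids, samples)
  out <- list()
  for (layer in .LAYERS) {
    sel <- records$biotype == layerBiotype(layer)
    if (!any(sel)) next
    out[[layer]] <- LayerExperiment(cnt[sel, , drop = FALSE], layer, group)
  }
  out
}

.randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate transcript, 3'UTR and mature miRNA sequences
#'
#' Mature miRNAs are 22-mers whose seed (nt 2-7) contains at least one C,
#' so the reverse-complement seed core always contains a G; non-target
#' 3'UTRs are drawn from the {A, C, T} alphabet and therefore provably
#' contain no seed site for any generated miRNA, while each planted
#' (miRNA, target) pair receives one exact 8mer site spliced into the
#' target's UTR. lncRNA transcript sequences are rejection-sampled to be
#' ORF-poor (longest-ORF fraction < 0.3 and Fickett score < 0.9 for the
#' novel ones); coding sequences for antisense partners carry a long ORF,
#' and a planted antisense lncRNA embeds the reverse complement of a
#' 40-mer of its partner so the duplex score is maximally stable.
#'
#' @param records Annotation `GRanges`.
#' @param truth Ground truth from [plantTruth()].
#' @param utr_len 3'UTR length (nt).
#' @param seed RNG seed.
#' @return List `transcripts`, `utrs`, `mirnas` (named character maps).
#' @export
generateSequences <- function(records, truth, utr_len = 300L, seed = 1L) {
  set.seed(seed + 3L)
  bt <- stats::setNames(records$biotype, names(records))
  len <- stats::setNames(GenomicRanges::width(records), names(records))
  # mature miRNAs: distinct seeds, each with a C in nt 2-7
  mir_ids <- names(bt)[bt == "miRNA"]
  mirnas <- character(0)
  seen <- character(0)
  for (m in mir_ids) {
    repeat {
      s <- .randSeq(22L)
      seedpart <- substr(s, 2L, 7L)
      if (grepl("C", seedpart, fixed = TRUE) && !seedpart %in% seen) break
    }
    seen <- c(seen, substr(s, 2L, 7L))
    mirnas[m] <- s
  }
  # lncRNA transcript sequences (novel ones screened to be non-coding-like)
  transcripts <- character(0)
  for (id in names(bt)[bt == "lncRNA"]) {
    L <- max(len[[id]], 200L)
    if (id %in% truth$novel_lnc_ids) {
      for (try in 1:50) {
        s <- .randSeq(L)
        if (orfCoverage(s) < 0.3 && fickettScore(s) < 0.9) break
      }
    } else s <- .randSeq(L)
    transcripts[id] <- s
  }
  # coding sequences for antisense partner genes: ATG + non-stop codons + stop
  .codingSeq <- function(L) {
    n_cod <- max(20L, floor(L * 0.8 / 3))
    non_stop <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1L, paste, collapse = ""),
      c("TAA", "TAG", "TGA"))
    orf <- paste0("ATG", paste(sample(non_stop, n_cod - 2L, TRUE),
                               collapse = ""), "TAA")
    lead <- max(0L, floor((L - nchar(orf)) / 2))
    lead <- lead - lead %% 3L + 1L   # keep the ORF out of frame 0 sometimes
    paste0(.randSeq(max(lead, 1L)), orf,
           .randSeq(max(L - nchar(orf) - max(lead, 1L), 1L)))
  }
  for (g in unique(truth$planted_antisense_pairs$gene_id))
    transcripts[g] <- .codingSeq(max(len[[g]], 600L))
  # embed the reverse complement of a partner 40-mer in each antisense lncRNA
  for (i in seq_len(nrow(truth$planted_antisense_pairs))) {
    lnc <- truth$planted_antisense_pairs$lnc_id[i]
    g <- truth$planted_antisense_pairs$gene_id[i]
    win <- substr(transcripts[[g]], 51L, 90L)
    s <- transcripts[[lnc]]
    pos <- min(101L, nchar(s) - 40L)
    transcripts[lnc] <- paste0(substr(s, 1L, pos - 1L), .revcompChr(win),
                               substr(s, pos + 40L, nchar(s)))
  }
  # 3'UTRs: G-free background, planted 8mer sites spliced in
  sponge_ids <- names(bt)[bt %in% c("coding", "lncRNA", "circRNA")]
  utrs <- stats::setNames(
    vapply(sponge_ids, function(id) .randSeq(utr_len, c("A", "C", "T")),
           ""), sponge_ids)
  target_of <- list()
  for (m in names(truth$planted_sites))
    for (t in truth$planted_sites[[m]])
      target_of[[t]] <- c(target_of[[t]], m)
  for (t in names(target_of)) {
    s <- utrs[[t]]
    pos <- 20L
    for (m in target_of[[t]]) {
      site <- paste0(.revcompChr(substr(mirnas[[m]], 2L, 8L)), "A")  # 8mer
      s <- paste0(substr(s, 1L, pos - 1L), site,
                  substr(s, pos + nchar(site), nchar(s)))
      pos <- pos + 30L
    }
    utrs[t] <- s
  }
  list(transcripts = transcripts, utrs = utrs, mirnas = mirnas)
}

#' Simulate a complete layered experiment with planted ground truth
#'
#' Convenience wrapper chaining [generateAnnotation()], [plantTruth()],
#' [generateCounts()] and [generateSequences()] under one seed.
#'
#' @param seed RNG seed (single source of randomness).
#' @param annotation_params,truth_params,count_params,sequence_params
#'   Named lists of overrides forwarded to the stage generators.
#' @return List `layers`, `records`, `sequences`, `known_ids`, `truth`,
#'   `seed`.
#' @export
simulateExperiment <- function(seed = 1L, annotation_params = list(),
                               truth_params = list(),
                               count_params = list(),
                               sequence_params = list()) {
  ann <- do.call(generateAnnotation,
                 c(annotation_params, list(seed = seed)))
  truth <- do.call(plantTruth,
                   c(list(records = ann$records, skeleton = ann$skeleton),
                     truth_params, list(seed = seed)))
  layers <- do.call(generateCounts,
                    c(list(records = ann$records, truth = truth),
                      count_params, list(seed = seed)))
  seqs <- do.call(generateSequences,
                  c(list(records = ann$records, truth = truth),
                    sequence_params, list(seed = seed)))
  known <- names(ann$records)[ann$records$known]
  list(layers = layers, records = ann$records, sequences = seqs,
       known_ids = known, truth = truth, seed = seed)
}

#' Write a simulated experiment to disk
#'
#' Emits one counts TSV per layer, the GTF annotation, transcript / 3'UTR
#' / miRNA FASTA files, the known-id list and `ground_truth.json`.
#'
#' @param sim Output of [simulateExperiment()].
#' @param outdir Output directory.
#' @return Invisibly, the written paths.
#' @export
writeSimulation <- function(sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (layer in names(sim$layers)) {
    p <- file.path(outdir, paste0("counts_", layer, ".tsv"))
    writeCounts(sim$layers[[layer]], p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "annotation.gtf")
  writeAnnotation(sim$records, p); paths <- c(paths, p)
  for (nm in c("transcripts", "utrs", "mirnas")) {
    p <- file.path(outdir, paste0(nm, ".fa"))
    writeFasta(sim$sequences[[nm]], p); paths <- c(paths, p)
  }
  p <- file.path(outdir, "known_ids.txt")
  writeLines(sim$known_ids, p); paths <- c(paths, p)
  truth <- sim$truth
  truth$planted_de <- as.list(truth$planted_de)
  truth$baseline <- NULL
  p <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
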