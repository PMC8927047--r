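#' Read gene sets from a GMT file
#'
#' @param path GMT path: term id, description, then member ids,
#'   tab-separated.
#' @return Named list of character vectors; term descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric)
#'
#' Per term, the upper-tail hypergeometric probability of observing at
#' least `k` query genes among the term's `K` universe members when `n`
#' genes are drawn from a universe of `N`; Benjamini-Hochberg adjusted
#' across terms.
#'
#' @param query_ids Query gene ids (must be a subset of the universe).
#' @param universe_ids Universe gene ids.
#' @param gene_sets Named list of term member vectors.
#' @return data.frame with `term_id`, `k`, `K`, `n`, `N`, `gene_ratio`,
#'   `p`, `fdr`, ordered by `p`.
#' @export
ora <- function(query_ids, universe_ids, gene_sets) {
  query_ids <- unique(query_ids); universe_ids <- unique(universe_ids)
  off <- setdiff(query_ids, universe_ids)
  if (length(off))
    stop("query id(s) outside the universe: ", paste(off, collapse = ", "))
  N <- length(universe_ids); n <- length(query_ids)
  if (!length(gene_sets))
    return(data.frame(term_id = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      gene_ratio = numeric(0), p = numeric(0),
                      fdr = numeric(0)))
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), universe_ids)
    K <- length(members)
    k <- length(intersect(members, query_ids))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               gene_ratio = if (n > 0L) k / n else NA_real_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out[order(out$p, out$term_id), ]
}

#' GSEA enrichment score: the weighted Kolmogorov-Smirnov walk
#'
#' Genes are ranked by decreasing metric (ties broken by id); walking
#' down the list, hits increment the running sum proportionally to
#' `|metric|^weight_p` (normalized over the set's hits) and misses
#' decrement it by `1/(N - K)`. The enrichment score is the maximum
#' deviation from zero, signed.
#'
#' @param ranked Named numeric vector: gene -> ranking metric.
#' @param gene_set Character vector of member ids.
#' @param weight_p Metric weighting exponent (1 = classic weighted KS,
#'   0 = unweighted).
#' @return List `es` and `running` (the walk, in ranked order).
#' @export
gseaScore <- function(ranked, gene_set, weight_p = 1) {
  ord <- order(-ranked, names(ranked))
  ids <- names(ranked)[ord]
  metric <- ranked[ord]
  hit <- ids %in% gene_set
  N <- length(ids); K <- sum(hit)
  if (K == 0L) stop("gene set has no member in the ranked list")
  w <- abs(metric)^weight_p
  inc <- numeric(N)
  wsum <- sum(w[hit])
  inc[hit] <- if (wsum > 0) w[hit] / wsum else 1 / K
  if (N > K) inc[!hit] <- -1 / (N - K)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = stats::setNames(running, ids))
}

#' Gene set enrichment analysis with a permutation null
#'
#' Computes the weighted KS enrichment score and a gene-set (label)
#' permutation null: random sets of the same size drawn from the ranked
#' genes. NES is the score divided by the mean |null score| of the same
#' sign; the p-value is the empirical same-sign tail (add-one smoothed).
#' Gene-set permutation is used because phenotype permutation is
#' degenerate at 3 vs 3 (only 10 distinct relabelings).
#'
#' @inheritParams gseaScore
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed (the scores are deterministic under it).
#' @return List `es`, `nes`, `p`, `n_more_extreme`, `size`.
#' @export
gsea <- function(ranked, gene_set, weight_p = 1, n_perm = 1000L,
                 seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- gseaScore(ranked, gene_set, weight_p)
  K <- sum(names(ranked) %in% gene_set)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    gseaScore(ranked, sample(names(ranked), K), weight_p)$es
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  n_extreme <- sum(abs(same) >= abs(obs$es))
  p <- (n_extreme + 1) / (length(same) + 1)
  list(es = obs$es, nes = nes, p = p, n_more_extreme = n_extreme, size = K)
}

#' GSEA over a collection of gene sets
#'
#' @inheritParams gsea
#' @param gene_sets Named list of member vectors; sets without overlap
#'   with the ranked list are dropped.
#' @return data.frame `term_id`, `size`, `es`, `nes`, `p`, `fdr`
#'   (BH across terms), `direction`.
#' @export
gseaTable <- function(ranked, gene_sets, weight_p = 1, n_perm = 1000L,
                      seed = 1L) {
  keep <- vapply(gene_sets, function(s) any(names(ranked) %in% s), TRUE)
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets))
    return(data.frame(term_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      fdr = numeric(0), direction = character(0)))
  rows <- lapply(seq_along(gene_sets), function(i) {
    g <- gsea(ranked, gene_sets[[i]], weight_p, n_perm, seed + i)
    data.frame(term_id = names(gene_sets)[i], size = g$size, es = g$es,
               nes = g$nes, p = g$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out$direction <- ifelse(out$es >= 0, "up", "down")
  out[order(out$p, out$term_id), ]
}

#' Signed significance ranking metric for GSEA
#'
#' `sign(log2FC) * -log10(max(p, 1e-300))`; deterministic tie order by
#' id is applied downstream when ranking.
#'
#' @param de A called DE table (columns `id`, `log2fc`, `p`).
#' @return Named numeric vector gene -> metric.
#' @export
rankMetric <- function(de) {
  stats::setNames(sign(de$log2fc) * -log10(pmax(de$p, 1e-300)), de$id)
}
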