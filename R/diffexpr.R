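#' Counts-per-million matrices
#'
#' @param counts Raw count matrix (transcripts x samples).
#' @param lib_sizes Effective library sizes; defaults to column sums.
#' @return CPM matrix of the same shape.
#' @export
cpmMatrix <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' @rdname cpmMatrix
#' @return `logCpmMatrix`: log2(CPM + 1) matrix, the expression scale used
#'   for every correlation and for PCA.
#' @export
logCpmMatrix <- function(counts, lib_sizes = colSums(counts)) {
  log2(cpmMatrix(counts, lib_sizes) + 1)
}

#' Remove lowly expressed transcripts
#'
#' A transcript is kept iff its group-wise mean raw count reaches the
#' biotype threshold (5 for coding, 2 for non-coding) in at least one
#' group; transcripts low in both groups are removed. The mean (rather
#' than the sum) makes the rule invariant to the number of replicates.
#'
#' @param x A [LayerExperiment-class].
#' @param biotype_of Optional named map transcript id -> biotype; defaults
#'   to the layer's own biotype for every transcript.
#' @param config A [runConfig()] carrying `filter_coding` /
#'   `filter_noncoding`.
#' @return The filtered `LayerExperiment` (row order preserved).
#' @export
filterLowCounts <- function(x, biotype_of = NULL, config = runConfig()) {
  cnt <- layerCounts(x)
  if (is.null(biotype_of))
    biotype_of <- stats::setNames(rep(layerBiotype(layerType(x)), nrow(cnt)),
                                  rownames(cnt))
  bt <- biotype_of[rownames(cnt)]
  if (anyNA(bt) || !all(bt %in% .BIOTYPES))
    stop("unknown biotype for transcript(s): ",
         paste(rownames(cnt)[is.na(bt) | !bt %in% .BIOTYPES], collapse = ", "))
  thr <- ifelse(bt == "coding", config$filter_coding, config$filter_noncoding)
  grp <- sampleGroups(x)
  m_stress <- rowMeans(cnt[, grp == "stress", drop = FALSE])
  m_ctrl <- rowMeans(cnt[, grp == "control", drop = FALSE])
  keep <- m_stress >= thr | m_ctrl >= thr
  x[keep, ]
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes TMM scaling factors against a reference sample (the
#' highest-depth sample by default), following the published algorithm:
#' gene-wise log2 expression ratios (M) and average log expression (A)
#' versus the reference, double trimming (30% on M, 5% on A by default),
#' and an inverse-asymptotic-variance weighted mean of the surviving M
#' values. Factors are rescaled to geometric mean 1.
#'
#' @param x A [LayerExperiment-class] or count matrix.
#' @param logratio_trim Fraction trimmed from each tail of the M values.
#' @param abs_trim Fraction trimmed from each tail of the A values.
#' @param ref_column Reference sample (index or name); default the
#'   highest-depth sample.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(x, logratio_trim = 0.30, abs_trim = 0.05,
                       ref_column = NULL) {
  cnt <- if (is(x, "LayerExperiment")) layerCounts(x) else as.matrix(x)
  if (ncol(cnt) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(cnt)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(cnt)[lib == 0], collapse = ", "))
  if (is.null(ref_column)) ref_column <- which.max(lib)
  if (is.character(ref_column)) ref_column <- match(ref_column, colnames(cnt))
  ref <- cnt[, ref_column]
  nR <- lib[ref_column]
  f <- vapply(seq_len(ncol(cnt)), function(j) {
    obs <- cnt[, j]; nO <- lib[j]
    use <- obs > 0 & ref > 0
    if (!any(use)) return(1)
    o <- obs[use]; r <- ref[use]
    logR <- log2((o / nO) / (r / nR))
    absE <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    if (!any(keep)) return(1)
    fj <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(fj) || fj <= 0) 1 else fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(cnt))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are scaled to a common (geometric-mean) effective library size
#' and rounded; the common dispersion maximizes the within-group
#' conditional log-likelihood (the distribution of each group's counts
#' given their sum, which for i.i.d. NB observations is free of the
#' group mean). To keep a handful of extremely variable transcripts
#' (e.g. strongly co-regulated ones) from inflating the shared estimate,
#' genes whose per-gene moment dispersion exceeds 10x the positive
#' median are set aside before fitting.
#'
#' @param counts Count matrix.
#' @param group Group label per sample.
#' @param lib_sizes Effective library sizes.
#' @param min_mean Minimum gene mean (common scale) to enter the fit.
#' @return A single non-negative dispersion estimate.
#' @export
estimateCommonDispersion <- function(counts, group,
                                     lib_sizes = colSums(counts),
                                     min_mean = 1) {
  lstar <- exp(mean(log(lib_sizes)))
  z <- round(sweep(counts, 2L, lstar / lib_sizes, "*"))
  groups <- unique(group)
  # per-gene moment screen for outlier (contaminated) transcripts
  mom <- rep(0, nrow(z)); mtot <- rowMeans(z)
  for (g in groups) {
    zg <- z[, group == g, drop = FALSE]
    if (ncol(zg) < 2L) next
    m <- rowMeans(zg)
    v <- .rowVars(zg)
    mom <- mom + ifelse(m > 0, (v - m) / pmax(m, 1)^2, 0) / length(groups)
  }
  med <- stats::median(mom[mom > 0 & mtot >= min_mean])
  cutoff <- if (is.finite(med) && med > 0) 10 * med else Inf
  use <- mtot >= min_mean & mom <= cutoff
  if (!any(use)) return(0)
  zu <- z[use, , drop = FALSE]
  negCondLogLik <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (g in groups) {
      zg <- zu[, group == g, drop = FALSE]
      n <- ncol(zg)
      if (n < 2L) next
      t <- rowSums(zg)
      ll <- ll + sum(rowSums(lgamma(zg + r))) - length(t) * n * lgamma(r) +
        sum(lgamma(n * r) - lgamma(t + n * r))
    }
    -ll
  }
  opt <- stats::optimize(negCondLogLik, lower = log(1e-6), upper = log(10))
  phi <- exp(opt$minimum)
  # boundary: likelihood monotone toward zero dispersion
  if (phi <= 1.1e-6 ||
      negCondLogLik(log(1e-6)) < opt$objective) return(0)
  phi
}

# row variances without a matrixStats dependency
.rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Conditional exact test on pseudo-equalized library totals: counts are
#' scaled to the geometric-mean effective library size, each group's sum
#' is formed, and the two-sided p-value is the probability mass of all
#' splits of the total whose conditional probability does not exceed that
#' of the observed split. Group sums are negative-binomially distributed
#' (a sum of n NB(mu, phi) variables is NB(n*mu, phi/n)); at dispersion 0
#' the conditional law reduces to the binomial split test.
#'
#' @param x A [LayerExperiment-class] or count matrix.
#' @param group Group labels (needed when `x` is a bare matrix).
#' @param dispersion Common NB dispersion; estimated by
#'   [estimateCommonDispersion()] when `NULL`.
#' @param norm_factors TMM factors; computed when `NULL`.
#' @param pseudocount Prior count (raw-count units at the average
#'   effective library size) added to group mean CPMs before the log2
#'   fold change.
#' @return data.frame with `id`, `mean_cpm_stress`, `mean_cpm_control`,
#'   `log2fc`, `p` and attribute `"dispersion"`.
#' @export
nbExactTest <- function(x, group = NULL, dispersion = NULL,
                        norm_factors = NULL, pseudocount = 0.5) {
  if (is(x, "LayerExperiment")) {
    cnt <- layerCounts(x)
    group <- sampleGroups(x)
  } else cnt <- as.matrix(x)
  if (is.null(group) || length(group) != ncol(cnt))
    stop("'group' must label every sample")
  if (!is.null(dispersion) && dispersion < 0)
    stop("dispersion must be non-negative")
  if (is.null(norm_factors)) norm_factors <- tmmFactors(cnt)
  lib <- colSums(cnt) * norm_factors
  if (is.null(dispersion))
    dispersion <- estimateCommonDispersion(cnt, group, lib)
  lstar <- exp(mean(log(lib)))
  pseudo <- sweep(cnt, 2L, lstar / lib, "*")
  isA <- group == "stress"
  nA <- sum(isA); nB <- sum(!isA)
  a <- round(rowSums(pseudo[, isA, drop = FALSE]))
  b <- round(rowSums(pseudo[, !isA, drop = FALSE]))
  p <- vapply(seq_len(nrow(cnt)), function(i)
    .exactNbPvalue(a[i], b[i], nA, nB, dispersion), numeric(1))
  cpm <- cpmMatrix(cnt, lib)
  mA <- rowMeans(cpm[, isA, drop = FALSE])
  mB <- rowMeans(cpm[, !isA, drop = FALSE])
  pc <- pseudocount * 1e6 / mean(lib)   # half a count, in CPM units
  lfc <- log2((mA + pc) / (mB + pc))
  lfc[a + b == 0] <- 0
  out <- data.frame(id = rownames(cnt), mean_cpm_stress = mA,
                    mean_cpm_control = mB, log2fc = lfc, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  out
}

# two-sided conditional NB p-value for an observed split (a, b) of t = a + b
.exactNbPvalue <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (phi < 1e-10) {
    pr <- stats::dbinom(k, t, nA / (nA + nB))
  } else {
    m <- t / (nA + nB)
    pr <- stats::dnbinom(k, size = nA / phi, mu = nA * m) *
          stats::dnbinom(t - k, size = nB / phi, mu = nB * m)
    s <- sum(pr)
    if (s <= 0) return(1)
    pr <- pr / s
  }
  pobs <- pr[a + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1), delegating to
#' [stats::p.adjust()] after validating the inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Layer-specific differential-expression calling
#'
#' mRNA and lncRNA are called on `|log2FC| > 1` (strict) and `FDR < 0.05`;
#' miRNA and circRNA on `|log2FC| > 1` and raw `p < 0.05`. The fold-change
#' sign sets up/down.
#'
#' @param records DE table from [nbExactTest()], with an `fdr` column
#'   (added here if absent).
#' @param layer Expression layer the table belongs to.
#' @param config A [runConfig()].
#' @return The table with `fdr` and `status` (`up`/`down`/`ns`) columns.
#' @export
callDE <- function(records, layer, config = runConfig()) {
  layer <- match.arg(layer, .LAYERS)
  if (is.null(records$fdr)) records$fdr <- bhAdjust(records$p)
  sig <- if (layer %in% c("mRNA", "lncRNA")) records$fdr < config$fdr_cut
         else records$p < config$p_cut
  de <- abs(records$log2fc) > config$lfc_cut & sig
  records$status <- ifelse(de & records$log2fc > 0, "up",
                    ifelse(de & records$log2fc < 0, "down", "ns"))
  records
}

#' Filter, normalize, test and call one expression layer
#'
#' @param x A [LayerExperiment-class] of raw counts.
#' @param config A [runConfig()].
#' @param biotype_of Optional transcript -> biotype map for filtering.
#' @param dispersion Optional fixed common dispersion.
#' @return List with the filtered `LayerExperiment` (`filtered`), its TMM
#'   factors (`norm_factors`), effective library sizes (`lib_sizes`), the
#'   called DE table (`de`) and the dispersion used.
#' @export
runDiffExpr <- function(x, config = runConfig(), biotype_of = NULL,
                        dispersion = NULL) {
  xf <- filterLowCounts(x, biotype_of, config)
  if (!nrow(xf)) stop("no transcripts survive filtering in layer ",
                      layerType(x))
  nf <- tmmFactors(xf)
  lib <- colSums(layerCounts(xf)) * nf
  de <- nbExactTest(xf, dispersion = dispersion, norm_factors = nf,
                    pseudocount = config$pseudocount)
  de <- callDE(de, layerType(x), config)
  de$layer <- layerType(x)
  list(filtered = xf, norm_factors = nf, lib_sizes = lib, de = de,
       dispersion = attr(de, "dispersion"))
}

#' Sample PCA on log2(CPM + 1)
#'
#' @param x A [LayerExperiment-class].
#' @param n_components Number of components to return.
#' @return List with `coords` (samples x components), `explained`
#'   (variance fractions, non-increasing) and the sample `group` labels.
#' @export
pcaSamples <- function(x, n_components = 2L) {
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  lib <- colSums(layerCounts(x)) * tmmFactors(x)
  m <- logCpmMatrix(layerCounts(x), lib)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       group = sampleGroups(x))
}
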