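#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite). Inputs are
#'   expected on the log2(CPM + 1) scale across all samples of both
#'   groups.
#' @return List with `r`, `p` and `ok`; zero variance in either vector is
#'   flagged (`ok = FALSE`, `r`/`p` NA) so callers skip the pair instead
#'   of propagating NaN.
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, ok = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, ok = TRUE)
}

# correlation matrix between rows of two expression matrices, with
# two-sided t p-values; zero-variance rows yield NA columns/rows
.corMatrixWithP <- function(a, b) {
  n <- ncol(a)
  sda <- apply(a, 1L, stats::sd)
  sdb <- apply(b, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(a), t(b)))
  r[sda == 0, ] <- NA
  r[, sdb == 0] <- NA
  rc <- pmin(pmax(r, -1), 1)
  tt <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[rc == 1 | rc == -1] <- 0
  list(r = r, p = p)
}

#' Cis-regulation candidates: DEL-DEM pairs within the genomic window
#'
#' Pairs every differentially expressed lncRNA with every differentially
#' expressed coding gene on the same chromosome whose interval gap is
#' strictly below `cis_window_bp` (100 kb default); overlapping intervals
#' have distance 0. Strand is ignored for proximity.
#'
#' @param annotation `GRanges` from [readAnnotation()].
#' @param del_ids,dem_ids Transcript ids of the DE lncRNAs / coding genes.
#' @param config A [runConfig()].
#' @return data.frame `lnc_id`, `gene_id`, `distance_bp`.
#' @export
findCisCandidates <- function(annotation, del_ids, dem_ids,
                              config = runConfig()) {
  lnc <- annotation[names(annotation) %in% del_ids]
  gen <- annotation[names(annotation) %in% dem_ids]
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      distance_bp = integer(0))
  if (!length(lnc) || !length(gen)) return(empty)
  hits <- GenomicRanges::findOverlaps(lnc, gen,
                                      maxgap = config$cis_window_bp - 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  d <- GenomicRanges::distance(lnc[S4Vectors::queryHits(hits)],
                               gen[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  data.frame(lnc_id = names(lnc)[S4Vectors::queryHits(hits)],
             gene_id = names(gen)[S4Vectors::subjectHits(hits)],
             distance_bp = as.integer(d), stringsAsFactors = FALSE)
}

#' Antisense candidates: opposite-strand overlapping DEL-DEM pairs
#'
#' @inheritParams findCisCandidates
#' @return data.frame `lnc_id`, `gene_id`, `overlap_bp`.
#' @export
findAntisenseCandidates <- function(annotation, del_ids, dem_ids) {
  lnc <- annotation[names(annotation) %in% del_ids]
  gen <- annotation[names(annotation) %in% dem_ids]
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      overlap_bp = integer(0))
  if (!length(lnc) || !length(gen)) return(empty)
  hits <- GenomicRanges::findOverlaps(lnc, gen, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  opp <- as.character(GenomicRanges::strand(lnc))[q] !=
         as.character(GenomicRanges::strand(gen))[s]
  q <- q[opp]; s <- s[opp]
  if (!length(q)) return(empty)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(lnc)[q],
                                           IRanges::ranges(gen)[s]))
  data.frame(lnc_id = names(lnc)[q], gene_id = names(gen)[s],
             overlap_bp = as.integer(ov), stringsAsFactors = FALSE)
}

#' Antisense duplex score (complementarity energy surrogate)
#'
#' Minimum, over all ungapped antiparallel window alignments, of the
#' summed pair scores: Watson-Crick pair -2, G.U wobble -1, mismatch +3.
#' Lower is more stable; a window that is the exact reverse complement of
#' its partner scores `-2 * window`. This is a documented surrogate for
#' minimum-free-energy duplex prediction: it ranks complementarity, it
#' does not model nearest-neighbor thermodynamics.
#'
#' @param lnc_seq,mrna_seq ACGT strings, each at least `window` long.
#' @param window Alignment window length (nt).
#' @return The minimum window score (numeric).
#' @export
duplexScore <- function(lnc_seq, mrna_seq, window = 40L) {
  .checkAcgt(lnc_seq); .checkAcgt(mrna_seq)
  n <- nchar(lnc_seq); m <- nchar(mrna_seq)
  if (n < window || m < window)
    stop("sequence shorter than the ", window,
         " nt window; use a smaller 'window'")
  code <- function(s) match(strsplit(s, "", fixed = TRUE)[[1L]],
                            c("A", "C", "G", "T"))
  a <- code(lnc_seq)
  # antiparallel pairing: reverse the mRNA, then score parallel diagonals
  b <- rev(code(mrna_seq))
  # pair score lookup: rows lnc base, cols mRNA base (A C G T)
  tab <- matrix(3, 4, 4)
  tab[cbind(c(1, 4, 3, 2), c(4, 1, 2, 3))] <- -2   # A-T T-A G-C C-G
  tab[cbind(c(3, 4), c(4, 3))] <- -1               # G-T / T-G wobble
  S <- matrix(tab[cbind(rep(a, times = m), rep(b, each = n))], n, m)
  best <- Inf
  for (d in (window - n):(m - window)) {
    i <- max(1L, 1L - d):min(n, m - d)       # a[i] pairs b[i + d]
    s <- S[cbind(i, i + d)]
    cs <- cumsum(s)
    wsum <- cs[window:length(s)] -
      c(0, cs)[1:(length(s) - window + 1L)]
    best <- min(best, min(wsum))
  }
  best
}

#' Assign coding-gene targets to differentially expressed lncRNAs
#'
#' Structural candidates (cis proximity, antisense overlap; all remaining
#' DEL x DEM pairs as trans candidates) are gated by Pearson correlation
#' across all pooled samples: a pair is emitted iff `|r| > corr_cut`
#' (0.9) and `p < p_cut` (0.05), both strict. Each (lncRNA, gene) pair is
#' reported once with mode priority antisense > cis > trans. Antisense
#' pairs are annotated with the duplex score when sequences are supplied
#' (and gated by `duplex_max` when configured).
#'
#' @param annotation `GRanges` annotation.
#' @param del_ids,dem_ids DE lncRNA / DE coding transcript ids.
#' @param expr Named-row matrix of log2(CPM + 1) values (all samples
#'   pooled) covering both id sets.
#' @param config A [runConfig()].
#' @param sequences Optional named sequence map for duplex scoring.
#' @param include_trans When `TRUE` (default) every DEL x DEM pair not
#'   already claimed as cis or antisense is a trans candidate; set
#'   `FALSE` to restrict the search to the structural modes.
#' @return data.frame of regulatory pairs: `lnc_id`, `gene_id`, `mode`,
#'   `distance_bp`, `duplex_score`, `r`, `p`.
#' @export
assignTargets <- function(annotation, del_ids, dem_ids, expr,
                          config = runConfig(), sequences = NULL,
                          include_trans = TRUE) {
  del_ids <- intersect(del_ids, rownames(expr))
  dem_ids <- intersect(dem_ids, rownames(expr))
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      mode = character(0), distance_bp = integer(0),
                      duplex_score = numeric(0), r = numeric(0),
                      p = numeric(0))
  if (!length(del_ids) || !length(dem_ids)) return(empty)
  cis <- findCisCandidates(annotation, del_ids, dem_ids, config)
  anti <- findAntisenseCandidates(annotation, del_ids, dem_ids)
  key <- function(df) paste(df$lnc_id, df$gene_id, sep = "\r")
  cand <- rbind(
    if (nrow(anti)) data.frame(lnc_id = anti$lnc_id, gene_id = anti$gene_id,
                               mode = "antisense", distance_bp = 0L),
    if (nrow(cis)) data.frame(lnc_id = cis$lnc_id, gene_id = cis$gene_id,
                              mode = "cis", distance_bp = cis$distance_bp))
  if (include_trans) {
    trans <- expand.grid(lnc_id = del_ids, gene_id = dem_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    trans$mode <- "trans"; trans$distance_bp <- NA_integer_
    cand <- rbind(cand, trans)
  }
  if (is.null(cand) || !nrow(cand)) return(empty)
  # mode priority antisense > cis > trans: keep first occurrence
  cand$mode <- factor(cand$mode, levels = c("antisense", "cis", "trans"))
  cand <- cand[order(key(cand), cand$mode), ]
  cand <- cand[!duplicated(key(cand)), ]
  cand$mode <- as.character(cand$mode)
  cp <- .corMatrixWithP(expr[del_ids, , drop = FALSE],
                        expr[dem_ids, , drop = FALSE])
  ij <- cbind(match(cand$lnc_id, del_ids), match(cand$gene_id, dem_ids))
  cand$r <- cp$r[ij]
  cand$p <- cp$p[ij]
  keep <- !is.na(cand$r) & abs(cand$r) > config$corr_cut &
    cand$p < config$p_cut
  out <- cand[keep, , drop = FALSE]
  out$duplex_score <- rep(NA_real_, nrow(out))
  if (!is.null(sequences) && nrow(out)) {
    is_anti <- out$mode == "antisense"
    for (i in which(is_anti)) {
      sl <- unname(sequences[out$lnc_id[i]])
      sg <- unname(sequences[out$gene_id[i]])
      if (!is.na(sl) && !is.na(sg) &&
          min(nchar(sl), nchar(sg)) >= config$duplex_window)
        out$duplex_score[i] <- duplexScore(sl, sg, config$duplex_window)
    }
    if (!is.null(config$duplex_max))
      out <- out[!(out$mode == "antisense" &
                   (is.na(out$duplex_score) |
                    out$duplex_score > config$duplex_max)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("lnc_id", "gene_id", "mode", "distance_bp", "duplex_score",
          "r", "p")]
}
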