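# Fickett TESTCODE lookup tables (position and composition parameters with
# their published weights). Position bins: >=1.9, >=1.8, ..., >=1.1, <1.1.
# Composition bins: >=0.33 down to >=0.17 by 0.02, then <0.17.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

.checkAcgt <- function(sequence) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("need a single non-empty sequence")
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-ACGT symbol(s)")
}

#' Longest-ORF coverage of a transcript sequence
#'
#' Scans the three forward reading frames for ATG..stop open reading
#' frames (stop codon included in the length) and returns the longest ORF
#' length divided by the sequence length; 0 when no complete ORF exists.
#' Transcript sequences are already stranded, so reverse frames are not
#' scanned.
#'
#' @param sequence Single ACGT string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' orfCoverage("ATGAAATGA")  # 1.0
#' @export
orfCoverage <- function(sequence) {
  .checkAcgt(sequence)
  n <- nchar(sequence)
  best <- 0L
  for (frame in 0:2) {
    if (n - 2L < 1L + frame) next
    codons <- substring(sequence, seq(1L + frame, n - 2L, by = 3L),
                        seq(3L + frame, n, by = 3L))
    if (!length(codons)) next
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    # first in-frame stop at or after each start
    idx <- findInterval(starts - 1L, stops) + 1L
    ok <- idx <= length(stops)
    if (!any(ok)) next
    len <- (stops[idx[ok]] - starts[ok] + 1L) * 3L
    best <- max(best, len)
  }
  best / n
}

#' Fickett TESTCODE statistic
#'
#' The classical coding-potential score: for each base, a position
#' parameter (how unevenly the base is distributed over the three codon
#' positions) and a composition parameter (its overall frequency) are
#' mapped through the published probability lookup tables and combined in
#' the published weighted sum of eight terms. Higher scores indicate
#' coding-like periodicity.
#'
#' @param sequence Single ACGT string, length >= 10 (>= 200 recommended
#'   for stable values).
#' @return The TESTCODE score.
#' @export
fickettScore <- function(sequence) {
  .checkAcgt(sequence)
  if (nchar(sequence) < 10L) stop("sequence shorter than 10 nt")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pos <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(k) sum(chars == base & pos == k), 0L)
    posval <- max(cnt) / (min(cnt) + 1)
    # bins >=1.9, >=1.8, ..., >=1.1, else (epsilon guards fp boundaries)
    bin <- 10L - findInterval(posval + 1e-9, seq(1.1, 1.9, by = 0.1))
    score <- score + .fickett_position_prob[[base]][bin] *
      .fickett_position_weight[[base]]
    comp <- sum(cnt) / length(chars)
    bin <- 10L - findInterval(comp + 1e-9, seq(0.17, 0.33, by = 0.02))
    score <- score + .fickett_content_prob[[base]][bin] *
      .fickett_content_weight[[base]]
  }
  score
}

#' Classify transcripts as known, novel lncRNA or coding-like
#'
#' A transcript is a novel lncRNA iff both coding-potential scorers call
#' it non-coding (Fickett score below `fickett_max` AND longest-ORF
#' fraction below `orf_frac_max`), it has no annotation hit (its id is
#' absent from the known catalogue) and it is at least 200 nt long — the
#' intersection rule. Transcripts in the known catalogue are `known`
#' regardless of scores; everything else is `coding`.
#'
#' @param sequences Named character map transcript id -> sequence.
#' @param known_ids Character vector: the known-transcript catalogue.
#' @param config A [runConfig()] carrying `fickett_max` / `orf_frac_max`.
#' @return data.frame with per-transcript scores, the three boolean
#'   screens and the `novelty` call.
#' @export
callNovelty <- function(sequences, known_ids, config = runConfig()) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by transcript id")
  if (anyNA(sequences) || any(!nzchar(sequences)))
    stop("transcript(s) lacking sequence: ",
         paste(names(sequences)[is.na(sequences) | !nzchar(sequences)],
               collapse = ", "))
  fick <- vapply(sequences, fickettScore, numeric(1))
  orf <- vapply(sequences, orfCoverage, numeric(1))
  len <- nchar(sequences)
  scorer1 <- fick < config$fickett_max
  scorer2 <- orf < config$orf_frac_max
  hit <- names(sequences) %in% known_ids
  novelty <- ifelse(hit, "known",
             ifelse(scorer1 & scorer2 & len >= 200L, "novel", "coding"))
  data.frame(transcript_id = names(sequences), length = len,
             fickett_score = fick, orf_fraction = orf,
             scorer1_noncoding = scorer1, scorer2_noncoding = scorer2,
             annotation_hit = hit, novelty = novelty,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression distribution summaries for known vs novel lncRNAs
#'
#' Summarizes log2(CPM + 1) per novelty class and group by deciles, and
#' counts differentially expressed lncRNAs (DELs) per class.
#'
#' @param x A (filtered) lncRNA [LayerExperiment-class].
#' @param novelty data.frame from [callNovelty()] (or any table with
#'   `transcript_id` and `novelty`).
#' @param de Optional called DE table for the lncRNA layer (for DEL
#'   counts).
#' @return List with `deciles` (long data.frame: class, group, decile,
#'   value) and `del_counts` (class -> DEL count; NA without `de`).
#' @export
expressionDensityByClass <- function(x, novelty, de = NULL) {
  m <- logCpmMatrix(layerCounts(x))
  cls <- stats::setNames(novelty$novelty, novelty$transcript_id)[rownames(m)]
  grp <- sampleGroups(x)
  probs <- seq(0.1, 0.9, by = 0.1)
  rows <- list()
  for (cl in c("known", "novel")) {
    sel <- which(!is.na(cls) & cls == cl)
    for (g in .GROUPS) {
      vals <- m[sel, grp == g, drop = FALSE]
      q <- if (length(vals)) stats::quantile(vals, probs, names = FALSE)
           else rep(NA_real_, length(probs))
      rows[[paste(cl, g)]] <- data.frame(class = cl, group = g,
                                         decile = probs, value = q)
    }
  }
  del <- c(known = NA_integer_, novel = NA_integer_)
  if (!is.null(de)) {
    de_ids <- de$id[de$status != "ns"]
    del["known"] <- sum(cls[rownames(m) %in% de_ids] == "known", na.rm = TRUE)
    del["novel"] <- sum(cls[rownames(m) %in% de_ids] == "novel", na.rm = TRUE)
  }
  list(deciles = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       del_counts = del)
}
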