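# shared fixtures and independent oracles, all built in code

toyLayer <- function(counts, layer = "mRNA",
                     group = rep(c("stress", "control"),
                                 each = ncol(counts) / 2)) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(ifelse(group == "stress", "S", "C"),
                               seq_along(group))
  LayerExperiment(counts, layer, group)
}

toyAnnotation <- function(df) {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(df$start, df$end), strand = df$strand,
    transcript_id = df$id, gene_id = paste0("G_", df$id),
    biotype = df$biotype, known = TRUE)
  names(gr) <- df$id
  gr
}

# brute-force step-up BH, straight from the definition
bhBruteForce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# hypergeometric upper tail by exhaustive enumeration over all draws
hyperEnumeration <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# per-bp interval gap: count bases strictly between two 1-based intervals
gapByBpScan <- function(s1, e1, s2, e2) {
  b1 <- seq(s1, e1); b2 <- seq(s2, e2)
  if (length(intersect(b1, b2))) return(0L)
  sum(!seq(min(e1, e2) + 1L, max(s1, s2) - 1L) %in% c(b1, b2))
}

# unweighted KS walk computed longhand
ksWalkES <- function(ids_ranked, member) {
  hit <- ids_ranked %in% member
  K <- sum(hit); N <- length(ids_ranked)
  step <- ifelse(hit, 1 / K, -1 / (N - K))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# brute-force duplex score: enumerate every pair of window starts
duplexBruteForce <- function(a, b, window) {
  pairScore <- function(x, y) {
    wc <- paste0(x, y) %in% c("AT", "TA", "GC", "CG")
    wob <- paste0(x, y) %in% c("GT", "TG")
    ifelse(wc, -2, ifelse(wob, -1, 3))
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- Inf
  for (i in seq_len(length(av) - window + 1))
    for (j in seq_len(length(bv) - window + 1)) {
      x <- av[i:(i + window - 1)]
      y <- rev(bv[j:(j + window - 1)])   # antiparallel
      best <- min(best, sum(pairScore(x, y)))
    }
  best
}

# 5 module miRNAs + 16 singleton DEMIs = universe of 21, so a single
# shared miRNA is still significant (1/21 < 0.05)
smallSimParams <- list(
  annotation_params = list(n_coding = 120, n_lnc = 40, n_mirna = 25,
                           n_circ = 20),
  truth_params = list(n_cis_pairs = 4, n_antisense_pairs = 3,
                      n_trans_pairs = 3, n_modules_lnc = 2,
                      n_modules_circ = 1, n_modules_common = 1,
                      n_single_de = c(mRNA = 12, miRNA = 16, lncRNA = 2,
                                      circRNA = 2)))
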