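.SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

.revcompChr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = ""))
}

#' Scan a 3'UTR for miRNA seed-match sites
#'
#' Finds reverse-complement matches to the miRNA seed (nucleotides 2-7,
#' the 6mer core) in the UTR and classifies each site: `8mer` when the
#' match extends to nucleotide 8 and an `A` faces miRNA position 1;
#' `7mer-m8` on the position-8 extension alone; `7mer-A1` on the core
#' plus the A; `6mer` otherwise. Overlapping sites are all reported.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3', >= 8 nt (DNA alphabet;
#'   [readFasta()] normalizes U to T).
#' @param utr_seq 3'UTR sequence, 5'->3'.
#' @param mirna_id,target_id Optional identifiers copied into the result.
#' @return data.frame of sites: `mirna_id`, `target_id`, `site_class`,
#'   `utr_position` (1-based start of the 6mer core match).
#' @export
findSeedSites <- function(mirna_seq, utr_seq, mirna_id = NA_character_,
                          target_id = NA_character_) {
  .checkAcgt(mirna_seq); .checkAcgt(utr_seq)
  if (nchar(mirna_seq) < 8L) stop("miRNA must be at least 8 nt")
  core <- .revcompChr(substr(mirna_seq, 2L, 7L))       # 6 nt
  m8 <- .revcompChr(substr(mirna_seq, 8L, 8L))         # base facing nt 8
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      site_class = character(0), utr_position = integer(0))
  starts <- gregexpr(core, utr_seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(empty)
  starts <- as.integer(starts)
  n <- nchar(utr_seq)
  # site layout on the UTR 5'->3': [m8][core][A facing nt 1]
  has_m8 <- starts > 1L &
    substr(utr_seq, starts - 1L, starts - 1L) == m8
  has_a1 <- starts + 6L <= n &
    substring(utr_seq, starts + 6L, starts + 6L) == "A"
  cls <- ifelse(has_m8 & has_a1, "8mer",
         ifelse(has_m8, "7mer-m8",
         ifelse(has_a1, "7mer-A1", "6mer")))
  data.frame(mirna_id = mirna_id, target_id = target_id,
             site_class = cls, utr_position = starts,
             stringsAsFactors = FALSE)
}

#' Seed-site table over all miRNA x UTR pairs
#'
#' @param mirnas Named map of mature miRNA sequences.
#' @param utrs Named map of 3'UTR sequences.
#' @return Concatenated [findSeedSites()] results.
#' @export
seedSiteTable <- function(mirnas, utrs) {
  out <- list()
  for (m in names(mirnas))
    for (u in names(utrs)) {
      s <- findSeedSites(mirnas[[m]], utrs[[u]], m, u)
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  if (!length(out))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      site_class = character(0), utr_position = integer(0)))
  do.call(rbind, out)
}

#' Collapse seed sites to miRNA target sets
#'
#' @param seed_sites data.frame from [seedSiteTable()].
#' @param min_class Weakest accepted site class (default `"7mer-m8"`, the
#'   strong classes only); ordering 6mer < 7mer-A1 < 7mer-m8 < 8mer.
#' @return Named list miRNA id -> character vector of target ids.
#' @export
mirnaTargetSets <- function(seed_sites, min_class = "7mer-m8") {
  min_class <- match.arg(min_class, .SITE_CLASSES)
  if (!nrow(seed_sites)) return(stats::setNames(list(), character(0)))
  ok <- match(seed_sites$site_class, .SITE_CLASSES) >=
    match(min_class, .SITE_CLASSES)
  ss <- seed_sites[ok, , drop = FALSE]
  if (!nrow(ss)) return(stats::setNames(list(), character(0)))
  lapply(split(ss$target_id, ss$mirna_id), unique)
}

#' miRNA-sponge co-expression gate
#'
#' A (miRNA, candidate target) pair passes iff the Pearson correlation of
#' their pooled log2(CPM + 1) profiles is strictly below the negative
#' gate (default -0.9).
#'
#' @param mirna_expr,target_expr Expression vectors across all samples.
#' @param cut The gate (default -0.9).
#' @return List `pass`, `r`, `reason` (`"zero variance"` when
#'   undefined, in which case the pair fails).
#' @export
coexpressionGate <- function(mirna_expr, target_expr, cut = -0.9) {
  if (stats::sd(mirna_expr) == 0 || stats::sd(target_expr) == 0)
    return(list(pass = FALSE, r = NA_real_, reason = "zero variance"))
  r <- stats::cor(mirna_expr, target_expr)
  list(pass = r < cut, r = r, reason = NA_character_)
}

#' Hypergeometric test for shared miRNA regulators
#'
#' Upper-tail probability of observing at least `k` shared miRNAs between
#' the miRNA sets of two sponges: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = universe_n, K = |a|, n = |b|)` and
#' `k = |a intersect b|`. Symmetric in the two sets.
#'
#' @param targets_a,targets_b Character vectors: miRNAs hitting each
#'   sponge.
#' @param universe_n Total number of miRNAs in the universe.
#' @return The tail probability.
#' @export
hypergeomSharedTest <- function(targets_a, targets_b, universe_n) {
  a <- unique(targets_a); b <- unique(targets_b)
  K <- length(a); n <- length(b); k <- length(intersect(a, b))
  if (universe_n < length(union(a, b)))
    stop("universe smaller than the union of the two sets")
  if (k > min(K, n)) stop("inconsistent sets: intersection exceeds a set")
  stats::phyper(k - 1, K, universe_n - K, n, lower.tail = FALSE)
}

#' Build the ceRNA network
#'
#' For every sponge pair of the allowed type combinations (mRNA-lncRNA
#' and mRNA-circRNA by default) the shared miRNAs are those predicted to
#' target both sponges (seed match at `min_site_class` or better) with
#' both miRNA-sponge correlations strictly below `cerna_corr_cut`. An
#' edge is emitted iff at least one miRNA is shared, the two sponges are
#' positively co-expressed (`r_ab > 0`) and the hypergeometric
#' shared-miRNA test gives `p < 0.05`. Node degree is the number of
#' distinct miRNAs a sponge shares across its edges (the plain edge count
#' is reported alongside); nodes with degree >= `hub_degree` (5) are
#' hubs.
#'
#' @param target_sets Named list miRNA -> predicted target ids (from
#'   [mirnaTargetSets()]).
#' @param expr Matrix of log2(CPM + 1), rows covering miRNAs and sponges,
#'   all samples pooled.
#' @param node_types Named map id -> type (`mRNA`, `lncRNA`, `circRNA`)
#'   for every candidate sponge (differentially expressed transcripts).
#' @param config A [runConfig()].
#' @param universe_n miRNA universe size for the test; defaults to the
#'   number of differentially expressed miRNAs (= `length(target_sets)`
#'   callers pass DEMI-restricted sets).
#' @param pair_types Allowed sponge type pairs, as a two-column matrix.
#' @return A [CeRNANetwork-class].
#' @export
buildCeRNANetwork <- function(target_sets, expr, node_types,
                              config = runConfig(), universe_n = NULL,
                              pair_types = rbind(c("mRNA", "lncRNA"),
                                                 c("mRNA", "circRNA"))) {
  if (is.null(universe_n)) universe_n <- length(target_sets)
  node_types <- node_types[names(node_types) %in% rownames(expr)]
  # per-sponge gated miRNA sets: miRNA targets it AND r(miRNA, sponge) < cut
  gated <- stats::setNames(vector("list", length(node_types)),
                           names(node_types))
  for (m in names(target_sets)) {
    if (!m %in% rownames(expr)) next
    tg <- intersect(target_sets[[m]], names(node_types))
    for (t in tg) {
      g <- coexpressionGate(expr[m, ], expr[t, ], config$cerna_corr_cut)
      if (g$pass) gated[[t]] <- c(gated[[t]], m)
    }
  }
  sponges <- names(gated)[lengths(gated) > 0L]
  edges <- list()
  if (length(sponges) >= 2L) {
    cmb <- utils::combn(sort(sponges), 2L)
    for (j in seq_len(ncol(cmb))) {
      aid <- cmb[1L, j]; bid <- cmb[2L, j]
      ta <- node_types[[aid]]; tb <- node_types[[bid]]
      allowed <- any((pair_types[, 1L] == ta & pair_types[, 2L] == tb) |
                     (pair_types[, 1L] == tb & pair_types[, 2L] == ta))
      if (!allowed) next
      shared <- intersect(gated[[aid]], gated[[bid]])
      if (!length(shared)) next
      if (stats::sd(expr[aid, ]) == 0 || stats::sd(expr[bid, ]) == 0) next
      r_ab <- stats::cor(expr[aid, ], expr[bid, ])
      if (!(r_ab > 0)) next
      p <- hypergeomSharedTest(gated[[aid]], gated[[bid]], universe_n)
      if (!(p < 0.05)) next
      edges[[length(edges) + 1L]] <- data.frame(
        node_a = aid, type_a = ta, node_b = bid, type_b = tb,
        shared_mirnas = paste(sort(shared), collapse = ","),
        n_shared = length(shared), r_ab = r_ab, hyper_p = p,
        stringsAsFactors = FALSE)
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), type_a = character(0),
               node_b = character(0), type_b = character(0),
               shared_mirnas = character(0), n_shared = integer(0),
               r_ab = numeric(0), hyper_p = numeric(0))
  # nodes: sponges on edges plus the miRNAs they share
  node_ids <- unique(c(edge_df$node_a, edge_df$node_b))
  mir_ids <- unique(unlist(strsplit(edge_df$shared_mirnas, ",", fixed = TRUE)))
  deg <- integer(0); edeg <- integer(0)
  if (length(node_ids)) {
    deg <- vapply(node_ids, function(id) {
      rows <- edge_df$node_a == id | edge_df$node_b == id
      length(unique(unlist(strsplit(edge_df$shared_mirnas[rows], ",",
                                    fixed = TRUE))))
    }, 0L)
    edeg <- vapply(node_ids, function(id)
      sum(edge_df$node_a == id | edge_df$node_b == id), 0L)
  }
  mir_deg <- vapply(mir_ids, function(m)
    sum(vapply(strsplit(edge_df$shared_mirnas, ",", fixed = TRUE),
               function(v) m %in% v, TRUE)), 0L)
  nodes <- S4Vectors::DataFrame(
    id = c(node_ids, mir_ids),
    type = c(unname(node_types[node_ids]), rep("miRNA", length(mir_ids))),
    degree = c(unname(deg), unname(mir_deg)),
    edge_degree = c(unname(edeg), rep(NA_integer_, length(mir_ids))))
  nodes$hub <- !is.na(nodes$degree) & nodes$degree >= config$hub_degree
  new("CeRNANetwork", nodes = nodes, edges = S4Vectors::DataFrame(edge_df),
      universe_n = as.integer(universe_n))
}

#' Partition mRNA nodes into lncRNA-specific vs commonly regulated
#'
#' mRNAs with at least one lncRNA sponge partner but no circRNA partner
#' are "lncRNA-specific"; mRNAs with both partner types are "common".
#'
#' @param network A [CeRNANetwork-class].
#' @return List `lnc_only` and `common` (character vectors of mRNA ids).
#' @export
specificVsCommon <- function(network) {
  ed <- as.data.frame(networkEdges(network))
  partner_types <- function(id) {
    c(ed$type_b[ed$node_a == id], ed$type_a[ed$node_b == id])
  }
  mrnas <- unique(c(ed$node_a[ed$type_a == "mRNA"],
                    ed$node_b[ed$type_b == "mRNA"]))
  has_lnc <- vapply(mrnas, function(id) "lncRNA" %in% partner_types(id), TRUE)
  has_circ <- vapply(mrnas, function(id) "circRNA" %in% partner_types(id), TRUE)
  list(lnc_only = mrnas[has_lnc & !has_circ],
       common = mrnas[has_lnc & has_circ])
}
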