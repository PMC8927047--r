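#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.LAYERS <- c("mRNA", "miRNA", "lncRNA", "circRNA")
.GROUPS <- c("stress", "control")
.BIOTYPES <- c("coding", "lncRNA", "miRNA", "circRNA")

#' Layer assignment between expression layers and biotypes
#'
#' The four expression layers carry one biotype each: the mRNA layer holds
#' coding genes, the other layers their namesake non-coding biotypes.
#'
#' @param layer One of `"mRNA"`, `"miRNA"`, `"lncRNA"`, `"circRNA"`.
#' @return The matching biotype string.
#' @export
layerBiotype <- function(layer) {
  layer <- match.arg(layer, .LAYERS)
  c(mRNA = "coding", miRNA = "miRNA", lncRNA = "lncRNA",
    circRNA = "circRNA")[[layer]]
}

#' One expression layer of a two-group transcriptome experiment
#'
#' `LayerExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with a `layer` tag (mRNA, miRNA, lncRNA or circRNA). The single assay
#' `"counts"` holds raw, non-negative integer read counts
#' (transcripts x samples) and `colData(x)$group` assigns each sample to
#' the stress or control arm.
#'
#' @slot layer character(1), one of the four expression layers.
#' @export
setClass("LayerExperiment",
  contains = "SummarizedExperiment",
  representation(layer = "character"))

setValidity("LayerExperiment", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of %s",
                          paste(.LAYERS, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)))
      msg <- c(msg, "counts must not contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate transcript identifier(s): %s",
      paste(unique(rownames(object)[duplicated(rownames(object))]),
            collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  grp <- SummarizedExperiment::colData(object)$group
  if (is.null(grp) || !all(grp %in% .GROUPS))
    msg <- c(msg, "colData(x)$group must assign every sample to 'stress' or 'control'")
  else if (any(table(factor(grp, levels = .GROUPS)) < 2L))
    msg <- c(msg, "each group needs at least 2 samples")
  if (length(msg)) msg else TRUE
})

#' Construct a LayerExperiment from a count matrix and a design map
#'
#' @param counts Integer matrix, transcripts x samples, with row and column
#'   names.
#' @param layer Expression layer of the matrix.
#' @param group Character vector (or named map over the sample names) giving
#'   `"stress"` / `"control"` per sample.
#' @return A validated [LayerExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 10), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' le <- LayerExperiment(m, "mRNA", rep(c("stress", "control"), each = 3))
#' @export
LayerExperiment <- function(counts, layer, group) {
  layer <- match.arg(layer, .LAYERS)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry transcript rownames and sample colnames")
  if (!is.null(names(group)))
    group <- group[colnames(counts)]
  if (length(group) != ncol(counts))
    stop("'group' must cover every sample")
  storage.mode(counts) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(counts)))
  new("LayerExperiment", se, layer = layer)
}

#' @describeIn LayerExperiment Expression layer tag of the object.
#' @param x A `LayerExperiment`.
#' @export
layerType <- function(x) x@layer

#' @describeIn LayerExperiment Raw count matrix accessor.
#' @export
layerCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn LayerExperiment Sample-to-group map (named character vector).
#' @export
sampleGroups <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))
}

setMethod("show", "LayerExperiment", function(object) {
  grp <- sampleGroups(object)
  cat(sprintf("LayerExperiment [%s]: %d transcripts x %d samples (%d stress / %d control)\n",
              layerType(object), nrow(object), ncol(object),
              sum(grp == "stress"), sum(grp == "control")))
})

#' Competing endogenous RNA network
#'
#' Sponge-sponge network where an edge joins two transcripts (mRNA-lncRNA or
#' mRNA-circRNA by default) that share at least one negatively co-expressed
#' miRNA, are positively co-expressed with each other, and pass the
#' hypergeometric shared-miRNA test.
#'
#' @slot nodes `DataFrame` with columns `id`, `type`, `degree` (distinct
#'   shared miRNAs across the node's edges), `edge_degree` (plain edge
#'   count) and `hub` (`degree >= hub_degree`).
#' @slot edges `DataFrame` with columns `node_a`, `type_a`, `node_b`,
#'   `type_b`, `shared_mirnas` (comma-joined ids), `n_shared`, `r_ab`,
#'   `hyper_p`.
#' @slot universe_n integer, miRNA universe size used by the test.
#' @export
setClass("CeRNANetwork",
  representation(nodes = "DataFrame", edges = "DataFrame",
                 universe_n = "integer"))

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  need_e <- c("node_a", "type_a", "node_b", "type_b", "shared_mirnas",
              "n_shared", "r_ab", "hyper_p")
  if (!all(need_e %in% colnames(object@edges)))
    msg <- c(msg, "edges must have the canonical edge columns")
  else if (nrow(object@edges)) {
    if (any(object@edges$n_shared < 1L))
      msg <- c(msg, "every edge must share at least one miRNA")
    if (any(object@edges$r_ab <= 0))
      msg <- c(msg, "sponge co-expression r_ab must be positive")
    if (any(object@edges$hyper_p >= 0.05))
      msg <- c(msg, "edges must pass the hypergeometric test")
  }
  if (!all(c("id", "type", "degree", "hub") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes must have id/type/degree/hub columns")
  if (length(msg)) msg else TRUE
})

#' @describeIn CeRNANetwork Edge table accessor.
#' @param x A `CeRNANetwork`.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CeRNANetwork Node table accessor.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn CeRNANetwork Per-type node composition (fractions summing
#'   to 1; empty network gives an empty vector).
#' @export
networkComposition <- function(x) {
  if (!nrow(x@nodes)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(x@nodes$type)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

setMethod("show", "CeRNANetwork", function(object) {
  cat(sprintf("CeRNANetwork: %d nodes, %d edges, %d hub nodes (miRNA universe %d)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@nodes$hub), object@universe_n))
  comp <- networkComposition(object)
  if (length(comp))
    cat("  composition:",
        paste(sprintf("%s %.1f%%", names(comp), 100 * comp), collapse = ", "),
        "\n")
})

#' Analysis run configuration
#'
#' Bundles every tunable threshold of the pipeline with the published
#' defaults: count filters 5 (coding) / 2 (non-coding), |log2FC| > 1,
#' FDR < 0.05 (mRNA/lncRNA) or p < 0.05 (miRNA/circRNA), cis window
#' 100 kb, correlation gates |r| > 0.9 and r < -0.9 with p < 0.05,
#' hub degree >= 5.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list with class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    filter_coding = 5, filter_noncoding = 2,
    lfc_cut = 1, fdr_cut = 0.05, p_cut = 0.05,
    corr_cut = 0.9, cerna_corr_cut = -0.9,
    cis_window_bp = 100000L, hub_degree = 5L,
    min_site_class = "7mer-m8",
    fickett_max = 0.95, orf_frac_max = 0.30,
    duplex_window = 40L, duplex_max = NULL,
    pseudocount = 0.5, seed = 1L)
  ovr <- list(...)
  if (length(ovr)) {
    bad <- setdiff(names(ovr), names(cfg))
    if (length(bad)) stop("unknown RunConfig field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(ovr)] <- ovr
  }
  num <- cfg[c("filter_coding", "filter_noncoding", "lfc_cut", "fdr_cut",
               "p_cut", "corr_cut", "cerna_corr_cut", "cis_window_bp",
               "hub_degree")]
  if (!all(vapply(num, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("all RunConfig thresholds must be finite numbers")
  if (cfg$cis_window_bp <= 0) stop("cis_window_bp must be positive")
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
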