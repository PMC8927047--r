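#' Read a gene-level count table into a LayerExperiment
#'
#' The file is a TSV whose first column holds transcript identifiers and
#' whose remaining columns are samples. Cells must be non-negative integers
#' (raw read counts). Every sample must be covered by the `design` map.
#'
#' @param path Path to the TSV file.
#' @param layer Expression layer of the table.
#' @param design Named character vector mapping sample id to `"stress"` or
#'   `"control"`.
#' @return A [LayerExperiment-class].
#' @export
readCounts <- function(path, layer, design) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs an id column plus samples")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate transcript identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell(s) in ", path)
  if (any(is.na(m))) stop("missing count cell(s) in ", path)
  if (any(m < 0)) stop("negative count(s) in ", path)
  if (any(m != round(m))) stop("non-integer count(s) in ", path)
  rownames(m) <- ids
  missing <- setdiff(colnames(m), names(design))
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  LayerExperiment(m, layer, design[colnames(m)])
}

#' Write a LayerExperiment back to a counts TSV
#'
#' @param x A [LayerExperiment-class].
#' @param path Output path.
#' @export
writeCounts <- function(x, path) {
  m <- layerCounts(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript annotation from a GTF file
#'
#' Imports `transcript` features and returns them as a
#' [GenomicRanges::GRanges] with metadata columns `transcript_id`,
#' `gene_id`, `biotype` and `known`. Coordinates stay 1-based inclusive as
#' in the GTF. Strand is mandatory for every transcript because the
#' antisense logic needs it.
#'
#' @param path Path to a GTF file.
#' @return `GRanges`, one range per transcript.
#' @export
readAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (!length(gr)) stop("no transcript features in ", path)
  for (attr in c("transcript_id", "gene_id")) {
    val <- S4Vectors::mcols(gr)[[attr]]
    if (is.null(val) || anyNA(val) || any(val == "")) {
      bad <- if (is.null(val)) seq_along(gr) else which(is.na(val) | val == "")
      stop(sprintf("transcript feature missing %s (file line %d)",
                   attr, .gtfLineOfTranscript(path, bad[1L])))
    }
  }
  if (any(GenomicRanges::strand(gr) == "*")) {
    bad <- which(as.character(GenomicRanges::strand(gr)) == "*")[1L]
    stop(sprintf("transcript without strand (file line %d); strand is required",
                 .gtfLineOfTranscript(path, bad)))
  }
  if (is.null(gr$biotype)) {
    bt <- gr$gene_biotype
    if (is.null(bt)) bt <- rep(NA_character_, length(gr))
    gr$biotype <- bt
  }
  if (is.null(gr$known)) gr$known <- TRUE else gr$known <- as.logical(gr$known)
  names(gr) <- gr$transcript_id
  gr
}

# line number (1-based, comments included) of the n-th transcript feature
.gtfLineOfTranscript <- function(path, n) {
  lines <- readLines(path)
  feat <- vapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) length(f) >= 3L && f[3L] == "transcript",
                 TRUE)
  which(feat)[n]
}

#' Write transcript annotation as GTF
#'
#' @param gr Annotation `GRanges` as returned by [readAnnotation()].
#' @param path Output path.
#' @export
writeAnnotation <- function(gr, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; biotype "%s"; known "%s";',
    gr$gene_id, gr$transcript_id, gr$biotype,
    ifelse(gr$known, "TRUE", "FALSE"))
  lines <- paste(
    as.character(GenomicRanges::seqnames(gr)), "mechanoCeRNA", "transcript",
    GenomicRanges::start(gr), GenomicRanges::end(gr), ".",
    as.character(GenomicRanges::strand(gr)), ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character map
#'
#' Identifiers are truncated at the first whitespace and must be unique.
#' Sequences are uppercased and RNA `U` is normalized to DNA `T` so seed
#' matching and duplex scoring share a single alphabet.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences (possibly empty).
#' @export
readFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "T", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  stats::setNames(seqs, ids)
}

#' Write a named sequence map as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
writeFasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds a mapping of [runConfig()] field names to values;
#' unknown fields are rejected. Format is chosen by extension
#' (`.json` vs anything YAML-parsable).
#'
#' @param path Path to the config file.
#' @return A validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(runConfig, as.list(vals))
}

#' Read a known-transcript catalogue (one identifier per line)
#'
#' @param path Path to the list file; blank lines and `#` comments ignored.
#' @return Character vector of identifiers.
#' @export
readKnownIds <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write all pipeline result tables to a directory
#'
#' Emits one TSV per stage (DE tables per layer, novelty calls, regulatory
#' pairs, enrichment), the ceRNA network as an edge-list TSV
#' (`nodeA, typeA, nodeB, typeB, shared_mirna_count, r, p`) and a JSON run
#' summary with the four differential-set counts (DEM, DEMI, DEL, DEC).
#'
#' @param tables Named list of data.frames (e.g. `de_mRNA`, `novelty`,
#'   `regulatory_pairs`, `enrichment_*`); may be empty.
#' @param network A [CeRNANetwork-class] or `NULL`.
#' @param outdir Output directory (created if needed).
#' @param summary Named list merged into the JSON run summary.
#' @return Invisibly, the vector of written paths.
#' @export
writeResults <- function(tables, network, outdir, summary = list()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  if (file.access(outdir, 2L) != 0L) stop("directory not writable: ", outdir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(network)) {
    ed <- as.data.frame(networkEdges(network))
    edge_df <- data.frame(
      nodeA = ed$node_a, typeA = ed$type_a,
      nodeB = ed$node_b, typeB = ed$type_b,
      shared_miRNA_count = ed$n_shared,
      shared_miRNAs = ed$shared_mirnas,
      r = ed$r_ab, p = ed$hyper_p,
      stringsAsFactors = FALSE)
    if (!nrow(ed))
      edge_df <- edge_df[0, , drop = FALSE]
    p <- file.path(outdir, "cerna_edges.tsv")
    utils::write.table(edge_df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(outdir, "cerna_nodes.tsv")
    utils::write.table(as.data.frame(networkNodes(network)), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  de_counts <- list()
  for (layer in .LAYERS) {
    tab <- tables[[paste0("de_", layer)]]
    if (is.null(tab)) next
    key <- c(mRNA = "DEM", miRNA = "DEMI", lncRNA = "DEL", circRNA = "DEC")[[layer]]
    de_counts[[key]] <- sum(tab$status != "ns")
  }
  summary <- c(list(de_counts = de_counts), summary)
  p <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
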