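#' Read an expression matrix from TSV
#'
#' Expects genes as rows: first column gene id, remaining columns samples
#' (header row with sample ids). Set `samplesAsRows = TRUE` for the
#' transposed layout. Missing values are an error.
#'
#' @param path TSV path.
#' @param labels optional path to a 2-column (sample id, population) TSV
#'   used to attach population labels.
#' @param samplesAsRows logical transpose flag.
#' @return a `SummarizedExperiment` (genes x samples).
#' @export
readExpression <- function(path, labels = NULL, samplesAsRows = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  M <- as.matrix(d)
  if (!is.numeric(M)) stop("expression values must be numeric")
  if (anyNA(M)) stop("expression matrix contains missing values")
  if (samplesAsRows) M <- t(M)
  pop <- NULL
  if (!is.null(labels)) {
    lab <- readLabels(labels)
    if (!all(colnames(M) %in% names(lab)))
      stop("labels file is missing samples: ",
           paste(utils::head(setdiff(colnames(M), names(lab))), collapse = ", "))
    pop <- unname(lab[colnames(M)])
  }
  pcorExperiment(M, population = pop, genesAsRows = TRUE)
}

#' Read per-sample population labels
#'
#' @param path 2-column TSV (sample id, population), no header required.
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE)
  first <- as.character(d[1, ])
  if (identical(tolower(first), c("sample", "population"))) d <- d[-1, ]
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Write an expression container back to TSV
#'
#' Genes as rows with a leading `gene` column; full precision.
#'
#' @param x `SummarizedExperiment` or samples x genes matrix.
#' @param path output TSV path.
#' @export
writeExpression <- function(x, path) {
  M <- t(.exprMatrix(x))
  d <- data.frame(gene = rownames(M), M, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a result table to TSV
#'
#' Numeric columns are rendered with 6 significant digits.
#'
#' @param table data.frame (edge tables, summaries).
#' @param path output TSV path.
#' @export
writeEdgeTable <- function(table, path) {
  t2 <- table
  num <- vapply(t2, is.numeric, TRUE)
  t2[num] <- lapply(t2[num], signif, digits = 6)
  utils::write.table(t2, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a partial-correlation matrix to TSV at full precision
#'
#' @param result a [PCorResult-class] or matrix.
#' @param path output TSV path.
#' @export
writePcorMatrix <- function(result, path) {
  M <- if (is(result, "PCorResult")) pcorValues(result) else result
  d <- data.frame(gene = rownames(M), M, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Select genes in a genomic window around anchor positions
#'
#' Keeps genes whose transcription start site lies within
#' `[anchorStart - flank, anchorEnd + flank]` (inclusive on both ends) on
#' the requested chromosome; this mirrors selecting a risk region spanning
#' a fixed flank around the outermost association signals.
#'
#' @param annotations data.frame with columns `gene`, `chrom`, `tss`
#'   (1-based bp).
#' @param chrom chromosome id.
#' @param anchorStart,anchorEnd bp positions of the outer anchors.
#' @param flank bp added on each side (study default 2e6).
#' @return character vector of gene ids (annotation order preserved).
#' @export
selectRegionGenes <- function(annotations, chrom, anchorStart, anchorEnd,
                              flank = 2e6) {
  if (anyDuplicated(annotations$gene)) stop("gene ids must be unique")
  if (!chrom %in% annotations$chrom) {
    warning("chromosome ", chrom, " not present in the annotation")
    return(character(0))
  }
  keep <- annotations$chrom == chrom &
    annotations$tss >= anchorStart - flank &
    annotations$tss <= anchorEnd + flank
  annotations$gene[keep]
}

#' Filter genes by expression presence
#'
#' Keeps genes whose value exceeds `threshold` in at least `minFraction` of
#' samples (the study removed genes with log-CPM > 0 in fewer than 75% of
#' patients). Gene order is preserved.
#'
#' @param x `SummarizedExperiment` or samples x genes matrix.
#' @param threshold expression presence cutoff (default 0).
#' @param minFraction minimum fraction of samples above threshold
#'   (default 0.75).
#' @return filtered object of the same type as the input.
#' @export
filterExpressed <- function(x, threshold = 0, minFraction = 0.75) {
  if (minFraction < 0 || minFraction > 1) stop("minFraction must be in [0, 1]")
  M <- .exprMatrix(x)
  frac <- colMeans(M > threshold)
  keep <- frac >= minFraction
  if (is(x, "SummarizedExperiment")) x[keep, ] else M[, keep, drop = FALSE]
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Fills defaults for missing fields and rejects invalid values; the result
#' drives the command-line pipeline and is serialized alongside outputs for
#' provenance.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file, or `NULL` for all
#'   defaults.
#' @return validated named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  def <- list(
    nGenesList = c(0, 1, 5, 10, 25, 50, 75, 100),
    minLambdaList = c(0, 0.1, 1, 10),
    damping = 0.85,
    penalty = "squared",
    nBoot = 1000, nPerm = 1000,
    fdrSignificant = 0.01, fdrDifferential = 0.1,
    percentiles = c(5, 95),
    consensusK = 10, minNGenes = 5,
    seed = 1
  )
  for (n in names(def)) if (is.null(cfg[[n]])) cfg[[n]] <- def[[n]]
  if (cfg$damping <= 0 || cfg$damping >= 1)
    stop("config field 'damping' must be in (0, 1)")
  if (!cfg$penalty %in% c("squared", "standard"))
    stop("config field 'penalty' must be 'squared' or 'standard'")
  for (n in c("nBoot", "nPerm"))
    if (cfg[[n]] < 2) stop("config field '", n, "' must be >= 2")
  for (n in c("fdrSignificant", "fdrDifferential"))
    if (cfg[[n]] <= 0 || cfg[[n]] >= 1)
      stop("config field '", n, "' must be in (0, 1)")
  if (any(cfg$nGenesList < 0) || any(cfg$minLambdaList < 0))
    stop("config grid lists must be non-negative")
  cfg
}

#' Serialize a run configuration to YAML
#'
#' @param cfg list from [readRunConfig()].
#' @param path output path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
}
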