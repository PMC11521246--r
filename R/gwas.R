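#' Read GWAS loci from a BED-like or two-column file
#'
#' Accepts 3-column BED-like input (`chrom`, `start`, `end`; the interval
#' midpoint is used, with BED treated as 0-based half-open) or 2-column
#' (`chrom`, `pos`) 1-based positions.
#'
#' @param path TSV file path.
#' @param zeroBased logical; `TRUE` for BED 0-based half-open coordinates.
#' @param header logical; file carries a header row.
#' @return data.frame with columns `chrom` (character), `pos` (numeric bp).
#' @export
readLoci <- function(path, zeroBased = FALSE, header = FALSE) {
  d <- utils::read.table(path, header = header, sep = "", as.is = TRUE)
  if (ncol(d) >= 3 && is.numeric(d[[3]])) {
    start <- d[[2]]; end <- d[[3]]
    if (zeroBased) start <- start + 1
    pos <- floor((start + end) / 2)
  } else {
    pos <- d[[2]]
    if (zeroBased) pos <- pos + 1
  }
  out <- data.frame(chrom = as.character(d[[1]]), pos = as.numeric(pos),
                    stringsAsFactors = FALSE)
  if (any(out$pos < 1)) stop("locus positions must be >= 1")
  out
}

#' Read a chromosome-length table
#'
#' @param path 2-column TSV (`chrom`, `length_bp`); `NULL` loads the
#'   bundled hg38 autosome + X layout.
#' @return named numeric vector of chromosome lengths.
#' @export
readGenomeLayout <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hg38_chrom_lengths.tsv",
                        package = "RidgePcor", mustWork = TRUE)
  d <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE)
  len <- stats::setNames(as.numeric(d[[2]]), as.character(d[[1]]))
  if (any(len <= 0)) stop("chromosome lengths must be > 0")
  len
}

#' Count regions with k clustered loci
#'
#' After sorting loci within each chromosome, counts the windows of `k`
#' consecutive same-chromosome loci whose span (last minus first position)
#' is at most `regionLength`; overlapping windows each count.
#'
#' @param loci data.frame with `chrom` and `pos` columns.
#' @param k number of hits per region (>= 2).
#' @param regionLength window span in bp.
#' @return integer count of qualifying k-windows.
#' @export
countRegions <- function(loci, k, regionLength) {
  if (k < 2) stop("k must be >= 2")
  if (regionLength <= 0) stop("regionLength must be > 0")
  total <- 0L
  for (ch in unique(loci$chrom)) {
    pos <- sort(loci$pos[loci$chrom == ch])
    n <- length(pos)
    if (n < k) next
    span <- pos[k:n] - pos[seq_len(n - k + 1)]
    total <- total + sum(span <= regionLength)
  }
  total
}

#' Monte-Carlo test for regional clustering of GWAS loci
#'
#' Compares the observed number of `k`-hit regions to its null distribution
#' under uniform placement of the same number of loci across the genome
#' (chromosome drawn proportional to its length, position uniform within
#' it). The p-value uses the add-one permutation convention
#' `(1 + #{sims >= observed}) / (nSims + 1)`.
#'
#' @param loci observed loci (data.frame `chrom`, `pos`).
#' @param layout named chromosome-length vector (see [readGenomeLayout()]).
#' @param k hits per region.
#' @param regionLength window span in bp.
#' @param nSims number of simulations (study scale 100000; >= 100 required).
#' @param seed integer RNG seed.
#' @return list with `observed` (region count), `p`, and `simCounts`.
#' @export
clusteringPvalue <- function(loci, layout = readGenomeLayout(), k = 3,
                             regionLength = 34.28e6, nSims = 1000,
                             seed = NULL) {
  if (nSims < 100) stop("nSims must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  observed <- countRegions(loci, k, regionLength)
  nLoci <- nrow(loci)
  chroms <- names(layout)
  pChrom <- layout / sum(layout)
  sims <- integer(nSims)
  for (s in seq_len(nSims)) {
    ci <- sample.int(length(layout), nLoci, replace = TRUE, prob = pChrom)
    sim <- data.frame(chrom = chroms[ci],
                      pos = floor(stats::runif(nLoci) * layout[ci]) + 1)
    sims[s] <- countRegions(sim, k, regionLength)
  }
  list(observed = observed,
       p = (1 + sum(sims >= observed)) / (nSims + 1),
       simCounts = sims)
}
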