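# TMM scaling factors, CPM and the expression filter.

#' Assemble a count SummarizedExperiment
#'
#' Wraps a raw gene x sample count matrix and its sample metadata into a
#' \link[SummarizedExperiment]{SummarizedExperiment} (assay "counts"),
#' checking the invariants the pipeline relies on: non-negative integer
#' counts, unique gene and sample ids, positive library sizes, and a unique
#' (ecotype, condition, time, replicate) combination per sample.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames
#'   required), samples in columns (colnames required).
#' @param meta data.frame with columns sample_id, ecotype, condition
#'   ("treated"/"control"), time, replicate; rows match the count columns.
#' @return a SummarizedExperiment with assay "counts" and the metadata as
#'   colData.
#' @export
stressCountSet <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (any(colSums(counts) <= 0)) stop("every library size must be > 0")
  meta <- as.data.frame(meta)
  need <- c("sample_id", "ecotype", "condition", "time", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata must cover every count column")
  if (!all(meta$condition %in% c("treated", "control")))
    stop("condition must be 'treated' or 'control'")
  key <- with(meta, paste(ecotype, condition, time, replicate))
  if (anyDuplicated(key))
    stop("(ecotype, condition, time, replicate) must be unique per sample")
  rownames(meta) <- meta$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
}

.counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' TMM normalization factors
#'
#' Trimmed Mean of M-values scaling factors between sequencing libraries.
#' The reference is the sample whose 75th-percentile CPM is closest to the
#' mean 75th percentile. For each sample, gene-wise log ratios M and
#' average abundances A versus the reference are computed over genes with
#' nonzero counts in both libraries, the extreme 30 percent of M and
#' 5 percent of A are trimmed from each tail, and the factor is the
#' precision-weighted mean of the surviving M values, exponentiated. The
#' factors are finally scaled so their geometric mean is exactly one.
#'
#' @param x a SummarizedExperiment with assay "counts" or a count matrix.
#' @param logratioTrim fraction of M values trimmed from each tail.
#' @param sumTrim fraction of A values trimmed from each tail.
#' @param minGenes if fewer genes survive trimming, the sample's factor
#'   falls back to 1 with a warning.
#' @return named numeric vector of positive factors (geometric mean 1),
#'   with the reference sample id in attribute "reference".
#' @export
tmmFactors <- function(x, logratioTrim = 0.30, sumTrim = 0.05,
                       minGenes = 10L) {
  y <- .counts(x)
  if (ncol(y) < 2L) stop("TMM needs at least two samples")
  N <- colSums(y)
  if (any(N <= 0)) stop("every library size must be > 0")
  # reference: 75th-percentile CPM closest to the mean across samples
  f75 <- apply(y, 2L, function(col) quantile(col, 0.75)) / N
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- y[, ref]; Nr <- N[ref]
  fac <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    yj <- y[, j]; Nj <- N[j]
    ok <- yj > 0 & yr > 0
    if (!any(ok)) { warning("no shared expressed genes; factor = 1"); return(1) }
    pj <- yj[ok] / Nj; pr <- yr[ok] / Nr
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1;      hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < minGenes) {
      warning(sprintf("sample %s: only %d genes survive trimming; factor = 1",
                      colnames(y)[j], sum(keep)))
      return(1)
    }
    v <- (Nj - yj[ok]) / (Nj * yj[ok]) + (Nr - yr[ok]) / (Nr * yr[ok])
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    2^f
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(y)
  attr(fac, "reference") <- colnames(y)[ref]
  fac
}

#' Counts per million
#'
#' \code{cpm_gs = y_gs / (N_s * factor_s) * 1e6}; with \code{normFactors =
#' NULL} the factors are taken as 1 (raw CPM).
#'
#' @param x a SummarizedExperiment with assay "counts" or a count matrix.
#' @param normFactors per-sample factors as from \code{\link{tmmFactors}},
#'   or NULL for raw CPM.
#' @return numeric matrix of the same shape as the counts.
#' @export
cpmMatrix <- function(x, normFactors = NULL) {
  y <- .counts(x)
  N <- colSums(y)
  if (any(N <= 0)) stop("every library size must be > 0")
  f <- if (is.null(normFactors)) rep(1, ncol(y)) else {
    if (!is.null(names(normFactors)))
      normFactors <- normFactors[colnames(y)]
    as.numeric(normFactors)
  }
  if (length(f) != ncol(y) || anyNA(f) || any(f <= 0))
    stop("normFactors must be positive and cover every sample")
  sweep(y, 2L, N * f, "/") * 1e6
}

#' Expression filter
#'
#' Keeps genes whose CPM exceeds \code{cpmThreshold} in strictly more than
#' \code{sampleFraction} of the samples (so a gene passing in exactly 90
#' percent of samples is dropped under the defaults). Gene order is
#' preserved.
#'
#' @param x a SummarizedExperiment with assay "counts" or a count matrix.
#' @param cpmThreshold CPM cutoff (default 2).
#' @param sampleFraction required fraction of samples, strict (default 0.90).
#' @param normFactors optional TMM factors used in the CPM computation.
#' @return the input restricted to the retained genes.
#' @export
expressionFilter <- function(x, cpmThreshold = 2, sampleFraction = 0.90,
                             normFactors = NULL) {
  if (cpmThreshold < 0 || sampleFraction < 0 || sampleFraction >= 1)
    stop("invalid thresholds")
  cp <- cpmMatrix(x, normFactors)
  keep <- rowMeans(cp > cpmThreshold) > sampleFraction
  if (!any(keep)) message("expression filter removed every gene")
  if (methods::is(x, "SummarizedExperiment")) x[keep, ] else
    .counts(x)[keep, , drop = FALSE]
}
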