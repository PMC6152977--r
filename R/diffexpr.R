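# Per-time-point NB exact-test differential expression and the
# stress-gene selection cascade.

.geomean <- function(x) exp(mean(log(x)))

# Shared method-of-moments dispersion on pseudo-counts: pooled
# regression-through-origin of (var - mean) on mean^2 across genes and
# groups, floored at zero.
.momDispersion <- function(groups) {
  num <- 0; den <- 0
  for (m in groups) {
    if (ncol(m) < 2L) next
    mu <- rowMeans(m)
    v <- apply(m, 1L, var)
    use <- mu > 0
    num <- num + sum(v[use] - mu[use])
    den <- den + sum(mu[use]^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# Exact conditional two-sided NB test for one gene: given rounded group
# sums s1, s2 from n1 and n2 samples at common per-sample mean mu and
# dispersion phi, condition on s = s1 + s2 and double the smaller tail.
.exactNbPvalue <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  x <- 0:s
  if (phi < 1e-10) {
    lw <- dbinom(x, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- s / (n1 + n2)
    lw <- dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(s - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  lower <- sum(w[x <= s1])
  upper <- sum(w[x >= s1])
  min(1, 2 * min(lower, upper))
}

#' Negative-binomial exact test for two-group count comparisons
#'
#' Re-implementation of an exact NB test for replicated counts: library
#' sizes are equalized to their geometric mean ("pseudo-counts"), a shared
#' dispersion is estimated by method of moments across genes when not
#' supplied, and each gene's p-value is the two-sided exact conditional
#' probability of the treated group sum given the total (doubling the
#' smaller tail, capped at one). The log2 fold change is computed on mean
#' CPM with a 0.5 prior: \code{log2((cpmT + 0.5) / (cpmC + 0.5))}.
#'
#' @param treated count matrix genes x replicates for the treated group.
#' @param control count matrix genes x replicates for the control group
#'   (same genes, same order).
#' @param libSizes effective library sizes for the columns of
#'   \code{cbind(treated, control)}; defaults to the column sums.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2), or NULL
#'   to estimate a shared value by method of moments.
#' @return data.frame with columns gene, log2fc, pvalue.
#' @export
nbExactTest <- function(treated, control, libSizes = NULL,
                        dispersion = NULL) {
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (nrow(treated) != nrow(control))
    stop("treated and control must cover the same genes")
  if (ncol(treated) < 2L || ncol(control) < 2L)
    stop("at least two replicates per group are required")
  y <- cbind(treated, control)
  if (is.null(libSizes)) libSizes <- colSums(y)
  if (length(libSizes) != ncol(y) || any(libSizes <= 0))
    stop("libSizes must be positive, one per sample")
  n1 <- ncol(treated); n2 <- ncol(control)
  N0 <- .geomean(libSizes)
  pseudo <- sweep(y, 2L, N0 / libSizes, "*")
  pt <- pseudo[, seq_len(n1), drop = FALSE]
  pc <- pseudo[, n1 + seq_len(n2), drop = FALSE]
  phi <- if (is.null(dispersion)) .momDispersion(list(pt, pc)) else dispersion
  if (phi < 0) stop("dispersion must be >= 0")
  s1 <- round(rowSums(pt)); s2 <- round(rowSums(pc))
  pval <- vapply(seq_len(nrow(y)), function(g) {
    if (s1[g] + s2[g] == 0) return(1)
    .exactNbPvalue(s1[g], s2[g], n1, n2, phi)
  }, numeric(1))
  cpmT <- rowMeans(pt) / N0 * 1e6
  cpmC <- rowMeans(pc) / N0 * 1e6
  lfc <- log2((cpmT + 0.5) / (cpmC + 0.5))
  lfc[s1 + s2 == 0] <- 0
  genes <- rownames(y)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(y)))
  data.frame(gene = genes, log2fc = lfc, pvalue = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate DEG calls
#'
#' Marks each result as a differentially expressed gene when the absolute
#' linear fold change exceeds \code{2^fcThreshold} (i.e. |log2FC| >
#' fcThreshold, boundary exclusive) and the raw p-value is below
#' \code{pThreshold}. Pure annotation; no rows are removed.
#'
#' @param de data.frame with columns log2fc and pvalue.
#' @param fcThreshold log2 fold-change cutoff (default 1, i.e. 2-fold).
#' @param pThreshold p-value cutoff (default 0.05).
#' @return the input with a logical is_deg column.
#' @export
callDegs <- function(de, fcThreshold = 1, pThreshold = 0.05) {
  if (fcThreshold <= 0 || pThreshold <= 0) stop("thresholds must be positive")
  de$is_deg <- abs(de$log2fc) > fcThreshold & de$pvalue < pThreshold
  de
}

#' Run DE across ecotypes and time points
#'
#' For each ecotype and time point, compares the treated replicates against
#' the matching control replicates with \code{\link{nbExactTest}} and
#' annotates DEG calls.
#'
#' @param se SummarizedExperiment with assay "counts" and colData columns
#'   ecotype, condition, time, replicate.
#' @param normFactors optional TMM factors (effective library size =
#'   library size x factor).
#' @param dispersion optional shared NB dispersion; estimated per contrast
#'   when NULL.
#' @param fcThreshold,pThreshold DEG thresholds, see \code{\link{callDegs}}.
#' @return data.frame with columns gene, ecotype, time, log2fc, pvalue,
#'   is_deg.
#' @export
runDifferentialExpression <- function(se, normFactors = NULL,
                                      dispersion = NULL, fcThreshold = 1,
                                      pThreshold = 0.05) {
  y <- .counts(se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  N <- colSums(y)
  f <- if (is.null(normFactors)) rep(1, ncol(y)) else
    as.numeric(normFactors[colnames(y)])
  eff <- N * f
  out <- list()
  for (eco in unique(cd$ecotype)) {
    times <- unique(cd$time[cd$ecotype == eco])
    for (tp in times) {
      trt <- cd$sample_id[cd$ecotype == eco & cd$time == tp &
                            cd$condition == "treated"]
      ctl <- cd$sample_id[cd$ecotype == eco & cd$time == tp &
                            cd$condition == "control"]
      if (length(trt) < 2L || length(ctl) < 2L) next
      de <- nbExactTest(y[, trt, drop = FALSE], y[, ctl, drop = FALSE],
                        libSizes = eff[c(trt, ctl)],
                        dispersion = dispersion)
      de <- callDegs(de, fcThreshold, pThreshold)
      de$ecotype <- eco
      de$time <- tp
      out[[length(out) + 1L]] <- de
    }
  }
  if (!length(out)) stop("no (ecotype, time) contrast had 2+ replicates per group")
  res <- do.call(rbind, out)
  res[, c("gene", "ecotype", "time", "log2fc", "pvalue", "is_deg")]
}

#' Select stress-affected and stress-responding genes
#'
#' Per ecotype, a gene is stress affected if it is a DEG at two or more
#' time points; the stress-affected genes are ranked by their minimum
#' p-value over their DEG time points (or the mean, see \code{rankBy}) and
#' the top \code{perEcotypeCap} are kept. The union over ecotypes is the
#' stress-responding set, partitioned into TFs and TGs by the TF list.
#' Ties at the cap boundary are broken by gene id.
#'
#' @param de data.frame from \code{\link{runDifferentialExpression}}.
#' @param tfList character vector of TF gene ids.
#' @param perEcotypeCap maximum stress-affected genes kept per ecotype
#'   (default 1500).
#' @param minDegTimepoints minimum number of DEG time points (default 2).
#' @param rankBy "min" (default) or "mean" p-value over DEG time points.
#' @return a \linkS4class{StressGeneSets}.
#' @export
selectStressGenes <- function(de, tfList, perEcotypeCap = 1500L,
                              minDegTimepoints = 2L,
                              rankBy = c("min", "mean")) {
  rankBy <- match.arg(rankBy)
  affected <- list()
  for (eco in sort(unique(de$ecotype))) {
    d <- de[de$ecotype == eco & de$is_deg, , drop = FALSE]
    if (!nrow(d)) { affected[[eco]] <- character(); next }
    ntp <- tapply(d$time, d$gene, function(t) length(unique(t)))
    elig <- names(ntp)[ntp >= minDegTimepoints]
    if (!length(elig)) { affected[[eco]] <- character(); next }
    score <- tapply(d$pvalue, d$gene,
                    if (rankBy == "min") min else mean)[elig]
    ord <- order(score, elig)
    affected[[eco]] <- elig[ord][seq_len(min(perEcotypeCap, length(elig)))]
  }
  responding <- sort(unique(unlist(affected)))
  methods::new("StressGeneSets",
               stressAffected = affected,
               stressResponding = responding,
               tfs = intersect(responding, tfList),
               tgs = setdiff(responding, tfList))
}
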