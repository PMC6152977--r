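# GO term over-representation: classic hypergeometric and the elim
# variant that discounts genes claimed by significant descendants.

# propagate gene -> term annotations to all ancestors (true-path rule)
.propagateAnnotations <- function(annotations, dag) {
  anc <- lapply(setNames(termIds(dag), termIds(dag)), .ancestorsOf,
                dag = dag)
  byTerm <- split(annotations$gene, annotations$go_id)
  genesOf <- lapply(setNames(termIds(dag), termIds(dag)),
                    function(t) character())
  for (t in names(byTerm)) {
    if (!t %in% termIds(dag)) next
    for (u in c(t, anc[[t]]))
      genesOf[[u]] <- c(genesOf[[u]], byTerm[[t]])
  }
  lapply(genesOf, unique)
}

#' GO term enrichment
#'
#' Hypergeometric over-representation of a study gene set against an
#' annotated background. Annotations are propagated to ancestors before
#' testing (true-path rule). With \code{algorithm = "classic"} every term
#' is tested independently; with \code{"elim"} terms are processed bottom
#' up and, whenever a term's p-value falls below \code{elimThreshold},
#' its annotated study genes are removed from all its ancestors before
#' those are tested, so a parent is never reported purely on the strength
#' of genes already claimed by a significant child.
#'
#' @param study character vector of study genes (must be inside
#'   \code{background}).
#' @param annotations data.frame gene, go_id.
#' @param dag a \linkS4class{GoDag}.
#' @param background character vector: the annotated gene universe.
#' @param algorithm "classic" (default) or "elim".
#' @param alpha enrichment call threshold on the raw p-value (default
#'   0.01).
#' @param elimThreshold p-value below which a term's genes are eliminated
#'   from its ancestors (elim only; default 0.01).
#' @return data.frame term, name, k (study hits), n (study size), K (term
#'   genes in background), N (background size), pvalue, enriched,
#'   algorithm; terms with K = 0 are skipped.
#' @export
goEnrichment <- function(study, annotations, dag, background,
                         algorithm = c("classic", "elim"), alpha = 0.01,
                         elimThreshold = 0.01) {
  algorithm <- match.arg(algorithm)
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background))
    stop("study genes must be a subset of the background")
  if (!length(study))
    return(data.frame(term = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), pvalue = numeric(),
                      enriched = logical(), algorithm = character()))
  genesOf <- .propagateAnnotations(annotations, dag)
  genesOf <- lapply(genesOf, intersect, background)
  N <- length(background); n <- length(study)
  nameOf <- setNames(dag@terms$name, dag@terms$id)
  lev <- .termLevels(dag)
  order_terms <- names(sort(lev, decreasing = TRUE))  # leaves first
  eliminated <- lapply(setNames(termIds(dag), termIds(dag)),
                       function(t) character())
  rows <- list()
  for (t in order_terms) {
    gs <- setdiff(genesOf[[t]], eliminated[[t]])
    K <- length(gs)
    if (K == 0L) next
    k <- length(intersect(study, gs))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[t]] <- data.frame(term = t, name = unname(nameOf[t]), k = k,
                            n = n, K = K, N = N, pvalue = p,
                            enriched = p < alpha, algorithm = algorithm,
                            stringsAsFactors = FALSE)
    if (algorithm == "elim" && p < elimThreshold) {
      claimed <- intersect(study, gs)
      for (a in .ancestorsOf(dag, t))
        eliminated[[a]] <- union(eliminated[[a]], claimed)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
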