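# Wang GO semantic similarity, gene-level best-match-average aggregation,
# functional-relevance validation with a randomized background, and the
# saturation (knee) cutoff analysis.

# S-values of all ancestors of `term` (including itself): S(term) = 1,
# S(a) = max over children c of a inside the ancestor closure of
# w(edge) * S(c), memoized recursion down the DAG.
.wangSvalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag@terms$id) stop("term not in DAG: ", term)
  anc <- c(term, .ancestorsOf(dag, term))
  env <- new.env(parent = emptyenv())
  assign(term, 1, envir = env)
  calc <- function(a) {
    got <- get0(a, envir = env, ifnotfound = NULL)
    if (!is.null(got)) return(got)
    ch <- dag@children[[a]]
    ch <- ch[ch$child %in% anc, , drop = FALSE]
    s <- max(vapply(seq_len(nrow(ch)), function(i)
      weights[[ch$type[i]]] * calc(ch$child[i]), numeric(1)))
    assign(a, s, envir = env)
    s
  }
  setNames(vapply(anc, calc, numeric(1)), anc)
}

#' Wang semantic similarity between two GO terms
#'
#' Graph-based similarity: each term's semantic contributions S decay
#' along child-to-parent edges (factor 0.8 for is_a, 0.6 for part_of,
#' taking the best path), and the similarity is the summed contribution of
#' the shared ancestors (including the terms themselves) relative to the
#' two terms' total semantic values.
#'
#' @param t1,t2 term ids present in \code{dag}.
#' @param dag a \linkS4class{GoDag}.
#' @param weights named edge-decay factors for is_a and part_of.
#' @return similarity in (0, 1]; 1 iff the terms coincide (for terms whose
#'   ancestor closures are equal).
#' @export
wangSimilarity <- function(t1, t2, dag,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- .wangSvalues(dag, t1, weights)
  s2 <- .wangSvalues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# pairwise Wang similarity for a set of terms
.termSimMatrix <- function(dag, terms,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  terms <- unique(terms)
  sv <- lapply(setNames(terms, terms), .wangSvalues, dag = dag,
               weights = weights)
  n <- length(terms)
  M <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      common <- intersect(names(sv[[i]]), names(sv[[j]]))
      M[i, j] <- M[j, i] <-
        sum(sv[[i]][common] + sv[[j]][common]) / (sum(sv[[i]]) + sum(sv[[j]]))
    }
  M
}

#' Gene-level GO similarity (best-match average)
#'
#' Aggregates term similarities over the two genes' BP annotation sets:
#' the mean of the row maxima and column maxima of the term-similarity
#' matrix.
#'
#' @param g1,g2 gene ids with at least one annotation each.
#' @param annotations data.frame with columns gene, go_id.
#' @param dag a \linkS4class{GoDag}.
#' @param termSim optional precomputed term-similarity matrix covering all
#'   annotated terms (from internal batching); computed on the fly if NULL.
#' @return similarity in [0, 1].
#' @export
geneSimilarity <- function(g1, g2, annotations, dag, termSim = NULL) {
  ts1 <- unique(annotations$go_id[annotations$gene == g1])
  ts2 <- unique(annotations$go_id[annotations$gene == g2])
  if (!length(ts1) || !length(ts2))
    stop("gene without BP annotation: ", if (!length(ts1)) g1 else g2)
  if (is.null(termSim)) termSim <- .termSimMatrix(dag, unique(c(ts1, ts2)))
  M <- termSim[ts1, ts2, drop = FALSE]
  (sum(apply(M, 1L, max)) + sum(apply(M, 2L, max))) / (nrow(M) + ncol(M))
}

.pairwiseGeneSims <- function(genes, annByGene, termSim) {
  n <- length(genes)
  M <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  diag(M) <- 1
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      S <- termSim[annByGene[[genes[i]]], annByGene[[genes[j]]],
                   drop = FALSE]
      M[i, j] <- M[j, i] <-
        (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) /
        (nrow(S) + ncol(S))
    }
  M
}

#' Functional-relevance validation of predicted targets
#'
#' For every TF of the final network with at least two annotated targets,
#' computes the pairwise gene similarities among its targets; an edge
#' TF -> g is validated when the mean similarity of g to the TF's other
#' annotated targets reaches \code{cutoff} (mode "edge"), or when the
#' TF-level Wilcoxon test is significant (mode "tf", which then validates
#' all the TF's annotated edges). The background consists of
#' \code{nBackground} random same-size gene sets drawn from the annotated
#' background universe; a one-sided Wilcoxon rank-sum test (exact for
#' pooled n <= 25, normal approximation with continuity and tie
#' correction otherwise) asks whether the TF's target similarities exceed
#' the background's.
#'
#' @param net a \linkS4class{Grn} at stage "final".
#' @param annotations data.frame gene, go_id (BP).
#' @param dag a \linkS4class{GoDag}.
#' @param cutoff similarity cutoff for edge validation (default 0.3).
#' @param nBackground number of random background sets (default 1000).
#' @param background character vector: the annotated gene universe.
#' @param seed RNG seed for the background draws.
#' @param mode "edge" (default) or "tf"; see above.
#' @return list with elements perTf (list: targets, simMatrix,
#'   meanSimilarity, wilcoxonP), validatedEdges (data.frame tf, tg,
#'   funct_validated), pooledTargetSims, pooledBackgroundSims.
#' @export
functionalRelevance <- function(net, annotations, dag, cutoff = 0.3,
                                nBackground = 1000L, background,
                                seed = 1L, mode = c("edge", "tf")) {
  mode <- match.arg(mode)
  stopifnot(networkStage(net) == "final")
  edges <- edgeTable(net)
  annotations <- annotations[annotations$gene %in% background, ,
                             drop = FALSE]
  annByGene <- split(unique(annotations[, c("gene", "go_id")])$go_id,
                     unique(annotations[, c("gene", "go_id")])$gene)
  annGenes <- names(annByGene)
  termSim <- .termSimMatrix(dag, unique(annotations$go_id))
  perTf <- list()
  pooledT <- numeric()
  valEdges <- edges[, c("tf", "tg")]
  valEdges$funct_validated <- FALSE
  .withSeed(seed, {
    for (tf in sort(unique(edges$tf))) {
      tgt <- intersect(edges$tg[edges$tf == tf], annGenes)
      if (length(tgt) < 2L) {
        message("TF ", tf, " has < 2 annotated targets; skipped")
        next
      }
      M <- .pairwiseGeneSims(tgt, annByGene, termSim)
      off <- M[upper.tri(M)]
      meanToOthers <- (rowSums(M) - 1) / (length(tgt) - 1L)
      # background: random same-size sets from the annotated universe
      bg <- numeric()
      for (b in seq_len(nBackground)) {
        draw <- sample(annGenes, length(tgt))
        B <- .pairwiseGeneSims(draw, annByGene, termSim)
        bg <- c(bg, B[upper.tri(B)])
      }
      nPool <- length(off) + length(bg)
      wp <- suppressWarnings(wilcox.test(
        off, bg, alternative = "greater",
        exact = nPool <= 25L, correct = TRUE)$p.value)
      perTf[[tf]] <- list(targets = tgt, simMatrix = M,
                          meanSimilarity = mean(off),
                          meanToOthers = meanToOthers,
                          backgroundSims = bg, wilcoxonP = wp)
      pooledT <- c(pooledT, off)
      sel <- valEdges$tf == tf & valEdges$tg %in% tgt
      if (mode == "edge") {
        okTg <- names(meanToOthers)[meanToOthers >= cutoff]
        valEdges$funct_validated[valEdges$tf == tf &
                                   valEdges$tg %in% okTg] <- TRUE
      } else if (wp < 0.05) {
        valEdges$funct_validated[sel] <- TRUE
      }
    }
  })
  pooledBg <- unlist(lapply(perTf, `[[`, "backgroundSims"), use.names = FALSE)
  list(perTf = perTf, validatedEdges = valEdges,
       pooledTargetSims = pooledT, pooledBackgroundSims = pooledBg)
}

#' Saturation (knee) analysis of a similarity pool
#'
#' Computes the fraction of similarities retained at each cutoff of the
#' grid and returns the knee of that curve: the grid point with maximum
#' distance to the chord joining the curve's endpoints. Advisory only; the
#' pipeline default cutoff stays 0.3.
#'
#' @param pool numeric vector of similarity values.
#' @param grid cutoff grid (default seq(0, 1, 0.05)).
#' @return list with elements cutoff (a member of the grid), retained
#'   (fraction per grid point).
#' @export
saturationCutoff <- function(pool, grid = seq(0, 1, by = 0.05)) {
  if (!length(pool)) stop("empty similarity pool")
  retained <- vapply(grid, function(c) mean(pool >= c), numeric(1))
  if (diff(range(retained)) == 0) {
    warning("constant retained-fraction curve; returning the grid minimum")
    return(list(cutoff = min(grid), retained = retained))
  }
  x0 <- grid[1]; y0 <- retained[1]
  x1 <- grid[length(grid)]; y1 <- retained[length(retained)]
  num <- abs((y1 - y0) * grid - (x1 - x0) * retained + x1 * y0 - y1 * x0)
  d <- num / sqrt((y1 - y0)^2 + (x1 - x0)^2)
  list(cutoff = grid[which.max(d)], retained = retained)
}
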