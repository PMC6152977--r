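#' stressGRN: regulatory network inference from time-course stress RNA-seq
#'
#' The package re-implements, at a desk-testable scale, a complete pipeline
#' for inferring stress-response gene regulatory networks from time-course
#' RNA-seq counts: TMM/CPM normalization, NB exact-test differential
#' expression, PCC co-expression network construction, Network Component
#' Analysis (NCA) decomposition under identifiability constraints,
#' orthology- and GO-semantic-similarity-based validation, a
#' Gaussian-emission temporal model with bifurcation events, and GO
#' enrichment. A seeded synthetic-data generator plants the full ground
#' truth so every stage can be verified.
#'
#' @import methods
#' @importFrom stats cor dnorm dnbinom dbinom dpois kmeans median phyper
#'   quantile rbinom rnbinom rpois runif rnorm sd setNames var wilcox.test
#'   ks.test
#' @importFrom utils head read.delim write.table packageVersion
#' @name stressGRN-package
#' @aliases stressGRN
"_PACKAGE"

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic study: a planted bipartite TF-to-target
#' network driving negative-binomial counts for two ecotypes under a
#' treated/control design with replicated time points, optionally with a
#' planted trajectory bifurcation.
#'
#' @slot nTfs number of transcription factors.
#' @slot nTgs number of target genes (genes may end up unregulated and act
#'   as background).
#' @slot nTimepoints number of time points (the study designs use 6 or 8).
#' @slot nReplicates biological replicates per condition/time (>= 2).
#' @slot nEcotypes number of ecotypes simulated as independent
#'   parameterizations sharing the gene universe.
#' @slot nHousekeeping spike-in genes with condition-independent means.
#' @slot edgeDensity Bernoulli probability of a TF-target edge, in (0,1).
#' @slot dispersion NB dispersion phi >= 0 (variance = mu + phi mu^2);
#'   phi = 0 gives Poisson counts.
#' @slot librarySizeRange min/max of per-sample sequencing depth.
#' @slot bifurcationTime time index (1-based, NA for none) from which two
#'   planted gene groups diverge.
#' @slot seed master seed; all generation is deterministic given it.
#' @export
setClass("SimulationConfig",
  slots = c(
    nTfs = "integer", nTgs = "integer", nTimepoints = "integer",
    nReplicates = "integer", nEcotypes = "integer", nHousekeeping = "integer",
    edgeDensity = "numeric", dispersion = "numeric",
    librarySizeRange = "numeric", bifurcationTime = "integer",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTfs < 1L) msg <- c(msg, "nTfs must be >= 1")
  if (object@nTgs < 1L) msg <- c(msg, "nTgs must be >= 1")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (object@nEcotypes < 1L) msg <- c(msg, "nEcotypes must be >= 1")
  if (!(object@edgeDensity > 0 && object@edgeDensity <= 1))
    msg <- c(msg, "edgeDensity must be in (0, 1]")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "librarySizeRange must be an increasing positive pair")
  if (!is.na(object@bifurcationTime) &&
      (object@bifurcationTime < 2L ||
       object@bifurcationTime > object@nTimepoints))
    msg <- c(msg, "bifurcationTime must lie in 2..nTimepoints")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ConnectivityMatrix / TFAMatrix
# ---------------------------------------------------------------------------

#' Signed sparse connectivity matrix (the NCA "A")
#'
#' Target genes in rows, TFs in columns. The binary support encodes which
#' regulatory edges exist; the weights are the signed control strengths,
#' nonzero exactly on the support.
#'
#' @slot weights numeric matrix with complete unique dimnames; zero entries
#'   are absent edges.
#' @export
setClass("ConnectivityMatrix", slots = c(weights = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (is.null(rownames(w)) || is.null(colnames(w)))
    msg <- c(msg, "weights must carry target-gene rownames and TF colnames")
  else {
    if (anyDuplicated(rownames(w))) msg <- c(msg, "duplicate target ids")
    if (anyDuplicated(colnames(w))) msg <- c(msg, "duplicate TF ids")
  }
  if (!all(is.finite(w))) msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' TF activity matrix (the NCA "P")
#'
#' TFs in rows, samples in columns; each row is the latent activity profile
#' of one TF across the samples, distinct from the TF's own expression.
#'
#' @slot activities numeric matrix with TF rownames and sample colnames.
#' @export
setClass("TFAMatrix", slots = c(activities = "matrix"))

setValidity("TFAMatrix", function(object) {
  a <- object@activities
  msg <- character()
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "activities must carry TF rownames and sample colnames")
  if (!all(is.finite(a))) msg <- c(msg, "activities must be finite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Grn
# ---------------------------------------------------------------------------

#' Bipartite TF-target regulatory network
#'
#' An edge list with the Pearson correlation (pcc), the NCA control
#' strength (cs, NA before decomposition) and the interaction sign
#' ("+" for pcc > 0, "-" for pcc < 0), together with the processing stage:
#' "initial" (PCC thresholding), "nca" (pruned + decomposed) or "final"
#' (high-confidence PCC re-thresholding).
#'
#' @slot edges data.frame with columns tf, tg, pcc, cs, sign.
#' @slot stage character, one of "initial", "nca", "final".
#' @slot pccCut numeric, the |PCC| threshold that produced this stage.
#' @export
setClass("Grn",
  slots = c(edges = "data.frame", stage = "character", pccCut = "numeric"))

setValidity("Grn", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("tf", "tg", "pcc", "cs", "sign")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (!object@stage %in% c("initial", "nca", "final"))
    msg <- c(msg, "stage must be initial, nca or final")
  if (nrow(e)) {
    if (any(abs(e$pcc) > 1 + 1e-12)) msg <- c(msg, "pcc out of [-1, 1]")
    bad <- e$sign != ifelse(e$pcc > 0, "+", "-")
    if (any(bad)) msg <- c(msg, "sign must follow the sign of pcc")
    if (anyDuplicated(paste(e$tf, e$tg))) msg <- c(msg, "duplicate edges")
    if (object@stage == "final" &&
        any(abs(e$pcc) < object@pccCut - 1e-12))
      msg <- c(msg, "final-stage edges must satisfy |pcc| >= pccCut")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Planted ground truth of a simulation
#'
#' @slot connectivity planted \linkS4class{ConnectivityMatrix}.
#' @slot tfa list of planted \linkS4class{TFAMatrix}, one per ecotype,
#'   columns = time points.
#' @slot bifurcation list with elements time (index or NA), tfGroups and
#'   tgGroups (two-level factor partitions).
#' @slot orthologTruth data.frame (tf, tg) of edges planted as transferable.
#' @slot goTruth named list mapping each TF to the GO term its true targets
#'   are annotated under.
#' @export
setClass("GroundTruth",
  slots = c(connectivity = "ConnectivityMatrix", tfa = "list",
            bifurcation = "list", orthologTruth = "data.frame",
            goTruth = "list"))

setValidity("GroundTruth", function(object) {
  w <- object@connectivity@weights
  msg <- character()
  ntarg <- colSums(w != 0)
  if (any(ntarg < 2L))
    msg <- c(msg, "every planted TF must have >= 2 targets")
  supp <- w != 0
  if (ncol(supp) > 1L) {
    key <- apply(supp, 2L, paste, collapse = "")
    if (anyDuplicated(key))
      msg <- c(msg, "planted TFs must not share identical target sets")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# StressGeneSets
# ---------------------------------------------------------------------------

#' Stress-affected and stress-responding gene selections
#'
#' @slot stressAffected named list (per ecotype) of genes that are DEGs at
#'   two or more time points, capped at the per-ecotype limit.
#' @slot stressResponding union of the per-ecotype selections.
#' @slot tfs members of stressResponding present in the TF list.
#' @slot tgs the remaining stressResponding genes.
#' @export
setClass("StressGeneSets",
  slots = c(stressAffected = "list", stressResponding = "character",
            tfs = "character", tgs = "character"))

setValidity("StressGeneSets", function(object) {
  msg <- character()
  if (length(intersect(object@tfs, object@tgs)))
    msg <- c(msg, "tfs and tgs must be disjoint")
  if (!setequal(c(object@tfs, object@tgs), object@stressResponding))
    msg <- c(msg, "tfs and tgs must partition stressResponding")
  if (!setequal(unique(unlist(object@stressAffected)),
                object@stressResponding))
    msg <- c(msg, "stressResponding must be the union over ecotypes")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TemporalMap
# ---------------------------------------------------------------------------

#' Tree-structured Gaussian-emission temporal map
#'
#' A dynamic regulatory map: one node per (time, branch) with a Gaussian
#' emission over log2 fold change, edges between consecutive time points,
#' at most two children per node (a bifurcation event), and per-gene path
#' posteriors over the root-to-leaf chains.
#'
#' @slot nodes data.frame with columns id, time (0-based index; 0 is the
#'   artificial start node), mu, var.
#' @slot edges data.frame with columns parent, child (node ids).
#' @slot paths list of integer node-id vectors, root to leaf.
#' @slot posteriors numeric matrix genes x paths, rows summing to one.
#' @slot assignmentVec named integer vector of hard path assignments.
#' @slot times character labels of the time points (including t0).
#' @slot logLik final observed-data log-likelihood.
#' @slot bic BIC of the accepted structure.
#' @slot varFloor variance floor used in fitting.
#' @export
setClass("TemporalMap",
  slots = c(nodes = "data.frame", edges = "data.frame", paths = "list",
            posteriors = "matrix", assignmentVec = "integer",
            times = "character", logLik = "numeric", bic = "numeric",
            varFloor = "numeric"))

setValidity("TemporalMap", function(object) {
  msg <- character()
  if (nrow(object@posteriors)) {
    rs <- rowSums(object@posteriors)
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "path posteriors must sum to 1 per gene")
  }
  if (any(object@nodes$var < object@varFloor - 1e-12))
    msg <- c(msg, "node variances must respect the floor")
  if (nrow(object@edges)) {
    nch <- table(object@edges$parent)
    if (any(nch > 2L)) msg <- c(msg, "nodes may have at most two children")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GoDag
# ---------------------------------------------------------------------------

#' Gene Ontology DAG (minimal)
#'
#' Directed acyclic graph of GO terms with typed child-to-parent edges
#' (is_a, part_of), as used for Wang semantic similarity and enrichment.
#'
#' @slot terms data.frame with columns id, name.
#' @slot edges data.frame with columns child, parent, type.
#' @slot parents named list: term id -> data.frame(parent, type).
#' @slot children named list: term id -> data.frame(child, type).
#' @slot roots character vector of terms without parents.
#' @export
setClass("GoDag",
  slots = c(terms = "data.frame", edges = "data.frame", parents = "list",
            children = "list", roots = "character"))

setValidity("GoDag", function(object) {
  msg <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate term ids")
  e <- object@edges
  if (nrow(e)) {
    if (!all(c(e$child, e$parent) %in% ids))
      msg <- c(msg, "edge endpoints must be known terms")
    if (!all(e$type %in% c("is_a", "part_of")))
      msg <- c(msg, "edge types must be is_a or part_of")
    g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                       vertices = ids)
    if (!igraph::is_dag(g)) msg <- c(msg, "ontology graph must be acyclic")
    else {
      nonroot <- setdiff(ids, object@roots)
      if (length(nonroot) && length(object@roots)) {
        d <- igraph::distances(g, v = nonroot, to = object@roots,
                               mode = "out")
        if (any(!is.finite(apply(d, 1L, min))))
          msg <- c(msg, "every non-root term must reach a root")
      }
    }
  }
  if (length(msg)) msg else TRUE
})
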