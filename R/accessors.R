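# Accessor and show methods for the S4 containers.

#' @describeIn ConnectivityMatrix TF ids (column names).
#' @param x,object a ConnectivityMatrix.
#' @export
setMethod("tfIds", "ConnectivityMatrix", function(x) colnames(x@weights))

#' @describeIn ConnectivityMatrix target-gene ids (row names).
#' @export
setMethod("tgIds", "ConnectivityMatrix", function(x) rownames(x@weights))

#' @describeIn ConnectivityMatrix binary support (weights != 0).
#' @export
setMethod("support", "ConnectivityMatrix", function(x) x@weights != 0)

#' @describeIn ConnectivityMatrix signed control-strength matrix.
#' @export
setMethod("controlStrengths", "ConnectivityMatrix", function(x) x@weights)

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights
  cat(sprintf("ConnectivityMatrix: %d targets x %d TFs, %d edges (density %.3f)\n",
              nrow(w), ncol(w), sum(w != 0),
              sum(w != 0) / max(1, length(w))))
})

#' @describeIn TFAMatrix TF ids (row names).
#' @param x,object a TFAMatrix.
#' @export
setMethod("tfIds", "TFAMatrix", function(x) rownames(x@activities))

#' @describeIn TFAMatrix the activity matrix itself.
#' @export
setMethod("activities", "TFAMatrix", function(x) x@activities)

setMethod("show", "TFAMatrix", function(object) {
  a <- object@activities
  cat(sprintf("TFAMatrix: %d TFs x %d samples\n", nrow(a), ncol(a)))
})

#' @describeIn Grn edge data.frame (tf, tg, pcc, cs, sign).
#' @param x,object a Grn.
#' @export
setMethod("edgeTable", "Grn", function(x) x@edges)

#' @describeIn Grn processing stage.
#' @export
setMethod("networkStage", "Grn", function(x) x@stage)

#' @describeIn Grn TFs appearing in at least one edge.
#' @export
setMethod("tfIds", "Grn", function(x) sort(unique(x@edges$tf)))

#' @describeIn Grn target genes appearing in at least one edge.
#' @export
setMethod("tgIds", "Grn", function(x) sort(unique(x@edges$tg)))

#' @describeIn Grn binary support matrix built from the edge list.
#' @export
setMethod("support", "Grn", function(x) {
  tfs <- tfIds(x); tgs <- tgIds(x)
  m <- matrix(FALSE, length(tgs), length(tfs), dimnames = list(tgs, tfs))
  if (nrow(x@edges)) m[cbind(x@edges$tg, x@edges$tf)] <- TRUE
  m
})

setMethod("show", "Grn", function(object) {
  e <- object@edges
  cat(sprintf("Grn [stage %s]: %d TFs, %d targets, %d edges (%d +, %d -)\n",
              object@stage, length(unique(e$tf)), length(unique(e$tg)),
              nrow(e), sum(e$sign == "+"), sum(e$sign == "-")))
})

#' @describeIn GroundTruth planted TF ids.
#' @param x,object a GroundTruth.
#' @export
setMethod("tfIds", "GroundTruth", function(x) tfIds(x@connectivity))

#' @describeIn GroundTruth planted target-gene ids.
#' @export
setMethod("tgIds", "GroundTruth", function(x) tgIds(x@connectivity))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  show(object@connectivity)
  bt <- object@bifurcation$time
  cat(sprintf("  ecotypes: %d; bifurcation at time index: %s\n",
              length(object@tfa), if (is.na(bt)) "none" else bt))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d TFs, %d TGs, %d time points x %d replicates,",
    " %d ecotypes\n  edge density %.2f, dispersion %.3f, library sizes",
    " [%g, %g], bifurcation %s, seed %d\n"),
    object@nTfs, object@nTgs, object@nTimepoints, object@nReplicates,
    object@nEcotypes, object@edgeDensity, object@dispersion,
    object@librarySizeRange[1], object@librarySizeRange[2],
    if (is.na(object@bifurcationTime)) "none" else object@bifurcationTime,
    object@seed))
})

setMethod("show", "StressGeneSets", function(object) {
  cat(sprintf("StressGeneSets: %d stress-responding genes (%d TFs, %d TGs)\n",
              length(object@stressResponding), length(object@tfs),
              length(object@tgs)))
  for (e in names(object@stressAffected))
    cat(sprintf("  %s: %d stress-affected\n", e,
                length(object@stressAffected[[e]])))
})

#' @describeIn TemporalMap root-to-leaf node-id paths.
#' @param x,object a TemporalMap.
#' @export
setMethod("pathList", "TemporalMap", function(x) x@paths)

#' @describeIn TemporalMap hard (max-posterior) path assignment per gene.
#' @export
setMethod("assignments", "TemporalMap", function(x) x@assignmentVec)

#' @describeIn TemporalMap per-gene path posterior matrix.
#' @export
setMethod("posteriors", "TemporalMap", function(x) x@posteriors)

#' @describeIn TemporalMap ids of nodes with two children.
#' @export
setMethod("splitNodes", "TemporalMap", function(x) {
  if (!nrow(x@edges)) return(integer())
  tab <- table(x@edges$parent)
  as.integer(names(tab)[tab == 2L])
})

setMethod("show", "TemporalMap", function(object) {
  cat(sprintf(paste0("TemporalMap: %d nodes over %d time points, %d chains,",
                     " %d bifurcation(s); logLik %.2f, BIC %.2f\n"),
              nrow(object@nodes), length(object@times),
              length(object@paths), length(splitNodes(object)),
              object@logLik, object@bic))
})

#' @describeIn GoDag term ids.
#' @param x,object a GoDag.
#' @export
setMethod("termIds", "GoDag", function(x) x@terms$id)

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag: %d terms, %d edges (%d is_a, %d part_of), %d root(s)\n",
              nrow(object@terms), nrow(object@edges),
              sum(object@edges$type == "is_a"),
              sum(object@edges$type == "part_of"), length(object@roots)))
})
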