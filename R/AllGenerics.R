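#' Transcription-factor identifiers of an object
#'
#' @param x a \linkS4class{ConnectivityMatrix}, \linkS4class{TFAMatrix},
#'   \linkS4class{Grn} or \linkS4class{GroundTruth}.
#' @return character vector of TF ids.
#' @export
setGeneric("tfIds", function(x) standardGeneric("tfIds"))

#' Target-gene identifiers of an object
#'
#' @param x a \linkS4class{ConnectivityMatrix}, \linkS4class{Grn} or
#'   \linkS4class{GroundTruth}.
#' @return character vector of target-gene ids.
#' @export
setGeneric("tgIds", function(x) standardGeneric("tgIds"))

#' Binary support of a connectivity matrix
#'
#' @param x a \linkS4class{ConnectivityMatrix} or \linkS4class{Grn}.
#' @return logical matrix, target genes in rows and TFs in columns, TRUE
#'   where a regulatory edge is present.
#' @export
setGeneric("support", function(x) standardGeneric("support"))

#' Signed edge weights (control strengths)
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return numeric matrix, nonzero exactly on the support.
#' @export
setGeneric("controlStrengths", function(x) standardGeneric("controlStrengths"))

#' TF activity profiles
#'
#' @param x a \linkS4class{TFAMatrix}.
#' @return numeric matrix, TFs in rows and samples in columns.
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' Edge table of a regulatory network
#'
#' @param x a \linkS4class{Grn}.
#' @return data.frame with columns tf, tg, pcc, cs, sign.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Processing stage of a network
#'
#' @param x a \linkS4class{Grn}.
#' @return one of "initial", "nca", "final".
#' @export
setGeneric("networkStage", function(x) standardGeneric("networkStage"))

#' Root-to-leaf paths of a temporal map
#'
#' @param x a \linkS4class{TemporalMap}.
#' @return list of integer vectors of node ids, one per chain.
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' Hard path assignments of a temporal map
#'
#' @param x a \linkS4class{TemporalMap}.
#' @return named integer vector mapping each gene to its maximum-posterior
#'   path index.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' Per-gene path posteriors of a temporal map
#'
#' @param x a \linkS4class{TemporalMap}.
#' @return numeric matrix genes x paths; rows sum to one.
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' Bifurcation (split) nodes of a temporal map
#'
#' @param x a \linkS4class{TemporalMap}.
#' @return integer vector of node ids that have two children.
#' @export
setGeneric("splitNodes", function(x) standardGeneric("splitNodes"))

#' Term identifiers of an ontology DAG
#'
#' @param x a \linkS4class{GoDag}.
#' @return character vector of term ids.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
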