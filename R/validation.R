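# Orthology-transfer validation of predicted TF-target interactions.

#' Validate predicted edges by ortholog transfer
#'
#' An edge (tf, tg) is validated when some reference interaction source
#' contains a pair (tf_ref, tg_ref) in one reference species such that
#' tf_ref is an ortholog of tf and tg_ref an ortholog of tg. Co-orthologs
#' (a query gene mapping to several reference genes) are allowed, and
#' duplicated reference rows have no effect on the counts.
#'
#' @param net a \linkS4class{Grn}.
#' @param orthologMap data.frame with columns query_gene, ref_species,
#'   ref_gene (group_id optional).
#' @param referenceSets data.frame with columns source, ref_species, tf,
#'   target.
#' @return list with elements edges (the edge table with a logical
#'   orthology_validated column and the supporting sources) and perSource
#'   (data.frame source, n_validated, n_tfs — validated edges and the
#'   distinct TFs involved per source).
#' @export
validateByOrthology <- function(net, orthologMap, referenceSets) {
  edges <- edgeTable(net)
  refs <- unique(referenceSets[, c("source", "ref_species", "tf", "target")])
  orth <- unique(orthologMap[, c("query_gene", "ref_species", "ref_gene")])
  orthKey <- split(paste(orth$ref_species, orth$ref_gene), orth$query_gene)
  edges$orthology_validated <- FALSE
  edges$orthology_sources <- ""
  perSourceEdges <- setNames(vector("list", length(unique(refs$source))),
                             sort(unique(refs$source)))
  if (nrow(edges) && nrow(refs)) {
    refKey <- paste(refs$ref_species, refs$tf, refs$ref_species, refs$target)
    for (i in seq_len(nrow(edges))) {
      otf <- orthKey[[edges$tf[i]]]
      otg <- orthKey[[edges$tg[i]]]
      if (is.null(otf) || is.null(otg)) next
      combos <- as.vector(outer(otf, otg, paste))
      hit <- refKey %in% combos
      if (any(hit)) {
        srcs <- sort(unique(refs$source[hit]))
        edges$orthology_validated[i] <- TRUE
        edges$orthology_sources[i] <- paste(srcs, collapse = ",")
        for (s in srcs)
          perSourceEdges[[s]] <- rbind(perSourceEdges[[s]],
                                       edges[i, c("tf", "tg")])
      }
    }
  }
  perSource <- data.frame(
    source = names(perSourceEdges),
    n_validated = vapply(perSourceEdges, function(d)
      if (is.null(d)) 0L else nrow(d), 1L),
    n_tfs = vapply(perSourceEdges, function(d)
      if (is.null(d)) 0L else length(unique(d$tf)), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(edges = edges, perSource = perSource)
}
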