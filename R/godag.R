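# Minimal GO DAG container, OBO subset reader/writer, ancestor utilities.

#' Construct a GoDag
#'
#' @param terms data.frame with columns id, name.
#' @param edges data.frame with columns child, parent, type ("is_a" or
#'   "part_of"); may be empty.
#' @return a validated \linkS4class{GoDag}.
#' @export
goDag <- function(terms, edges) {
  terms <- data.frame(id = as.character(terms$id),
                      name = as.character(terms$name),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(child = character(), parent = character(),
                        type = character(), stringsAsFactors = FALSE)
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  parents <- lapply(setNames(terms$id, terms$id), function(id) {
    e <- edges[edges$child == id, c("parent", "type"), drop = FALSE]
    rownames(e) <- NULL; e
  })
  children <- lapply(setNames(terms$id, terms$id), function(id) {
    e <- edges[edges$parent == id, c("child", "type"), drop = FALSE]
    rownames(e) <- NULL; e
  })
  roots <- terms$id[vapply(parents[terms$id], nrow, 1L) == 0L]
  methods::new("GoDag", terms = terms, edges = edges, parents = parents,
               children = children, roots = roots)
}

#' Read a minimal OBO file
#'
#' Parses the OBO subset used by the pipeline: \code{[Term]} stanzas with
#' \code{id}, \code{name}, \code{is_a} and \code{relationship: part_of}
#' lines; everything else is ignored.
#'
#' @param path OBO file.
#' @return a \linkS4class{GoDag}.
#' @export
readObo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "#")]
    getField <- function(key) {
      hit <- chunk[startsWith(chunk, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", hit))
    }
    id <- getField("id")[1]
    if (is.na(id)) next
    nm <- getField("name")
    terms[[length(terms) + 1L]] <-
      data.frame(id = id, name = if (length(nm)) nm[1] else id)
    isa <- sub("\\s*!.*$", "", getField("is_a"))
    for (p in isa)
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = p, type = "is_a")
    rel <- getField("relationship")
    rel <- rel[startsWith(rel, "part_of")]
    for (p in trimws(sub("\\s*!.*$", "", sub("^part_of", "", rel))))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = p, type = "part_of")
  }
  goDag(do.call(rbind, terms),
        if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Write a minimal OBO file
#'
#' @param dag a \linkS4class{GoDag}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  nameOf <- setNames(dag@terms$name, dag@terms$id)
  for (id in dag@terms$id) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", nameOf[id])), con)
    p <- dag@parents[[id]]
    if (nrow(p)) {
      isa <- p$parent[p$type == "is_a"]
      po <- p$parent[p$type == "part_of"]
      for (x in isa)
        writeLines(sprintf("is_a: %s ! %s", x, nameOf[x]), con)
      for (x in po)
        writeLines(sprintf("relationship: part_of %s ! %s", x, nameOf[x]),
                   con)
    }
  }
  invisible(path)
}

# all ancestors of a term (excluding itself), memoized per call
.ancestorsOf <- function(dag, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(lapply(frontier, function(t) dag@parents[[t]]$parent)))
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps)
    frontier <- ps
  }
  seen
}

# term depth levels (root = 0), via longest path from a root
.termLevels <- function(dag) {
  g <- igraph::graph_from_data_frame(dag@edges[, c("child", "parent")],
                                     vertices = dag@terms$id)
  ord <- igraph::topo_sort(g, mode = "in")   # parents before children
  lev <- setNames(rep(0L, nrow(dag@terms)), dag@terms$id)
  for (v in names(ord)) {
    p <- dag@parents[[v]]$parent
    if (length(p)) lev[v] <- max(lev[p]) + 1L
  }
  lev
}
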