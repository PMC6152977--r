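# DREM-style dynamic regulatory map: tree-structured Gaussian-emission
# model over log2 fold-change trajectories, greedy bifurcation search
# scored by BIC, EM for parameters, and hypergeometric TF split scores.

#' Build log2 fold-change trajectories
#'
#' Assembles the genes x times trajectory matrix for one ecotype from the
#' differential-expression table, prepending an artificial all-zero
#' column at t0 so every gene has a fold change at time point zero.
#'
#' @param de data.frame with columns gene, ecotype, time, log2fc (one
#'   ecotype's rows are used).
#' @param ecotype which ecotype to extract.
#' @param genes optional restriction (e.g. the final network's targets);
#'   defaults to all genes present.
#' @return numeric matrix genes x (T+1) with column names "t0", then the
#'   sorted time labels.
#' @export
buildTrajectories <- function(de, ecotype, genes = NULL) {
  d <- de[de$ecotype == ecotype, , drop = FALSE]
  if (!nrow(d)) stop("no rows for ecotype ", ecotype)
  if (is.null(genes)) genes <- sort(unique(d$gene))
  times <- sort(unique(d$time))
  M <- matrix(NA_real_, length(genes), length(times),
              dimnames = list(genes, sprintf("t%s", times)))
  d <- d[d$gene %in% genes, , drop = FALSE]
  M[cbind(match(d$gene, genes), match(d$time, times))] <- d$log2fc
  if (anyNA(M)) {
    gaps <- which(is.na(M), arr.ind = TRUE)
    stop("missing (gene, time) fold changes, e.g. ",
         paste(sprintf("%s@%s", rownames(M)[gaps[, 1]],
                       colnames(M)[gaps[, 2]])[seq_len(min(5, nrow(gaps)))],
               collapse = ", "))
  }
  cbind(t0 = 0, M)
}

.tmPaths <- function(nodes, edges) {
  childrenOf <- function(id) sort(edges$child[edges$parent == id])
  root <- nodes$id[nodes$time == 0L]
  stopifnot(length(root) == 1L)
  out <- list()
  walk <- function(path, id) {
    ch <- childrenOf(id)
    if (!length(ch)) out[[length(out) + 1L]] <<- c(path, id)
    else for (c in ch) walk(c(path, id), c)
  }
  walk(integer(), root)
  out
}

# EM for fixed tree structure; x is genes x (T+1), nodes/edges the tree
.tmEM <- function(x, nodes, edges, varFloor, maxIter = 500L, tol = 1e-8) {
  paths <- .tmPaths(nodes, edges)
  Np <- length(paths)
  pathRows <- lapply(paths, function(p) match(p, nodes$id))
  contains <- matrix(0, Np, nrow(nodes))          # path x node
  for (p in seq_len(Np)) contains[p, pathRows[[p]]] <- 1
  tx <- t(x)                                      # (T+1) x genes
  ll <- -Inf
  llTrace <- numeric()
  r <- NULL
  for (iter in seq_len(maxIter)) {
    L <- vapply(seq_len(Np), function(p) {
      rows <- pathRows[[p]]
      colSums(dnorm(tx, nodes$mu[rows], sqrt(nodes$var[rows]), log = TRUE))
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) L <- matrix(L, nrow = 1L)
    m <- apply(L, 1L, max)
    W <- exp(L - m)
    denom <- rowSums(W)
    r <- W / denom
    newll <- sum(m + log(denom)) - nrow(x) * log(Np)
    llTrace <- c(llTrace, newll)
    nodeW <- r %*% contains                       # genes x node
    for (vi in seq_len(nrow(nodes))) {
      w <- nodeW[, vi]
      sw <- sum(w)
      if (sw <= 0) { nodes$var[vi] <- varFloor; next }
      col <- x[, nodes$time[vi] + 1L]
      mu <- sum(w * col) / sw
      nodes$mu[vi] <- mu
      nodes$var[vi] <- max(varFloor, sum(w * (col - mu)^2) / sw)
    }
    if (is.finite(ll) && abs(newll - ll) <= tol * max(1, abs(newll))) {
      ll <- newll; break
    }
    ll <- newll
  }
  dimnames(r) <- list(rownames(x), NULL)
  list(nodes = nodes, edges = edges, paths = paths, posteriors = r,
       logLik = ll, llTrace = llTrace)
}

.tmBic <- function(fit, nGenes) -2 * fit$logLik +
  2 * nrow(fit$nodes) * log(nGenes)

# duplicate the subtree rooted at `childId`, returning new nodes/edges and
# the id of the copy's root
.tmCopySubtree <- function(nodes, edges, childId, nextId) {
  ids <- childId
  frontier <- childId
  while (length(frontier)) {
    nxt <- edges$child[edges$parent %in% frontier]
    ids <- c(ids, nxt); frontier <- nxt
  }
  newIds <- setNames(nextId + seq_along(ids) - 1L, ids)
  sub <- nodes[match(ids, nodes$id), , drop = FALSE]
  sub$id <- as.integer(newIds[as.character(ids)])
  se <- edges[edges$parent %in% ids & edges$child %in% ids, , drop = FALSE]
  if (nrow(se)) {
    se$parent <- as.integer(newIds[as.character(se$parent)])
    se$child <- as.integer(newIds[as.character(se$child)])
  }
  list(nodes = sub, edges = se, root = unname(newIds[as.character(childId)]))
}

#' Fit a temporal map with bifurcation search
#'
#' Starts from a single chain (one Gaussian node per time point,
#' initialized at the column mean/variance) and proposes, for each node
#' in time order, replacing the node's child subtree by two copies whose
#' entry nodes are initialized by a deterministic 2-means on the member
#' genes' values at that time. Each proposal re-fits the whole tree by
#' EM (E: per-gene posteriors over root-to-leaf paths under equal path
#' priors; M: posterior-weighted node means/variances with a variance
#' floor); a split is acceptable iff BIC = -2 logL + 2 #nodes ln(#genes)
#' improves and both children keep at least \code{minGenes} expected
#' members, and the best acceptable split of each scan is taken (so the
#' bifurcation lands at the latest time that explains the divergence,
#' which costs the fewest duplicated nodes). The search stops when no
#' split improves.
#'
#' @param traj trajectory matrix from \code{\link{buildTrajectories}}
#'   (genes x times, first column the artificial t0).
#' @param varFloor lower bound on node variances (default 1e-3).
#' @param minGenes minimum expected members per new child (default 5).
#' @param seed RNG seed (the fit is deterministic given it).
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return a \linkS4class{TemporalMap}.
#' @export
fitTemporalMap <- function(traj, varFloor = 1e-3, minGenes = 5L,
                           seed = 1L, maxIter = 500L, tol = 1e-8) {
  x <- as.matrix(traj)
  if (ncol(x) < 4L) stop("need at least 3 measured time points plus t0")
  if (nrow(x) < 20L) stop("need at least 20 genes")
  T1 <- ncol(x)
  nodes <- data.frame(id = seq_len(T1), time = 0:(T1 - 1L),
                      mu = colMeans(x),
                      var = pmax(varFloor, apply(x, 2L, var)))
  rownames(nodes) <- NULL
  edges <- data.frame(parent = seq_len(T1 - 1L), child = 2:T1)
  fit <- .tmEM(x, nodes, edges, varFloor, maxIter, tol)
  bic <- .tmBic(fit, nrow(x))
  .withSeed(seed, {
    repeat {
      improved <- FALSE
      best <- list(fit = NULL, bic = bic)
      nodes <- fit$nodes; edges <- fit$edges
      hard <- apply(fit$posteriors, 1L, which.max)
      ord <- nodes$id[order(nodes$time, nodes$id)]
      for (u in ord) {
        tU <- nodes$time[nodes$id == u]
        if (tU >= T1 - 1L) next
        ch <- edges$child[edges$parent == u]
        if (length(ch) != 1L) next
        onU <- vapply(fit$paths, function(p) u %in% p, logical(1))
        members <- rownames(x)[hard %in% which(onU)]
        if (length(members) < 2L * minGenes) next
        tC <- nodes$time[nodes$id == ch]
        vals <- x[members, tC + 1L]
        ctrs <- unname(quantile(vals, c(0.25, 0.75)))
        if (diff(ctrs) < 1e-9) next
        km <- suppressWarnings(
          kmeans(vals, centers = matrix(ctrs, 2L, 1L)))
        if (min(km$size) < minGenes) next
        cp1 <- .tmCopySubtree(nodes, edges, ch, max(nodes$id) + 1L)
        cp2 <- .tmCopySubtree(nodes, edges, ch,
                              max(cp1$nodes$id) + 1L)
        centers <- sort(km$centers[, 1L])
        cp1$nodes$mu[cp1$nodes$id == cp1$root] <- centers[1L]
        cp2$nodes$mu[cp2$nodes$id == cp2$root] <- centers[2L]
        # drop the old subtree, graft the two copies
        dropIds <- setdiff(c(ch, .tmDescendants(edges, ch)), integer())
        pn <- rbind(nodes[!nodes$id %in% dropIds, , drop = FALSE],
                    cp1$nodes, cp2$nodes)
        pe <- rbind(edges[!(edges$parent %in% c(u, dropIds) |
                              edges$child %in% dropIds), , drop = FALSE],
                    edges[edges$parent == u & edges$child != ch, ,
                          drop = FALSE],
                    data.frame(parent = u, child = c(cp1$root, cp2$root)),
                    cp1$edges, cp2$edges)
        pfit <- .tmEM(x, pn, pe, varFloor, maxIter, tol)
        pbic <- .tmBic(pfit, nrow(x))
        # expected members of the two new entry nodes
        expMembers <- vapply(c(cp1$root, cp2$root), function(id) {
          onN <- vapply(pfit$paths, function(p) id %in% p, logical(1))
          sum(pfit$posteriors[, onN, drop = FALSE])
        }, numeric(1))
        if (pbic < best$bic - 1e-9 && min(expMembers) >= minGenes)
          best <- list(fit = pfit, bic = pbic)
      }
      if (is.null(best$fit)) break
      fit <- best$fit; bic <- best$bic; improved <- TRUE
    }
  })
  hard <- as.integer(apply(fit$posteriors, 1L, which.max))
  names(hard) <- rownames(x)
  methods::new("TemporalMap",
               nodes = fit$nodes[order(fit$nodes$time, fit$nodes$id), ],
               edges = fit$edges, paths = fit$paths,
               posteriors = fit$posteriors,
               assignmentVec = hard,
               times = colnames(x), logLik = fit$logLik, bic = bic,
               varFloor = varFloor)
}

.tmDescendants <- function(edges, id) {
  out <- integer(); frontier <- id
  while (length(frontier)) {
    nxt <- edges$child[edges$parent %in% frontier]
    out <- c(out, nxt); frontier <- nxt
  }
  out
}

#' Hypergeometric TF split scores at bifurcation nodes
#'
#' For each bifurcation node, the universe is the set of genes whose hard
#' path passes through that node, split between its two children. For
#' each TF of the network, the split score is the smaller of the two
#' hypergeometric upper-tail probabilities of seeing at least the
#' observed number of the TF's targets in each child; TFs scoring below
#' the cutoff are reported with the branch their targets concentrate in.
#'
#' @param map a fitted \linkS4class{TemporalMap} with at least one split.
#' @param net a \linkS4class{Grn} (its edge list defines TF target sets).
#' @param cutoff report threshold on the split score (default 0.001).
#' @return data.frame node, time, tf, K (targets in universe), split_score,
#'   branch (child node id), reported.
#' @export
scoreSplits <- function(map, net, cutoff = 0.001) {
  splits <- splitNodes(map)
  if (!length(splits)) stop("map has no bifurcation nodes")
  edges <- edgeTable(net)
  genes <- rownames(posteriors(map))
  hard <- assignments(map)
  paths <- pathList(map)
  onNode <- function(id) {
    onN <- vapply(paths, function(p) id %in% p, logical(1))
    genes[hard %in% which(onN)]
  }
  rows <- list()
  for (u in splits) {
    universe <- onNode(u)
    ch <- sort(map@edges$child[map@edges$parent == u])
    g1 <- intersect(onNode(ch[1L]), universe)
    g2 <- intersect(onNode(ch[2L]), universe)
    N <- length(universe); n1 <- length(g1); n2 <- length(g2)
    tU <- map@nodes$time[map@nodes$id == u]
    for (tf in sort(unique(edges$tf))) {
      tgt <- intersect(edges$tg[edges$tf == tf], universe)
      K <- length(tgt)
      if (K == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          node = u, time = tU, tf = tf, K = 0L, split_score = 1,
          branch = NA_integer_, reported = FALSE)
        next
      }
      k1 <- length(intersect(tgt, g1))
      k2 <- length(intersect(tgt, g2))
      p1 <- phyper(k1 - 1L, K, N - K, n1, lower.tail = FALSE)
      p2 <- phyper(k2 - 1L, K, N - K, n2, lower.tail = FALSE)
      sc <- min(p1, p2)
      rows[[length(rows) + 1L]] <- data.frame(
        node = u, time = tU, tf = tf, K = K, split_score = sc,
        branch = if (p1 <= p2) ch[1L] else ch[2L],
        reported = sc < cutoff)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chain summary of a temporal map
#'
#' For every root-to-leaf chain: its member genes (hard assignment), the
#' posterior-weighted mean trajectory (the y-values of a dynamic
#' regulatory map figure), the TFs whose split scores select this chain's
#' branch at bifurcations along it, and optional attached GO enrichments.
#'
#' @param map a fitted \linkS4class{TemporalMap}.
#' @param traj the trajectory matrix the map was fitted on.
#' @param splitScores optional result of \code{\link{scoreSplits}}.
#' @param enrichments optional list of per-chain enrichment tables
#'   (index = chain).
#' @return list of per-chain lists (chain, nodes, members, meanTrajectory,
#'   regulatingTfs, enrichment); serializes losslessly to JSON.
#' @export
chainSummary <- function(map, traj, splitScores = NULL,
                         enrichments = NULL) {
  r <- posteriors(map)
  x <- as.matrix(traj)[rownames(r), , drop = FALSE]
  genes <- rownames(r)
  hard <- assignments(map)
  out <- vector("list", length(map@paths))
  for (p in seq_along(map@paths)) {
    members <- genes[hard == p]
    w <- r[, p]
    mt <- if (sum(w) > 0) colSums(x * w) / sum(w) else colMeans(x)
    names(mt) <- map@times
    tfs <- character()
    if (!is.null(splitScores) && nrow(splitScores)) {
      onPath <- splitScores$node %in% map@paths[[p]] &
        splitScores$branch %in% map@paths[[p]] & splitScores$reported
      tfs <- sort(unique(splitScores$tf[onPath]))
    }
    out[[p]] <- list(chain = p,
                     nodes = map@paths[[p]],
                     members = members,
                     meanTrajectory = as.list(mt),
                     regulatingTfs = tfs,
                     enrichment = if (!is.null(enrichments))
                       enrichments[[p]] else NULL)
  }
  out
}
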