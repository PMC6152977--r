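# PCC co-expression network, NCA identifiability, pruning, and the
# alternating-least-squares decomposition X ~ A %*% P.

.newGrn <- function(edges, stage, pccCut) {
  if (!nrow(edges))
    edges <- data.frame(tf = character(), tg = character(),
                        pcc = numeric(), cs = numeric(),
                        sign = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  methods::new("Grn", edges = edges, stage = stage, pccCut = pccCut)
}

#' Initial PCC co-expression network
#'
#' Builds the bipartite TF-to-target network: an edge is present iff the
#' absolute Pearson correlation between the TF's and the target's
#' expression profiles exceeds \code{threshold}. The signed PCC is kept;
#' positive interactions are activations (sign "+"), negative repressions
#' (sign "-"). Self pairs and TF-TF pairs are never considered.
#'
#' @param expr numeric expression matrix (typically log2(CPM+1)), genes in
#'   rows, samples in columns.
#' @param tfs,tgs gene ids of the TFs and candidate targets (rows of
#'   \code{expr}); overlap is resolved in favour of the TF role.
#' @param threshold absolute-PCC cutoff, strict (default 0.70).
#' @return a \linkS4class{Grn} at stage "initial".
#' @export
pccNetwork <- function(expr, tfs, tgs, threshold = 0.70) {
  if (ncol(expr) < 3L) stop("at least 3 samples are needed for PCC")
  tgs <- setdiff(tgs, tfs)
  tfs <- intersect(tfs, rownames(expr))
  tgs <- intersect(tgs, rownames(expr))
  if (!length(tfs) || !length(tgs)) stop("no TF or no TG rows in expr")
  v <- apply(expr[c(tfs, tgs), , drop = FALSE], 1L, var)
  dead <- names(v)[v == 0]
  if (length(dead)) {
    warning(sprintf("dropping %d zero-variance gene(s)", length(dead)))
    tfs <- setdiff(tfs, dead); tgs <- setdiff(tgs, dead)
  }
  C <- cor(t(expr[tfs, , drop = FALSE]), t(expr[tgs, , drop = FALSE]))
  hit <- which(abs(C) > threshold, arr.ind = TRUE)
  edges <- data.frame(tf = tfs[hit[, 1L]], tg = tgs[hit[, 2L]],
                      pcc = C[hit], cs = NA_real_,
                      sign = ifelse(C[hit] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$tg), , drop = FALSE]
  .newGrn(edges, "initial", threshold)
}

# generic rank of a binary pattern: rank of a random real instantiation
# (fixed stream), which equals the generic rank almost surely
.genericRank <- function(support, seed = 1L) {
  if (!sum(support)) return(0L)
  vals <- matrix(0, nrow(support), ncol(support))
  vals[support] <- .withSeed(seed, runif(sum(support), 0.5, 1.5))
  qr(vals)$rank
}

#' Check NCA identifiability of a support pattern
#'
#' Evaluates the two structural identifiability criteria on the binary
#' connectivity support (targets x TFs): (1) the support has full column
#' rank generically; (2) for every TF, deleting its column together with
#' all targets it regulates leaves a pattern of full column rank. (The
#' third criterion, full row rank of the activity matrix, is a property of
#' the recovered P and is reported by \code{\link{ncaDecompose}}.)
#'
#' @param support logical or 0/1 matrix, targets in rows, TFs in columns.
#' @param seed seed for the generic-rank instantiation.
#' @return list with elements pass (logical), fullColumnRank (logical) and
#'   violatingTfs (character).
#' @export
checkIdentifiability <- function(support, seed = 1L) {
  support <- support != 0
  if (!length(support) || !ncol(support)) stop("support must be nonempty")
  if (is.null(colnames(support)))
    colnames(support) <- paste0("TF", seq_len(ncol(support)))
  k <- ncol(support)
  fullRank <- .genericRank(support, seed) == k
  violators <- character()
  for (j in seq_len(k)) {
    keepRows <- !support[, j]
    sub <- support[keepRows, -j, drop = FALSE]
    if (ncol(sub) == 0L) next
    if (.genericRank(sub, seed) < ncol(sub))
      violators <- c(violators, colnames(support)[j])
  }
  list(pass = fullRank && !length(violators),
       fullColumnRank = fullRank, violatingTfs = violators)
}

.grnSupport <- function(edges) {
  tfs <- sort(unique(edges$tf)); tgs <- sort(unique(edges$tg))
  m <- matrix(FALSE, length(tgs), length(tfs), dimnames = list(tgs, tfs))
  m[cbind(edges$tg, edges$tf)] <- TRUE
  m
}

#' Prune a network to NCA identifiability
#'
#' Iteratively removes TFs until the support satisfies the identifiability
#' criteria: (a) TFs with fewer than \code{minTargets} targets; (b) among
#' TFs with identical target sets, all but the one with the largest mean
#' |PCC| (ties by id); (c) if the identifiability check still fails, the
#' violating TF whose removal discards the fewest edges (ties by id).
#'
#' @param net a \linkS4class{Grn} at stage "initial".
#' @param minTargets minimum targets per TF (default 2).
#' @param seed seed passed to \code{\link{checkIdentifiability}}.
#' @return list with elements net (the pruned \linkS4class{Grn}, still
#'   stage "initial") and removed (character vector of TF ids).
#' @export
pruneForNca <- function(net, minTargets = 2L, seed = 1L) {
  stopifnot(networkStage(net) == "initial")
  edges <- edgeTable(net)
  removed <- character()
  drop_tfs <- function(edges, tfs) edges[!edges$tf %in% tfs, , drop = FALSE]
  repeat {
    if (!nrow(edges)) stop("pruning removed every TF; no identifiable core")
    ntarg <- table(edges$tf)
    few <- names(ntarg)[ntarg < minTargets]
    if (length(few)) {
      removed <- c(removed, few); edges <- drop_tfs(edges, few); next
    }
    supp <- .grnSupport(edges)
    key <- apply(supp, 2L, paste, collapse = "")
    dup <- split(colnames(supp), key)
    dup <- dup[vapply(dup, length, 1L) > 1L]
    if (length(dup)) {
      meanAbs <- tapply(abs(edges$pcc), edges$tf, mean)
      lose <- unlist(lapply(dup, function(tfset) {
        tfset <- tfset[order(-meanAbs[tfset], tfset)]
        tfset[-1L]
      }), use.names = FALSE)
      removed <- c(removed, lose); edges <- drop_tfs(edges, lose); next
    }
    idr <- checkIdentifiability(supp, seed)
    if (idr$pass) break
    cand <- if (length(idr$violatingTfs)) idr$violatingTfs else colnames(supp)
    lost <- vapply(cand, function(tf) sum(edges$tf == tf), 1L)
    worst <- cand[order(lost, cand)][1L]
    removed <- c(removed, worst); edges <- drop_tfs(edges, worst)
  }
  list(net = .newGrn(edges, "initial", net@pccCut), removed = removed)
}

.lsSolve <- function(M, B, ridge = 1e-8) {
  # solve M %*% Z = B in least squares with a ridge fallback
  out <- tryCatch(qr.solve(M, B), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    warning("rank-deficient least-squares subproblem; ridge fallback")
    MtM <- crossprod(M) + diag(ridge, ncol(M))
    out <- solve(MtM, crossprod(M, B))
  }
  out
}

#' NCA decomposition by alternating least squares
#'
#' Minimizes \code{||X - A P||_F^2} over the signed connectivity A (fixed
#' sparse support) and the TF activity matrix P. Holding the support
#' fixed, P is solved by least squares given A, then each target row of A
#' is solved over its incident TFs given P. After each sweep every A
#' column is rescaled to unit Euclidean norm (the scale absorbed into the
#' matching P row) with the sign fixed so the column's largest-magnitude
#' entry is positive, resolving the scale/sign ambiguity. A is initialized
#' with the signed PCC values on the support.
#'
#' @param expr expression matrix restricted to the network's target genes
#'   (rows are centered internally), samples in columns.
#' @param net a pruned \linkS4class{Grn} that passes
#'   \code{\link{checkIdentifiability}}.
#' @param tol relative objective-decrease stopping threshold.
#' @param maxIter maximum ALS sweeps.
#' @param seed seed (used by the identifiability instantiation).
#' @param center center target rows before fitting (default TRUE).
#' @return list with elements connectivity
#'   (\linkS4class{ConnectivityMatrix}), tfa (\linkS4class{TFAMatrix}),
#'   net (a \linkS4class{Grn} at stage "nca" with cs filled in), trace
#'   (objective per sweep, non-increasing) and pRankOk (logical: recovered
#'   P has full numerical row rank).
#' @export
ncaDecompose <- function(expr, net, tol = 1e-6, maxIter = 1000L,
                         seed = 1L, center = TRUE) {
  edges <- edgeTable(net)
  if (!nrow(edges)) stop("empty network")
  supp <- .grnSupport(edges)
  idr <- checkIdentifiability(supp, seed)
  if (!idr$pass)
    stop("network is not NCA-identifiable; run pruneForNca first")
  tgs <- rownames(supp); tfs <- colnames(supp)
  missing <- setdiff(tgs, rownames(expr))
  if (length(missing)) stop("expr lacks target rows: ",
                            paste(head(missing, 5L), collapse = ", "))
  X <- expr[tgs, , drop = FALSE]
  if (center) X <- X - rowMeans(X)
  A <- matrix(0, length(tgs), length(tfs), dimnames = dimnames(supp))
  A[cbind(edges$tg, edges$tf)] <- edges$pcc
  rowsOf <- lapply(seq_along(tfs), function(j) which(supp[, j]))
  tfsOf <- lapply(seq_along(tgs), function(i) which(supp[i, ]))
  obj <- function(A, P) sum((X - A %*% P)^2)
  P <- .lsSolve(A, X)
  trace <- obj(A, P)
  for (it in seq_len(maxIter)) {
    # A-update: per target row over incident TFs
    for (i in seq_along(tgs)) {
      jj <- tfsOf[[i]]
      Pi <- P[jj, , drop = FALSE]
      G <- tcrossprod(Pi)
      a <- tryCatch(solve(G, Pi %*% X[i, ]), error = function(e) NULL)
      if (is.null(a)) a <- solve(G + diag(1e-8, nrow(G)), Pi %*% X[i, ])
      A[i, ] <- 0; A[i, jj] <- a
    }
    # P-update
    P <- .lsSolve(A, X)
    # normalize columns of A, absorb into P, fix signs
    for (j in seq_along(tfs)) {
      s <- sqrt(sum(A[, j]^2))
      if (s > 0) { A[, j] <- A[, j] / s; P[j, ] <- P[j, ] * s }
      jmax <- which.max(abs(A[, j]))
      if (length(jmax) && A[jmax, j] < 0) {
        A[, j] <- -A[, j]; P[j, ] <- -P[j, ]
      }
    }
    trace <- c(trace, obj(A, P))
    n <- length(trace)
    if (abs(trace[n - 1L] - trace[n]) <=
        tol * max(trace[n - 1L], .Machine$double.eps)) break
  }
  dimnames(P) <- list(tfs, colnames(X))
  edges$cs <- A[cbind(edges$tg, edges$tf)]
  pRank <- qr(P, tol = 1e-8)$rank
  list(connectivity = methods::new("ConnectivityMatrix", weights = A),
       tfa = methods::new("TFAMatrix", activities = P),
       net = .newGrn(edges, "nca", net@pccCut),
       trace = trace,
       pRankOk = pRank == nrow(P))
}

#' Final high-confidence edge calling
#'
#' Keeps the NCA-stage edges whose absolute Pearson correlation between TF
#' and target expression is at least \code{pccCut} (inclusive boundary);
#' signs follow the PCC. The final edge set is always nested inside the
#' initial one.
#'
#' @param net a \linkS4class{Grn} at stage "nca".
#' @param expr expression matrix containing both TF and target rows.
#' @param pccCut inclusive |PCC| threshold (default 0.75).
#' @return a \linkS4class{Grn} at stage "final".
#' @export
finalEdges <- function(net, expr, pccCut = 0.75) {
  stopifnot(networkStage(net) == "nca")
  edges <- edgeTable(net)
  if (nrow(edges)) {
    pcc <- vapply(seq_len(nrow(edges)), function(i)
      cor(expr[edges$tf[i], ], expr[edges$tg[i], ]), numeric(1))
    edges$pcc <- pcc
    edges$sign <- ifelse(pcc > 0, "+", "-")
    edges <- edges[abs(edges$pcc) >= pccCut - 1e-12, , drop = FALSE]
  }
  .newGrn(edges, "final", pccCut)
}
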