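# Shared fixtures and independent oracles for the test suite.
# Expensive objects (the default simulated study and its pipeline run) are
# built once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

defaultSim <- function() cached("sim", function() simulateStudy())

# the full pipeline on the default study, stage objects kept
defaultPipeline <- function() cached("pipeline", function() {
  sim <- defaultSim()
  se <- sim$se
  nf <- tmmFactors(se)
  kept <- expressionFilter(se, 2, 0.9, nf)
  de <- runDifferentialExpression(kept, nf)
  sets <- selectStressGenes(de, tfIds(sim$network))
  expr <- log2(cpmMatrix(kept, nf) + 1)
  net0 <- pccNetwork(expr, sets@tfs, sets@tgs, 0.70)
  pruned <- suppressWarnings(pruneForNca(net0))
  dec <- ncaDecompose(expr, pruned$net, seed = 1)
  netF <- finalEdges(dec$net, expr, 0.75)
  list(sim = sim, se = se, nf = nf, kept = kept, de = de, sets = sets,
       expr = expr, net0 = net0, pruned = pruned, dec = dec, netF = netF)
})

plantedEdgeKeys <- function(sim) {
  w <- controlStrengths(sim$network)
  hit <- which(w != 0, arr.ind = TRUE)
  paste(colnames(w)[hit[, 2]], rownames(w)[hit[, 1]])
}

edgeKeys <- function(net) {
  e <- edgeTable(net)
  paste(e$tf, e$tg)
}

# --- independent oracles ---------------------------------------------------

# TMM factors recomputed step by step without reusing package internals
oracleTmm <- function(y, logratioTrim = 0.30, sumTrim = 0.05) {
  N <- colSums(y)
  q75 <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) q75[j] <- quantile(y[, j], 0.75) / N[j]
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    if (j == ref) { f[j] <- 1; next }
    Ms <- c(); As <- c(); ws <- c()
    for (g in seq_len(nrow(y))) {
      yj <- y[g, j]; yr <- y[g, ref]
      if (yj <= 0 || yr <= 0) next
      Ms <- c(Ms, log2((yj / N[j]) / (yr / N[ref])))
      As <- c(As, 0.5 * log2((yj / N[j]) * (yr / N[ref])))
      ws <- c(ws, 1 / ((N[j] - yj) / (N[j] * yj) +
                         (N[ref] - yr) / (N[ref] * yr)))
    }
    n <- length(Ms)
    rM <- rank(Ms); rA <- rank(As)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- 2^(sum(ws[keep] * Ms[keep]) / sum(ws[keep]))
  }
  f / exp(mean(log(f)))
}

# Wang S-values by iterative fixpoint relaxation (not recursion)
oracleWang <- function(t1, t2, dag, w = c(is_a = 0.8, part_of = 0.6)) {
  svals <- function(t) {
    ids <- dag@terms$id
    S <- setNames(rep(-Inf, length(ids)), ids)
    S[t] <- 1
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(dag@edges))) {
        ch <- dag@edges$child[i]; pa <- dag@edges$parent[i]
        cand <- w[[dag@edges$type[i]]] * S[ch]
        if (cand > S[pa] + 1e-15) { S[pa] <- cand; changed <- TRUE }
      }
      if (!changed) break
    }
    S[is.finite(S)]
  }
  s1 <- svals(t1); s2 <- svals(t2)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# exact hypergeometric upper tail P(X >= k) by log-space enumeration
oracleHyperTail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# a small random DAG for similarity property tests
randomDag <- function(nTerms, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(nTerms))
  edges <- NULL
  for (i in 2:nTerms) {
    nPar <- sample(1:min(2, i - 1), 1)
    pars <- sample(ids[seq_len(i - 1)], nPar)
    edges <- rbind(edges, data.frame(
      child = ids[i], parent = pars,
      type = sample(c("is_a", "part_of"), nPar, replace = TRUE)))
  }
  goDag(data.frame(id = ids, name = ids), edges)
}

# two-node chain DAG used by several hand-computed examples
chainDag <- function() {
  goDag(data.frame(id = c("GO:R", "GO:C"), name = c("root", "child")),
        data.frame(child = "GO:C", parent = "GO:R", type = "is_a"))
}
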