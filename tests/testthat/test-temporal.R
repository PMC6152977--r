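# Trajectory assembly, tree-HMM fitting, bifurcation recovery and TF
# split scores.

test_that("trajectories get a zero t0 column and detect gaps", {
  de <- expand.grid(gene = c("g1", "g2"), time = 1:3)
  de$ecotype <- "E1"; de$log2fc <- c(0, 1, 0, 2, 0, 3)
  M <- buildTrajectories(de, "E1")
  expect_equal(unname(M[, "t0"]), c(0, 0))
  expect_equal(dim(M), c(2L, 4L))
  expect_error(buildTrajectories(de[-1, ], "E1"), "missing")
  # flat gene stays flat
  deFlat <- de; deFlat$log2fc <- 0
  expect_true(all(buildTrajectories(deFlat, "E1") == 0))
  # TSV round trip is lossless
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(M), M, check.names = FALSE), f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(f, check.names = FALSE)
  M2 <- as.matrix(back[, -1]); rownames(M2) <- back$gene
  expect_equal(M2, M)
})

test_that("homogeneous data yields a single chain", {
  set.seed(5)
  x <- cbind(0, matrix(rnorm(60 * 5, mean = rep(c(1, 2, 1, 0, -1),
                                                each = 60), sd = 0.3),
                       60, 5))
  dimnames(x) <- list(paste0("g", 1:60), c("t0", paste0("t", 1:5)))
  map <- fitTemporalMap(x, seed = 1)
  expect_length(pathList(map), 1L)
  expect_length(splitNodes(map), 0L)
  expect_equal(unname(assignments(map)), rep(1L, 60))
})

test_that("a planted divergence is located exactly with clean assignment", {
  sim <- defaultSim()
  for (sd in 1:3) {
    fx <- bifurcationTrajectories(sim$truth, nGenes = 120, noiseSd = 0.35,
                                  seed = sd)
    map <- fitTemporalMap(fx$values, seed = sd)
    sp <- splitNodes(map)
    expect_length(sp, 1L)
    # divergence starts at measured time bt, so the split node sits at bt-1
    expect_equal(map@nodes$time[map@nodes$id == sp],
                 sim$truth@bifurcation$time - 1L)
    tab <- table(fx$groups, assignments(map))
    expect_gte(sum(apply(tab, 2, max)) / 120, 0.95)
  }
})

test_that("EM log-likelihood never decreases within a structure", {
  set.seed(6)
  x <- cbind(0, matrix(rnorm(80 * 4), 80, 4))
  dimnames(x) <- list(paste0("g", 1:80), c("t0", paste0("t", 1:4)))
  nodes <- data.frame(id = 1:5, time = 0:4, mu = colMeans(x),
                      var = pmax(1e-3, apply(x, 2, var)))
  edges <- data.frame(parent = 1:4, child = 2:5)
  fit <- stressGRN:::.tmEM(x, nodes, edges, varFloor = 1e-3)
  expect_true(all(diff(fit$llTrace) >= -1e-8))
  # posteriors are normalized per gene
  expect_equal(unname(rowSums(fit$posteriors)), rep(1, 80))
})

test_that("split scores match exact combinatorial enumeration", {
  sim <- defaultSim()
  fx <- bifurcationTrajectories(sim$truth, nGenes = 100, noiseSd = 0.3,
                                seed = 2)
  map <- fitTemporalMap(fx$values, seed = 2)
  # synthetic TF target sets against the fitted 50/50 split
  g1 <- names(fx$groups)[fx$groups == 1L]
  g2 <- names(fx$groups)[fx$groups == 2L]
  ed <- rbind(
    data.frame(tf = "TFone", tg = g1[1:10], pcc = 0.9, cs = 1, sign = "+"),
    data.frame(tf = "TFprop", tg = c(g1[11:15], g2[1:5]), pcc = 0.9,
               cs = 1, sign = "+"))
  net <- stressGRN:::.newGrn(ed, "final", 0.75)
  sc <- scoreSplits(map, net, cutoff = 0.001)
  one <- sc[sc$tf == "TFone", ]
  prop <- sc[sc$tf == "TFprop", ]
  # all 10 targets in one branch of a 50/50 split of 100 genes
  expect_equal(one$split_score,
               prod((50 - 0:9) / (100 - 0:9)), tolerance = 1e-9)
  expect_true(one$reported)
  expect_false(prop$reported)
  expect_gt(prop$split_score, 0.1)
  # every reported score agrees with the log-space enumeration oracle
  universe <- rownames(posteriors(map))
  for (i in seq_len(nrow(sc))) {
    tgt <- intersect(ed$tg[ed$tf == sc$tf[i]], universe)
    if (!length(tgt)) next
    hard <- assignments(map)
    onCh <- function(id) {
      onN <- vapply(pathList(map), function(p) id %in% p, logical(1))
      universe[hard %in% which(onN)]
    }
    ch <- sort(map@edges$child[map@edges$parent == sc$node[i]])
    o <- min(oracleHyperTail(length(intersect(tgt, onCh(ch[1]))),
                             length(universe), length(tgt),
                             length(onCh(ch[1]))),
             oracleHyperTail(length(intersect(tgt, onCh(ch[2]))),
                             length(universe), length(tgt),
                             length(onCh(ch[2]))))
    expect_equal(sc$split_score[i], o, tolerance = 1e-9)
  }
  # a TF with no targets in the universe scores 1
  edK <- rbind(ed, data.frame(tf = "TFnone", tg = "absent_gene", pcc = 0.9,
                              cs = 1, sign = "+"))
  scK <- scoreSplits(map, stressGRN:::.newGrn(edK, "final", 0.75))
  expect_equal(scK$split_score[scK$tf == "TFnone"], 1)
  expect_false(scK$reported[scK$tf == "TFnone"])
})

test_that("chain summaries report weighted mean trajectories losslessly", {
  set.seed(9)
  x <- cbind(0, matrix(rnorm(40 * 4, mean = 1, sd = 0.2), 40, 4))
  dimnames(x) <- list(paste0("g", 1:40), c("t0", paste0("t", 1:4)))
  map <- fitTemporalMap(x, seed = 1)
  ch <- chainSummary(map, x)
  expect_length(ch, 1L)
  expect_setequal(ch[[1]]$members, rownames(x))
  r <- posteriors(map)[, 1]
  want <- colSums(x * r) / sum(r)
  expect_equal(unlist(ch[[1]]$meanTrajectory), setNames(want, map@times))
  # JSON round trip
  js <- jsonlite::toJSON(ch, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(unlist(back[[1]]$meanTrajectory),
               unlist(ch[[1]]$meanTrajectory), tolerance = 1e-12)
  expect_equal(unlist(back[[1]]$members), ch[[1]]$members)
})
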