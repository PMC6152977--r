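# The generator must plant exactly the structure the pipeline assumes:
# identifiable topology, decorrelated smooth activities, NB counts, and
# deterministic output under a fixed seed.

test_that("planted networks are identifiable, repaired and deterministic", {
  cfg1 <- simulationConfig(nTfs = 1, nTgs = 5, edgeDensity = 1,
                           bifurcationTime = NA, seed = 3)
  A <- controlStrengths(generateNetwork(cfg1))
  expect_equal(dim(A), c(5L, 1L))
  expect_true(all(A != 0))
  expect_true(checkIdentifiability(A != 0)$pass)

  cfg <- simulationConfig(nTfs = 3, nTgs = 30, edgeDensity = 0.2, seed = 1)
  n1 <- generateNetwork(cfg)
  n2 <- generateNetwork(cfg)
  expect_identical(controlStrengths(n1), controlStrengths(n2))
  expect_true(checkIdentifiability(support(n1))$pass)
  expect_true(all(colSums(support(n1)) >= 2))
  expect_true(all(abs(controlStrengths(n1)[support(n1)]) >= 0.5))
  expect_true(all(abs(controlStrengths(n1)[support(n1)]) <= 2))
})

test_that("planted activities are smooth, full row rank, and bifurcate on cue", {
  cfg <- simulationConfig(seed = 5)
  net <- generateNetwork(cfg)
  tfa <- generateTfa(cfg, net)
  P <- activities(tfa$tfa[[1]])
  expect_equal(qr(P)$rank, nrow(P))
  expect_true(all(apply(P, 1, var) > 0))
  # branch drivers coincide before the bifurcation index, diverge from it on
  bt <- cfg@bifurcationTime
  g1 <- names(tfa$tfGroups)[tfa$tfGroups == 1L]
  g2 <- names(tfa$tfGroups)[tfa$tfGroups == 2L]
  d <- abs(colMeans(P[g1, , drop = FALSE]) - colMeans(P[g2, , drop = FALSE]))
  expect_equal(unname(d[seq_len(bt - 1)]), rep(0, bt - 1))
  expect_true(all(d[bt:ncol(P)] > 0))

  cfgN <- simulationConfig(bifurcationTime = NA, seed = 5)
  tfaN <- generateTfa(cfgN, generateNetwork(cfgN))
  expect_true(all(tfaN$tfGroups == 0L))
  expect_true(all(tfaN$divergence == 0))
})

test_that("counts follow the NB model and are seed-deterministic", {
  cfg <- simulationConfig(nTgs = 30, dispersion = 0, seed = 9,
                          nEcotypes = 1, nReplicates = 3,
                          librarySizeRange = c(4e5, 4e5))
  net <- generateNetwork(cfg)
  tfa <- generateTfa(cfg, net)
  c1 <- generateCounts(cfg, net, tfa)
  c2 <- generateCounts(cfg, net, tfa)
  expect_identical(SummarizedExperiment::assay(c1$se),
                   SummarizedExperiment::assay(c2$se))
  y <- SummarizedExperiment::assay(c1$se)
  # phi = 0: Poisson, variance ~ mean across replicates of one condition
  cd <- as.data.frame(SummarizedExperiment::colData(c1$se))
  reps <- cd$sample_id[cd$condition == "control" & cd$time == 1]
  m <- rowMeans(y[, reps]); v <- apply(y[, reps], 1, var)
  use <- m > 50
  expect_lt(abs(median(v[use] / m[use]) - 1), 0.5)
  expect_true(all(y[c("SILENT1", "SILENT2"), ] == 0))
  # planted truth invariants
  expect_true(validObject(c1$truth))
  expect_true(all(colSums(support(c1$truth@connectivity)) >= 2))
})

test_that("written simulation files are byte-identical under one seed", {
  sim1 <- simulateStudy(simulationConfig(nTgs = 25, seed = 4))
  sim2 <- simulateStudy(simulationConfig(nTgs = 25, seed = 4))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(sim1, d1)
  writeSimulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("validation fixtures respect the transfer fraction", {
  cfg <- simulationConfig(nTgs = 30, seed = 6)
  net <- generateNetwork(cfg)
  tfa <- generateTfa(cfg, net)
  cnt <- generateCounts(cfg, net, tfa)
  # transfer 0: nothing is mappable, orthology validates no edge
  fx0 <- generateValidationFixtures(cfg, cnt$truth, transferFraction = 0)
  expect_equal(nrow(fx0$truth@orthologTruth), 0L)
  truthNet <- stressGRN:::.newGrn(
    data.frame(tf = cnt$truth@orthologTruth$tf,
               tg = cnt$truth@orthologTruth$tg,
               pcc = 1, cs = 1, sign = "+"), "final", 0)
  v0 <- validateByOrthology(truthNet, fx0$orthologMap, fx0$referenceSets)
  expect_equal(sum(v0$edges$orthology_validated), 0L)
  # transfer 1, no decoys: every planted edge validates
  fx1 <- generateValidationFixtures(cfg, cnt$truth, transferFraction = 1)
  v1 <- validateByOrthology(truthNet, fx1$orthologMap, fx1$referenceSets)
  expect_true(all(v1$edges$orthology_validated))
})

test_that("clade annotation separates co-targets from random gene sets", {
  sim <- defaultSim()
  w <- controlStrengths(sim$network)
  dag <- sim$goDag
  ann <- sim$annotations
  tf <- names(which.max(colSums(w != 0)))
  mine <- rownames(w)[w[, tf] != 0]
  mine <- intersect(mine, ann$gene)
  termSim <- NULL
  pairSims <- function(genes) {
    ps <- c()
    for (i in seq_len(length(genes) - 1)) for (j in (i + 1):length(genes))
      ps <- c(ps, geneSimilarity(genes[i], genes[j], ann, dag))
    ps
  }
  withinClade <- pairSims(mine)
  set.seed(2)
  rand <- replicate(10, mean(pairSims(sample(unique(ann$gene),
                                             length(mine)))))
  expect_gt(mean(withinClade), mean(rand))
})
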