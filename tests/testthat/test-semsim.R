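# Wang semantic similarity, gene-level aggregation, functional-relevance
# validation and the saturation cutoff.

test_that("Wang similarity reproduces hand-computed values", {
  dag <- chainDag()
  expect_equal(wangSimilarity("GO:C", "GO:C", dag), 1)
  expect_equal(wangSimilarity("GO:R", "GO:R", dag), 1)
  # chain: (0.8 + 1) / (1.8 + 1) = 9/14
  expect_equal(wangSimilarity("GO:C", "GO:R", dag), 9 / 14)
  expect_equal(wangSimilarity("GO:R", "GO:C", dag), 9 / 14)
  expect_error(wangSimilarity("GO:X", "GO:R", dag), "GO:X")
})

test_that("Wang similarity equals the fixpoint-relaxation oracle", {
  for (seed in 1:100) {
    dag <- randomDag(sample(4:10, 1), seed)
    ids <- termIds(dag)
    pick <- sample(ids, 2)
    got <- wangSimilarity(pick[1], pick[2], dag)
    want <- oracleWang(pick[1], pick[2], dag)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, wangSimilarity(pick[2], pick[1], dag),
                 tolerance = 1e-15)
    expect_true(got > 0 && got <= 1)
  }
})

test_that("gene similarity is a best-match average over term sets", {
  dag <- chainDag()
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    go_id = c("GO:C", "GO:C", "GO:R"))
  expect_equal(geneSimilarity("g1", "g2", ann, dag), 1)
  expect_equal(geneSimilarity("g1", "g3", ann, dag), 9 / 14)
  expect_error(geneSimilarity("g1", "gX", ann, dag), "gX")
  # two clades sharing only the root: cross-clade below within-clade
  sim <- defaultSim()
  ann2 <- sim$annotations
  w <- controlStrengths(sim$network)
  tfs <- colnames(w)
  t1 <- rownames(w)[w[, tfs[3]] != 0][1:2]
  t2 <- rownames(w)[w[, tfs[4]] != 0][1:2]
  within <- geneSimilarity(t1[1], t1[2], ann2, sim$goDag)
  cross <- geneSimilarity(t1[1], t2[1], ann2, sim$goDag)
  expect_gt(within, cross)
})

test_that("functional relevance validates clade-coherent targets", {
  sim <- defaultSim()
  pl <- defaultPipeline()
  bg <- sort(unique(sim$annotations$gene))
  fr <- functionalRelevance(pl$netF, sim$annotations, sim$goDag,
                            cutoff = 0.3, nBackground = 100,
                            background = bg, seed = 1)
  # planted TFs' targets share a clade: the Wilcoxon test must see it
  ps <- unlist(lapply(fr$perTf, `[[`, "wilcoxonP"))
  expect_true(any(ps < 0.01))
  expect_gt(mean(fr$validatedEdges$funct_validated), 0.9)
  # cutoff above 1 validates nothing
  fr2 <- functionalRelevance(pl$netF, sim$annotations, sim$goDag,
                             cutoff = 1.01, nBackground = 10,
                             background = bg, seed = 1)
  expect_equal(sum(fr2$validatedEdges$funct_validated), 0L)
  # a TF with uniformly random targets should not look coherent
  set.seed(4)
  randTg <- sample(setdiff(bg, tfIds(pl$netF)), 8)
  ed <- data.frame(tf = "TFRAND", tg = randTg, pcc = 0.9, cs = 1,
                   sign = "+")
  netR <- stressGRN:::.newGrn(ed, "final", 0.75)
  frR <- functionalRelevance(netR, sim$annotations, sim$goDag,
                             cutoff = 0.3, nBackground = 200,
                             background = bg, seed = 2)
  expect_gte(frR$perTf$TFRAND$wilcoxonP, 0.05)
})

test_that("targets annotated to one identical term all validate", {
  dag <- chainDag()
  ann <- data.frame(gene = paste0("g", 1:6), go_id = "GO:C")
  ed <- data.frame(tf = "TF1", tg = paste0("g", 1:4), pcc = 0.9, cs = 1,
                   sign = "+")
  net <- stressGRN:::.newGrn(ed, "final", 0.75)
  fr <- functionalRelevance(net, ann, dag, cutoff = 0.3, nBackground = 20,
                            background = paste0("g", 1:6), seed = 1)
  expect_true(all(fr$perTf$TF1$simMatrix == 1))
  expect_true(all(fr$validatedEdges$funct_validated))
})

test_that("pooled planted similarities dominate the random background", {
  sim <- defaultSim()
  pl <- defaultPipeline()
  bg <- sort(unique(sim$annotations$gene))
  fr <- functionalRelevance(pl$netF, sim$annotations, sim$goDag,
                            nBackground = 100, background = bg, seed = 3)
  p <- suppressWarnings(wilcox.test(fr$pooledTargetSims,
                                    fr$pooledBackgroundSims,
                                    alternative = "greater"))$p.value
  expect_lt(p, 1e-4)
})

test_that("saturation cutoff finds the knee of the retained curve", {
  set.seed(10)
  pool <- runif(20000)
  grid <- seq(0, 1, by = 0.05)
  out <- saturationCutoff(pool, grid)
  expect_equal(out$retained, 1 - grid, tolerance = 0.02)
  expect_true(out$cutoff %in% grid)
  # constant pool: warning, grid minimum
  expect_warning(flat <- saturationCutoff(rep(1, 50), grid), "constant")
  expect_equal(flat$cutoff, 0)
})

test_that("orthology validation transfers planted edges and ignores dupes", {
  pl <- defaultPipeline()
  sim <- pl$sim
  v <- validateByOrthology(pl$netF, sim$orthologMap, sim$referenceSets)
  truthKeys <- paste(sim$truth@orthologTruth$tf, sim$truth@orthologTruth$tg)
  gotKeys <- paste(v$edges$tf, v$edges$tg)[v$edges$orthology_validated]
  # transferFraction = 1, refs = images of true edges: validated set is
  # exactly the pipeline-truth intersection
  expect_setequal(gotKeys, intersect(edgeKeys(pl$netF), truthKeys))
  # duplicating reference rows changes nothing
  v2 <- validateByOrthology(pl$netF, sim$orthologMap,
                            rbind(sim$referenceSets, sim$referenceSets))
  expect_equal(v$perSource, v2$perSource)
  # empty references validate nothing
  v3 <- validateByOrthology(pl$netF, sim$orthologMap,
                            sim$referenceSets[0, ])
  expect_equal(sum(v3$edges$orthology_validated), 0L)
  # a TF that maps without its target does not validate
  om <- sim$orthologMap[sim$orthologMap$query_gene %in% tfIds(pl$netF), ]
  v4 <- validateByOrthology(pl$netF, om, sim$referenceSets)
  expect_equal(sum(v4$edges$orthology_validated), 0L)
})
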