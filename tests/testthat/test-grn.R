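# PCC network construction, identifiability, pruning and the ALS
# decomposition.

test_that("PCC network matches a naive all-pairs loop and records signs", {
  set.seed(21)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(c(paste0("TF", 1:4), paste0("G", 1:16)),
                                 paste0("s", 1:12)))
  expr["G1", ] <- expr["TF1", ]           # exact copy -> PCC 1
  expr["G2", ] <- -expr["TF2", ]          # negated -> PCC -1
  tfs <- paste0("TF", 1:4); tgs <- paste0("G", 1:16)
  net <- pccNetwork(expr, tfs, tgs, threshold = 0.5)
  e <- edgeTable(net)
  expect_equal(e$pcc[e$tf == "TF1" & e$tg == "G1"], 1)
  expect_equal(e$pcc[e$tf == "TF2" & e$tg == "G2"], -1)
  expect_equal(e$sign[e$tf == "TF2" & e$tg == "G2"], "-")
  # brute-force double loop
  want <- NULL
  for (tf in tfs) for (tg in tgs) {
    r <- cor(expr[tf, ], expr[tg, ])
    if (abs(r) > 0.5) want <- rbind(want, data.frame(tf, tg, pcc = r))
  }
  want <- want[order(want$tf, want$tg), ]
  expect_equal(e$tf, want$tf)
  expect_equal(e$tg, want$tg)
  expect_equal(e$pcc, want$pcc, tolerance = 1e-12)
  expect_error(pccNetwork(expr[, 1:2], tfs, tgs), "3 samples")
})

test_that("identifiability detects duplicate and degenerate supports", {
  # two TFs with the same single target: duplicate columns
  s <- matrix(c(1, 0, 1, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("TF1", "TF2")))
  rep1 <- checkIdentifiability(s)
  expect_false(rep1$pass)
  expect_false(rep1$fullColumnRank)
  # diagonal blocks with 3 private targets each: clean pass
  s2 <- kronecker(diag(3), matrix(1, 3, 1))
  dimnames(s2) <- list(paste0("g", 1:9), paste0("TF", 1:3))
  expect_true(checkIdentifiability(s2)$pass)
})

test_that("generic-rank verdicts agree with a prime-instantiation oracle", {
  set.seed(17)
  for (i in 1:25) {
    s <- matrix(runif(30 * 4) < 0.25, 30, 4,
                dimnames = list(paste0("g", 1:30), paste0("TF", 1:4)))
    got <- checkIdentifiability(s)$fullColumnRank
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                53, 59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107,
                109, 113, 127, 131, 137, 139, 149, 151, 157, 163, 167,
                173)
    m <- matrix(0, 30, 4)
    m[s] <- primes[seq_len(sum(s))]
    expect_equal(got, qr(m)$rank == 4L)
  }
})

test_that("pruning removes under-targeted and duplicate TFs, and only them", {
  mk <- function(df) stressGRN:::.newGrn(df, "initial", 0.7)
  base <- data.frame(
    tf = rep(c("TFA", "TFB", "TFC"), each = 3),
    tg = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9"),
    pcc = 0.9, cs = NA_real_, sign = "+")
  solo <- rbind(base, data.frame(tf = "TFD", tg = "g1", pcc = 0.8,
                                 cs = NA_real_, sign = "+"))
  out <- pruneForNca(mk(solo))
  expect_equal(out$removed, "TFD")
  # duplicate target set: the one with larger mean |pcc| survives
  dup <- rbind(base, data.frame(tf = "TFE", tg = c("g1", "g2", "g3"),
                                pcc = 0.95, cs = NA_real_, sign = "+"))
  out2 <- pruneForNca(mk(dup))
  expect_equal(out2$removed, "TFA")   # TFE wins on mean |pcc|
  expect_true("TFE" %in% edgeTable(out2$net)$tf)
  # three injected duplicates of existing TFs are exactly what goes
  inj <- rbind(base,
               data.frame(tf = c("TFX", "TFX", "TFX"),
                          tg = c("g1", "g2", "g3"), pcc = 0.80,
                          cs = NA_real_, sign = "+"),
               data.frame(tf = c("TFY", "TFY", "TFY"),
                          tg = c("g4", "g5", "g6"), pcc = 0.79,
                          cs = NA_real_, sign = "+"),
               data.frame(tf = c("TFZ", "TFZ", "TFZ"),
                          tg = c("g7", "g8", "g9"), pcc = 0.78,
                          cs = NA_real_, sign = "+"))
  out3 <- pruneForNca(mk(inj))
  expect_setequal(out3$removed, c("TFX", "TFY", "TFZ"))
})

test_that("ALS recovers a noiseless planted factorization", {
  set.seed(31)
  cfg <- simulationConfig(nTfs = 4, nTgs = 40, bifurcationTime = NA,
                          seed = 11)
  A0 <- controlStrengths(generateNetwork(cfg))
  P0 <- matrix(rnorm(4 * 30), 4, 30,
               dimnames = list(colnames(A0), paste0("s", 1:30)))
  X <- A0 %*% P0
  hit <- which(A0 != 0, arr.ind = TRUE)
  ed <- data.frame(tf = colnames(A0)[hit[, 2]], tg = rownames(A0)[hit[, 1]],
                   pcc = mapply(function(i, j) cor(X[i, ], P0[j, ]),
                                hit[, 1], hit[, 2]),
                   cs = NA_real_)
  ed$sign <- ifelse(ed$pcc > 0, "+", "-")
  net <- stressGRN:::.newGrn(ed, "initial", 0)
  dec <- ncaDecompose(X, net, tol = 1e-12, maxIter = 2000, seed = 1,
                      center = FALSE)
  expect_lt(tail(dec$trace, 1), 1e-8 * sum(X^2))
  for (tf in rownames(P0))
    expect_gt(abs(cor(activities(dec$tfa)[tf, ], P0[tf, ])), 0.99)
  # objective trace is non-increasing; runs from different seeds agree
  expect_true(all(diff(dec$trace) <= 1e-9))
  dec2 <- ncaDecompose(X, net, tol = 1e-12, maxIter = 2000, seed = 77,
                       center = FALSE)
  expect_equal(controlStrengths(dec$connectivity),
               controlStrengths(dec2$connectivity), tolerance = 1e-6)
  expect_equal(activities(dec$tfa), activities(dec2$tfa), tolerance = 1e-6)
  # normalization convention: unit columns, largest entry positive
  Ahat <- controlStrengths(dec$connectivity)
  expect_equal(unname(sqrt(colSums(Ahat^2))), rep(1, 4), tolerance = 1e-9)
  expect_true(all(apply(Ahat, 2, function(col) col[which.max(abs(col))]) > 0))
})

test_that("ALS handles an all-zero expression matrix", {
  s <- kronecker(diag(2), matrix(1, 3, 1))
  dimnames(s) <- list(paste0("g", 1:6), c("TF1", "TF2"))
  ed <- data.frame(tf = c(rep("TF1", 3), rep("TF2", 3)),
                   tg = paste0("g", 1:6), pcc = 0.9, cs = NA_real_,
                   sign = "+")
  net <- stressGRN:::.newGrn(ed, "initial", 0)
  X <- matrix(0, 6, 8, dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  dec <- suppressWarnings(ncaDecompose(X, net, center = FALSE))
  expect_equal(tail(dec$trace, 1), 0)
  expect_true(all(activities(dec$tfa) == 0))
})

test_that("final edge calling is inclusive at the cut and nested", {
  pl <- defaultPipeline()
  eN <- edgeTable(pl$dec$net)
  f75 <- finalEdges(pl$dec$net, pl$expr, 0.75)
  f80 <- finalEdges(pl$dec$net, pl$expr, 0.80)
  expect_true(all(abs(edgeTable(f75)$pcc) >= 0.75))
  expect_true(all(edgeKeys(f80) %in% edgeKeys(f75)))
  expect_true(all(edgeKeys(f75) %in% edgeKeys(pl$net0)))
  # boundary: synthetic pair exactly at the cut is kept, just below dropped
  t <- seq(0, 1, length.out = 8)
  mk <- function(r) {  # construct a pair with exact correlation r
    x <- scale(t); y <- r * x + sqrt(1 - r^2) * scale(resid(lm(rnorm(8) ~ x)))
    rbind(TFa = as.numeric(x), Gb = as.numeric(y))
  }
  set.seed(2)
  ex <- mk(0.75)
  ed <- data.frame(tf = "TFa", tg = "Gb", pcc = 0.9, cs = 1, sign = "+")
  netN <- stressGRN:::.newGrn(ed, "nca", 0.7)
  colnames(ex) <- paste0("s", 1:8)
  expect_equal(nrow(edgeTable(finalEdges(netN, ex, 0.75))), 1L)
  ex2 <- mk(0.74)
  colnames(ex2) <- paste0("s", 1:8)
  expect_equal(nrow(edgeTable(finalEdges(netN, ex2, 0.75))), 0L)
})
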