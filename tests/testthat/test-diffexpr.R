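# NB exact test calibration/power and the stress-gene selection cascade.

test_that("identical groups give log2fc 0 and p-value 1", {
  y <- matrix(rep(c(10, 20, 30), 2), 3, 2, byrow = FALSE)
  trt <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  ctl <- trt
  rownames(trt) <- rownames(ctl) <- paste0("g", 1:3)
  res <- nbExactTest(trt, ctl, libSizes = rep(100, 4), dispersion = 0.1)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  # all-zero gene
  res0 <- nbExactTest(matrix(0, 1, 2), matrix(0, 1, 2),
                      libSizes = rep(10, 4), dispersion = 0.1)
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$pvalue, 1)
})

test_that("type-I error is calibrated under a seeded NB null", {
  set.seed(123)
  n <- 2000
  mu <- runif(n, 20, 200)
  trt <- sapply(1:3, function(i) rnbinom(n, size = 10, mu = mu))
  ctl <- sapply(1:3, function(i) rnbinom(n, size = 10, mu = mu))
  rownames(trt) <- rownames(ctl) <- paste0("g", seq_len(n))
  res <- nbExactTest(trt, ctl, libSizes = rep(sum(mu), 6))
  rate <- mean(res$pvalue < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("an 8-fold planted effect is detected with the right fold change", {
  set.seed(99)
  n <- 500
  mu <- runif(n, 30, 100)
  trt <- sapply(1:3, function(i) rnbinom(n, size = 100, mu = 8 * mu))
  ctl <- sapply(1:3, function(i) rnbinom(n, size = 100, mu = mu))
  rownames(trt) <- rownames(ctl) <- paste0("g", seq_len(n))
  res <- nbExactTest(trt, ctl, libSizes = rep(mean(9 * mu) * n / 2, 6),
                     dispersion = 0.01)
  expect_gte(mean(abs(res$log2fc - 3) < 0.5), 0.95)
  expect_gte(mean(res$pvalue < 0.05), 0.95)
})

test_that("DEG calls follow the |log2FC| > 1 and p < 0.05 rule exactly", {
  de <- data.frame(gene = letters[1:4],
                   log2fc = c(1.5, 0.9, 3.0, -1.2),
                   pvalue = c(0.01, 0.001, 0.06, 0.04))
  out <- callDegs(de)
  expect_equal(out$is_deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(out), 4L)  # annotation only, no filtering
})

test_that("stress-gene selection needs two DEG time points and caps by p", {
  de <- data.frame(
    gene = c("g1", "g1", "g2", "g3", "g3", "g3"),
    ecotype = "E1",
    time = c(1, 2, 1, 1, 2, 3),
    log2fc = 2, pvalue = c(0.01, 0.02, 0.001, 0.04, 0.03, 0.02),
    is_deg = TRUE)
  sets <- selectStressGenes(de, tfList = "g3", perEcotypeCap = 10)
  expect_setequal(sets@stressResponding, c("g1", "g3"))  # g2: 1 time point
  expect_equal(sets@tfs, "g3")
  expect_equal(sets@tgs, "g1")
  # cap: with 2000 eligible genes keep exactly the 1500 smallest min-p
  set.seed(8)
  n <- 2000
  big <- do.call(rbind, lapply(1:2, function(tp)
    data.frame(gene = sprintf("g%04d", 1:n), ecotype = "E1", time = tp,
               log2fc = 2, pvalue = runif(n), is_deg = TRUE)))
  capd <- selectStressGenes(big, tfList = character(), perEcotypeCap = 1500)
  expect_length(capd@stressAffected$E1, 1500L)
  minp <- tapply(big$pvalue, big$gene, min)
  oracle <- names(sort(minp))[1:1500]   # full-sort oracle
  expect_setequal(capd@stressAffected$E1, oracle)
  # row-order invariance
  shuf <- big[sample(nrow(big)), ]
  capd2 <- selectStressGenes(shuf, tfList = character(),
                             perEcotypeCap = 1500)
  expect_setequal(capd2@stressAffected$E1, capd@stressAffected$E1)
})

test_that("most genes with a planted 2-fold effect are recovered as DEGs", {
  pl <- defaultPipeline()
  sim <- pl$sim
  w <- controlStrengths(sim$network)
  # planted log2 effect per (gene, ecotype, time) is the A P entry
  strong <- character()
  for (eco in names(sim$truth@tfa)) {
    Z <- w %*% activities(sim$truth@tfa[[eco]])
    strong <- union(strong, rownames(Z)[apply(abs(Z) > 1, 1, any)])
  }
  degGenes <- unique(pl$de$gene[pl$de$is_deg])
  expect_gt(mean(strong %in% degGenes), 0.8)
})
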