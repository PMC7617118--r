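test_that("Balding-Nichols draws have the stated mean and variance", {
  expect_identical(drawSubpopFrequencies(0.3, 0, 5), rep(0.3, 5))
  set.seed(4)
  x <- drawSubpopFrequencies(0.3, 0.05, 10000)
  expect_true(all(x > 0 & x < 1))
  expect_lt(abs(mean(x) - 0.3), 0.01)
  expect_lt(abs(var(x) - 0.05 * 0.3 * 0.7) / (0.05 * 0.3 * 0.7), 0.15)
  expect_error(drawSubpopFrequencies(0.3, 0.6, 5), "fst")
})

test_that("simulateCohort is seed-deterministic and restores the RNG state", {
  cfg <- simConfig(nCases = 80, nControls = 80, nNuclear = 20, nMt = 3,
                   b0 = 0, seed = 31)
  set.seed(999); before <- rnorm(1)
  set.seed(999)
  a <- simulateCohort(cfg)
  expect_identical(rnorm(1), before)  # caller RNG untouched
  b <- simulateCohort(cfg)
  expect_identical(nuclearGeno(a), nuclearGeno(b))
  expect_identical(mitoGeno(a), mitoGeno(b))
  cfg@seed <- 32L
  c_ <- simulateCohort(cfg)
  expect_false(identical(nuclearGeno(a), nuclearGeno(c_)))
})

test_that("neutral-model genotypes are in Hardy-Weinberg equilibrium", {
  ch <- simulateCohort(simConfig(nCases = 1000, nControls = 1000,
                                 nNuclear = 200, blockSize = 1,
                                 withinBlockCorr = 0, nMt = 2, b0 = 0,
                                 seed = 77))
  g <- nuclearGeno(ch)
  pvals <- apply(g, 2, function(x) {
    p <- mean(x) / 2
    expd <- 2000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(x + 1L, 3)
    suppressWarnings(chisq.test(obs, p = expd / sum(expd))$p.value)
  })
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("pre-ascertainment case fraction follows the logistic intercept", {
  cfg <- simConfig(nNuclear = 5, nMt = 1, b0 = qlogis(0.3), seed = 2)
  set.seed(6)
  batch <- mitoscan:::.simBatch(20000, cfg,
                                matrix(0.3, 1, 5), matrix(0.5, 1, 1))
  expect_lt(abs(mean(batch$dis) - 0.3), 0.015)
})

test_that("LD blocks induce within-block but not across-block correlation", {
  ch <- simulateCohort(simConfig(nCases = 1500, nControls = 1500,
                                 nNuclear = 20, blockSize = 10,
                                 withinBlockCorr = 0.8, nMt = 1, b0 = 0,
                                 seed = 13))
  g <- nuclearGeno(ch)
  within <- cor(g[, 1], g[, 2])    # adjacent, same block
  across <- cor(g[, 10], g[, 11])  # block boundary
  expect_gt(within, 0.4)
  expect_lt(abs(across), 0.1)
})

test_that("direct coupling reproduces the target mt-nuclear odds ratio", {
  cfg <- simConfig(nCases = 0, nControls = 50000, nNuclear = 2,
                   blockSize = 1, withinBlockCorr = 0, nMt = 1,
                   mtFreqs = matrix(0.3), baseFreqRange = c(0.2, 0.2),
                   b0 = -20, couplingOR = 1.5, couplingPair = c(1, 1),
                   seed = 9)
  ch <- simulateCohort(cfg)
  mt <- mitoGeno(ch)[, 1]
  carrier <- nuclearGeno(ch)[, 1] > 0
  or <- crossOR(c(sum(mt & carrier), sum(mt & !carrier),
                  sum(!mt & carrier), sum(!mt & !carrier)))
  expect_lt(abs(or - 1.5), 0.1)
  # uncoupled SNP keeps Hardy-Weinberg frequencies
  p2 <- mean(nuclearGeno(ch)[, 2]) / 2
  expect_lt(abs(p2 - 0.2), 0.01)
})

test_that("computePCs matches an eigendecomposition oracle up to sign", {
  m <- matrix(c(0, 1, 2, 1, 0, 2,
                2, 1, 0, 1, 2, 0,
                1, 1, 1, 0, 2, 2,
                0, 2, 1, 1, 1, 0), 6, 4)
  sc <- computePCs(m, 2)
  p <- colMeans(m) / 2
  Z <- sweep(sweep(m, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  ev <- eigen(tcrossprod(Z), symmetric = TRUE)
  oracle <- ev$vectors[, 1:2] %*% diag(sqrt(pmax(ev$values[1:2], 0)))
  for (j in 1:2) {
    expect_true(max(abs(sc[, j] - oracle[, j])) < 1e-8 ||
                max(abs(sc[, j] + oracle[, j])) < 1e-8)
  }
  expect_identical(ncol(computePCs(m, 0)), 0L)
  expect_error(computePCs(m, 5), "rank|polymorphic|samples")
})

test_that("PC1 separates diverged subpopulations", {
  ch <- simulateCohort(simConfig(nCases = 500, nControls = 500,
                                 nNuclear = 500, blockSize = 1,
                                 withinBlockCorr = 0, nMt = 2,
                                 subpopWeights = c(0.5, 0.5), fst = 0.1,
                                 b0 = 0, seed = 55))
  pcs <- computePCs(nuclearGeno(ch), 2)
  subpop <- sampleInfo(ch)$subpop
  expect_gt(abs(cor(pcs[, 1], subpop)), 0.9)
  # addPCs installs the scores as covariates
  ch2 <- addPCs(ch, 2)
  expect_identical(names(sampleInfo(ch2))[4:5], c("pc1", "pc2"))
})

test_that("the ascertainment budget guards against impossible case counts", {
  cfg <- simConfig(nCases = 5000, nControls = 10, nNuclear = 2, nMt = 1,
                   b0 = -14, seed = 1)
  expect_error(simulateCohort(cfg), "budget")
})
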