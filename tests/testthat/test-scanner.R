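test_that("additiveDosage counts the cohort-minor allele", {
  expect_identical(as.integer(additiveDosage(c(0L, 1L, 2L, 0L, 0L, 1L))),
                   c(0L, 1L, 2L, 0L, 0L, 1L))
  # ALT is the major allele here, so coding flips to the minor allele
  flipped <- additiveDosage(c(2L, 2L, 1L, 2L, 0L, 2L))
  expect_identical(as.integer(flipped), c(0L, 0L, 1L, 0L, 2L, 0L))
  expect_true(attr(flipped, "flipped"))
  expect_message(additiveDosage(c(2L, 2L, 1L), verbose = TRUE), "flipped")
})

test_that("fitLogistic recovers closed-form 2x2 and intercept-only fits", {
  # intercept-only, half the responses 1: logit(0.5) = 0
  y <- rep(c(0, 1), 50)
  f <- fitLogistic(y, matrix(1, 100, 1))
  expect_equal(unname(f$coef[1]), 0, tolerance = 1e-8)

  # single binary predictor from counts (a,b,c,d) = (30,70,20,80):
  # slope = ln((30*80)/(70*20))
  x <- rep(c(1, 1, 0, 0), c(30, 70, 20, 80))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 20, 80))
  f <- fitLogistic(y, cbind(1, x))
  expect_equal(unname(f$coef[2]), log(30 * 80 / (70 * 20)),
               tolerance = 1e-6)
  expect_identical(f$status, "ok")
  # Wald SE equals the classic 2x2 formula sqrt(sum of 1/counts)
  expect_equal(unname(f$se[2]), sqrt(1/30 + 1/70 + 1/20 + 1/80),
               tolerance = 1e-6)

  # perfectly separated data are flagged, not reported as estimates
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  f <- fitLogistic(as.integer(x > 0), cbind(1, x))
  expect_identical(f$status, "separation")

  expect_error(fitLogistic(rep(1, 10), matrix(1, 10, 1)), "constant")
})

test_that("scan OR equals the contingency cross-product OR without covariates", {
  set.seed(31)
  n <- 600
  mt <- rbinom(n, 1, 0.3)
  nn <- rbinom(n, 1, plogis(-1.2 + 0.5 * mt))  # binary-coded nSNP
  ch <- toyCohort(nuclear = nn, mito = mt, dis = rep(0:1, n / 2))
  res <- caseOnlyScan(ch, "mt.110", "rs1",
                      config = scanConfig(coding = "dominant"))
  cnt <- c(sum(mt & nn), sum(mt & !nn), sum(!mt & nn), sum(!mt & !nn))
  expect_equal(res$or[1], crossOR(cnt), tolerance = 1e-6)
  expect_identical(res$status[1], "ok")
  expect_equal(res$q[1], res$p[1])  # single test: q = p
})

test_that("collapsed no-covariate path equals the full per-sample fit", {
  ch <- simulateCohort(simConfig(nCases = 250, nControls = 250,
                                 nNuclear = 12, nMt = 2, b0 = 0, seed = 8))
  mtIds <- colnames(mitoGeno(ch))
  fast <- caseOnlyScan(ch, mtIds)
  ok <- which(fast$status == "ok")
  expect_gt(length(ok), 10)
  for (i in sample(ok, 5)) {
    y <- mitoGeno(ch)[, fast$mtsnp_id[i]]
    if (mean(y) > 0.5) y <- 1L - y  # scan codes the minor mt allele
    d <- as.numeric(additiveDosage(nuclearGeno(ch)[, fast$nsnp_id[i]]))
    f <- fitLogistic(y, cbind(1, d))  # full per-sample IRLS
    expect_equal(fast$beta[i], unname(f$coef[2]), tolerance = 1e-4)
    expect_equal(fast$se[i], unname(f$se[2]), tolerance = 1e-4)
    expect_equal(fast$p[i], unname(f$p[2]), tolerance = 1e-4)
  }
})

test_that("scan skips low-count tests and errors on monomorphic mtSNPs", {
  set.seed(5)
  n <- 200
  rare <- c(rep(1L, 2), rep(0L, n - 2))  # two minor alleles only
  common <- rbinom(n, 1, 0.4)
  ch <- toyCohort(nuclear = cbind(rare, common),
                  mito = rbinom(n, 1, 0.4), dis = rep(0:1, n / 2))
  res <- caseOnlyScan(ch, "mt.110")
  expect_identical(res$status[res$nsnp_id == "rs1"], "skipped_low_count")
  expect_true(is.na(res$p[res$nsnp_id == "rs1"]))
  chMono <- toyCohort(nuclear = common, mito = rep(0L, n),
                      dis = rep(0:1, n / 2))
  expect_error(caseOnlyScan(chMono, "mt.110"), "monomorphic")
})

test_that("bhFDR matches the hand step-up recursion and p.adjust", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(17)
  for (i in 1:25) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bhFDR(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_identical(bhFDR(numeric(0)), numeric(0))
  expect_error(bhFDR(c(0.5, 0)), "0, 1")
})

test_that("genomicInflation is 1 at the null median and monotone", {
  expect_equal(genomicInflation(rep(0.5, 25)), 1)
  set.seed(2)
  p <- runif(10000)
  lam <- genomicInflation(p)
  expect_lt(abs(lam - 1), 0.05)
  expect_gt(genomicInflation(p / 2), lam)
  expect_error(genomicInflation(runif(10)), "at least 20")
})

test_that("qqData pairs observed with mid-rank expected quantiles", {
  d <- qqData(0.1)
  expect_equal(d$expected, -log10(0.5))
  expect_equal(d$observed, 1)
  set.seed(3)
  p <- runif(10000)
  d <- qqData(p)
  expect_identical(nrow(d), 10000L)
  expect_lt(max(abs(d$observed - d$expected)[d$expected < 2]), 0.25)
})
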