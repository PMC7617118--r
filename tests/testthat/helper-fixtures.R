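# Small fixture builders and independent oracles shared across test files.

# Build a Cohort directly from matrices; variant/sample metadata invented.
toyCohort <- function(nuclear, mito, dis,
                      cohort = ifelse(dis == 1, "case", "control"),
                      covs = NULL) {
  nuclear <- as.matrix(nuclear)
  mito <- as.matrix(mito)
  n <- nrow(nuclear)
  L <- ncol(nuclear); M <- ncol(mito)
  mtPos <- 100L + 10L * seq_len(M)
  variants <- data.frame(
    id = c(sprintf("rs%d", seq_len(L)), sprintf("mt.%d", mtPos)),
    chrom = c(rep("1", L), rep("MT", M)),
    pos = c(10L * seq_len(L), mtPos),
    ref = c(rep("A", L), rep("T", M)),
    alt = c(rep("G", L), rep("C", M)),
    maf = rep(NA_real_, L + M), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                        cohort = cohort, disease_status = as.integer(dis),
                        stringsAsFactors = FALSE)
  if (!is.null(covs)) samples <- cbind(samples, as.data.frame(covs))
  Cohort(nuclear, mito, variants, samples)
}

# Saturated 2x2x2 cohort from per-stratum counts in the order
# (mt=1,n=1), (mt=1,n=0), (mt=0,n=1), (mt=0,n=0).
cohort222 <- function(ctrlCounts, caseCounts) {
  mk <- function(cnt, dis) {
    mt <- rep(c(1L, 1L, 0L, 0L), cnt)
    nn <- rep(c(1L, 0L, 1L, 0L), cnt)
    list(mt = mt, nn = nn, dis = rep(dis, sum(cnt)))
  }
  a <- mk(ctrlCounts, 0L); b <- mk(caseCounts, 1L)
  toyCohort(nuclear = c(a$nn, b$nn), mito = c(a$mt, b$mt),
            dis = c(a$dis, b$dis))
}

# Cross-product odds ratio of a 2x2 count table given as (n11,n10,n01,n00).
crossOR <- function(cnt) (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])

# 2x2x2 counts of a cohort222-style object, per disease stratum, in the
# cohort222 order; computed by direct tabulation, independent of any fit.
counts222 <- function(mt, nn, dis, stratum) {
  sel <- dis == stratum
  c(sum(mt[sel] == 1 & nn[sel] == 1), sum(mt[sel] == 1 & nn[sel] == 0),
    sum(mt[sel] == 0 & nn[sel] == 1), sum(mt[sel] == 0 & nn[sel] == 0))
}

# Brute-force BH step-up: q_(i) = min_{j >= i} m p_(j) / j, by definition.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  out <- numeric(m)
  for (i in seq_len(m)) out[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  out
}

# Minimal null simulation config used by several calibration tests.
nullScanConfig <- function(nSamples, nNuclear, seed, nMt = 4,
                           fst = 0, subpopWeights = 1, mtFreqs = NULL,
                           blockSize = 1, withinBlockCorr = 0) {
  simConfig(nCases = ceiling(nSamples / 2), nControls = floor(nSamples / 2),
            nNuclear = nNuclear, blockSize = blockSize,
            withinBlockCorr = withinBlockCorr, nMt = nMt,
            subpopWeights = subpopWeights, fst = fst, mtFreqs = mtFreqs,
            b0 = 0, seed = seed)
}
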