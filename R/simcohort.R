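#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws per-subpopulation allele frequencies around an ancestral
#' frequency p from the Beta distribution with mean p and variance
#' Fst p (1 - p) — the Balding-Nichols model of population
#' differentiation. Fst = 0 returns the ancestral frequency exactly.
#'
#' @param baseFreq ancestral allele frequency in (0, 1).
#' @param fst differentiation parameter in [0, 0.5).
#' @param nSubpops number of subpopulations to draw.
#' @return Numeric vector of length \code{nSubpops}, strictly inside
#'   (0, 1).
#' @export
drawSubpopFrequencies <- function(baseFreq, fst, nSubpops) {
  if (baseFreq <= 0 || baseFreq >= 1) stop("baseFreq must lie in (0, 1)")
  if (fst < 0 || fst >= 0.5) stop("fst must lie in [0, 0.5)")
  if (fst == 0) return(rep(baseFreq, nSubpops))
  a <- baseFreq * (1 - fst) / fst
  b <- (1 - baseFreq) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(nSubpops, a, b), 1e-4), 1 - 1e-4)
}

# vectorised over SNPs: nSubpops x length(base) frequency matrix
.bnMatrix <- function(base, fst, nSubpops) {
  L <- length(base)
  if (fst == 0 || nSubpops == 0)
    return(matrix(rep(base, each = nSubpops), nrow = nSubpops))
  a <- base * (1 - fst) / fst
  b <- (1 - base) * (1 - fst) / fst
  m <- matrix(stats::rbeta(nSubpops * L, rep(a, each = nSubpops),
                           rep(b, each = nSubpops)), nrow = nSubpops)
  pmin(pmax(m, 1e-4), 1 - 1e-4)
}

# nh haplotypes from per-SNP frequencies with first-order copying in blocks
.genHaplotypes <- function(nh, freq, blockSize, rho) {
  L <- length(freq)
  H <- matrix(0L, nh, L)
  for (j in seq_len(L)) {
    fresh <- stats::rbinom(nh, 1L, freq[j])
    firstInBlock <- ((j - 1) %% blockSize) == 0
    if (firstInBlock || rho == 0) {
      H[, j] <- fresh
    } else {
      copy <- stats::rbinom(nh, 1L, rho) == 1L
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    }
  }
  H
}

# one unascertained batch of m individuals under the generative model
.simBatch <- function(m, config, nucFreq, mtFreq) {
  nS <- length(config@subpopWeights)
  L <- config@nNuclear
  sp <- sample.int(nS, m, replace = TRUE, prob = config@subpopWeights)
  nuclear <- matrix(0L, m, L)
  mito <- matrix(0L, m, config@nMt)
  for (s in seq_len(nS)) {
    idx <- which(sp == s)
    if (!length(idx)) next
    H <- .genHaplotypes(2 * length(idx), nucFreq[s, ], config@blockSize,
                        config@withinBlockCorr)
    nuclear[idx, ] <- H[seq_len(length(idx)) * 2 - 1, , drop = FALSE] +
      H[seq_len(length(idx)) * 2, , drop = FALSE]
    if (config@nMt > 0)
      mito[idx, ] <- matrix(
        stats::rbinom(length(idx) * config@nMt, 1L,
                      rep(mtFreq[s, ], each = length(idx))),
        nrow = length(idx))
  }
  if (!is.na(config@couplingOR)) {
    i <- config@couplingPair[1]; j <- config@couplingPair[2]
    for (s in seq_len(nS)) {
      idx <- which(sp == s)
      if (!length(idx)) next
      q <- mtFreq[s, i]; p <- nucFreq[s, j]
      pc <- 1 - (1 - p)^2
      tab <- solveJointDistribution(q, pc, config@couplingOR)
      cell <- sample.int(4, length(idx), replace = TRUE, prob = tab)
      M <- as.integer(cell <= 2)              # p11, p10 have mt allele
      C <- as.integer(cell %in% c(1, 3))      # p11, p01 are carriers
      het <- 2 * p * (1 - p) / pc
      g <- ifelse(C == 1,
                  1L + stats::rbinom(length(idx), 1L, 1 - het), 0L)
      mito[idx, i] <- M
      nuclear[idx, j] <- g
    }
  }
  eta <- rep(config@b0, m)
  for (nm in names(config@bN))
    eta <- eta + config@bN[[nm]] * nuclear[, as.integer(nm)]
  for (nm in names(config@bM))
    eta <- eta + config@bM[[nm]] * mito[, as.integer(nm)]
  if (nrow(config@bI))
    for (r in seq_len(nrow(config@bI)))
      eta <- eta + config@bI$beta[r] *
        mito[, config@bI$mt[r]] * nuclear[, config@bI$n[r]]
  dis <- stats::rbinom(m, 1L, stats::plogis(eta))
  list(nuclear = nuclear, mito = mito, dis = dis, sp = sp)
}

#' Simulate a stratified case/control cohort
#'
#' Draws individuals from a mixture of subpopulations whose nuclear allele
#' frequencies diverge under the Balding-Nichols model; each individual
#' gets two nuclear haplotypes generated by first-order copying within LD
#' blocks (independent across blocks), haploid mtSNP calls from the
#' subpopulation's mitochondrial frequencies, and a disease status from
#' the logistic model in the configuration. When a direct mt-nuclear
#' coupling odds ratio is set, the designated pair is drawn jointly from
#' the 2x2 table built by \code{\link{solveJointDistribution}} (mt allele
#' x nuclear carrier status), independent of disease. Individuals are
#' rejection-sampled until the requested numbers of cases and controls are
#' reached (draw budget 1e7). Identical seeds give identical cohorts; the
#' caller's RNG state is restored on exit.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \code{\linkS4class{Cohort}} with cases first (cohort label
#'   "case") then controls ("control"); a \code{subpop} column records the
#'   true subpopulation of origin, handy for checking stratification
#'   control (it is a covariate column, so place PCs before it or use
#'   \code{\link{addPCs}}, which replaces covariates).
#' @export
simulateCohort <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(config@seed)
  nS <- length(config@subpopWeights)
  base <- stats::runif(config@nNuclear, config@baseFreqRange[1],
                       config@baseFreqRange[2])
  nucFreq <- .bnMatrix(base, config@fst, nS)
  mtFreq <- if (is.null(config@mtFreqs))
    .bnMatrix(stats::runif(config@nMt, 0.2, 0.8), config@fst, nS)
  else config@mtFreqs

  needCase <- config@nCases
  needCtrl <- config@nControls
  keptN <- list(); keptM <- list(); keptD <- list(); keptS <- list()
  drawn <- 0
  batch <- max(1000L, needCase + needCtrl)
  while (needCase > 0 || needCtrl > 0) {
    if (drawn >= 1e7)
      stop("ascertainment budget exceeded; disease too rare for the ",
           "requested case count - increase b0")
    b <- .simBatch(batch, config, nucFreq, mtFreq)
    drawn <- drawn + batch
    takeCase <- utils::head(which(b$dis == 1L), needCase)
    takeCtrl <- utils::head(which(b$dis == 0L), needCtrl)
    take <- c(takeCase, takeCtrl)
    needCase <- needCase - length(takeCase)
    needCtrl <- needCtrl - length(takeCtrl)
    if (length(take)) {
      keptN[[length(keptN) + 1]] <- b$nuclear[take, , drop = FALSE]
      keptM[[length(keptM) + 1]] <- b$mito[take, , drop = FALSE]
      keptD[[length(keptD) + 1]] <- b$dis[take]
      keptS[[length(keptS) + 1]] <- b$sp[take]
    }
    # size the next batch from the observed case rate and the rarer quota
    rateCase <- max(mean(b$dis), 1 / batch)
    rateCtrl <- max(1 - mean(b$dis), 1 / batch)
    need <- max(needCase / rateCase, needCtrl / rateCtrl)
    batch <- as.integer(min(1e6, max(1000, ceiling(1.25 * need))))
  }
  nuclear <- do.call(rbind, keptN)
  mito <- do.call(rbind, keptM)
  dis <- unlist(keptD)
  sp <- unlist(keptS)
  ord <- order(-dis)  # cases first, stable
  nuclear <- nuclear[ord, , drop = FALSE]
  mito <- mito[ord, , drop = FALSE]
  dis <- dis[ord]; sp <- sp[ord]

  L <- config@nNuclear
  mtPos <- 100L + 200L * seq_len(config@nMt)
  variants <- data.frame(
    id = c(sprintf("rs%05d", seq_len(L)), sprintf("mt.%d", mtPos)),
    chrom = c(rep("1", L), rep("MT", config@nMt)),
    pos = c(1000L * seq_len(L), mtPos),
    ref = c(rep("A", L), rep("T", config@nMt)),
    alt = c(rep("G", L), rep("C", config@nMt)),
    maf = NA_real_, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("ind%06d", seq_along(dis)),
    cohort = ifelse(dis == 1L, "case", "control"),
    disease_status = dis,
    subpop = as.numeric(sp),
    stringsAsFactors = FALSE)
  Cohort(nuclear, mito, variants, samples)
}

#' Principal-component scores from a nuclear genotype matrix
#'
#' Centers each SNP column at twice its allele frequency, scales by
#' \eqn{\sqrt{2 p (1 - p)}}, mean-imputes missing entries, and returns
#' the leading k left singular-vector scores — the standard covariates
#' used to adjust association scans for population stratification.
#' Deterministic up to column sign.
#'
#' @param nuclear samples x SNPs dosage matrix.
#' @param k number of components (0 gives a zero-column matrix).
#' @return samples x k matrix with columns \code{pc1..pck}.
#' @export
computePCs <- function(nuclear, k) {
  n <- nrow(nuclear)
  if (k == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  if (n < k + 1) stop("need at least k + 1 samples")
  p <- colMeans(nuclear, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (length(keep) < k) stop("need at least k polymorphic SNPs")
  Z <- sweep(nuclear[, keep, drop = FALSE], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = 0)
  if (length(sv$d) < k || sv$d[k] < 1e-8 * sv$d[1])
    stop("k exceeds the rank of the genotype matrix")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
}

#' Attach principal-component covariates to a cohort
#'
#' Computes \code{\link{computePCs}} on the cohort's nuclear matrix and
#' installs the scores as the cohort's covariate columns (replacing any
#' existing covariates).
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param k number of components.
#' @return The cohort with covariate columns \code{pc1..pck}.
#' @export
addPCs <- function(cohort, k) {
  pcs <- computePCs(cohort@nuclear, k)
  s <- cbind(cohort@samples[, 1:3, drop = FALSE], as.data.frame(pcs))
  Cohort(cohort@nuclear, cohort@mito, cohort@variants, s)
}

#' Monte-Carlo power for the coupled mitonuclear pair
#'
#' Repeatedly simulates a cohort with the configured direct mt-nuclear
#' coupling and scans the designated pair with the case-only scan
#' (dominant coding by default, matching the 2x2 construction of the
#' analytic power formula), returning the empirical rejection rate at
#' \code{alpha} with its binomial standard error. Serves as the
#' independent Monte-Carlo oracle for \code{\link{associationPower}}.
#'
#' @param config a \code{\link{simConfig}} with \code{couplingOR} set;
#'   replicate r uses seed \code{config@seed + r}.
#' @param nReps number of replicates, at least 100.
#' @param alpha per-test significance level.
#' @param coding genotype coding passed to the scan.
#' @return List with \code{rate}, \code{se}, \code{nReps}, \code{alpha}.
#' @export
powerExperiment <- function(config, nReps, alpha, coding = "dominant") {
  if (is.na(config@couplingOR)) stop("config must set couplingOR")
  if (nReps < 100) stop("nReps must be at least 100")
  sc <- scanConfig(coding = coding)
  rej <- 0L
  for (r in seq_len(nReps)) {
    cfg <- config
    cfg@seed <- config@seed + r
    ch <- simulateCohort(cfg)
    mtId <- colnames(ch@mito)[config@couplingPair[1]]
    nId <- colnames(ch@nuclear)[config@couplingPair[2]]
    res <- caseOnlyScan(ch, mtId, nId, sc)
    if (!is.na(res$p[1]) && res$status[1] == "ok" && res$p[1] < alpha)
      rej <- rej + 1L
  }
  rate <- rej / nReps
  list(rate = rate, se = sqrt(rate * (1 - rate) / nReps),
       nReps = nReps, alpha = alpha)
}
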