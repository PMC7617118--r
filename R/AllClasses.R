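#' Cohort: aligned nuclear and mitochondrial genotypes with metadata
#'
#' Container holding a cohort's diploid nuclear genotype matrix, haploid
#' mitochondrial genotype matrix, variant metadata and sample metadata in a
#' single aligned object. Rows of both genotype matrices follow the sample
#' table; columns follow the variant table (nuclear variants first, then
#' mitochondrial).
#'
#' Genotypes are stored as ALT-allele counts: nuclear entries are diploid
#' dosages in \{0, 1, 2, NA\}, mitochondrial entries are haploid calls in
#' \{0, 1, NA\}. Heteroplasmy is not representable; heterozygous
#' mitochondrial input calls are treated as missing. Minor-allele coding is
#' applied at analysis time (see \code{\link{additiveDosage}}), so the
#' stored matrices survive a write/read round trip unchanged.
#'
#' @slot nuclear integer matrix, samples x nuclear SNPs, dosages in
#'   \{0,1,2,NA\}.
#' @slot mito integer matrix, samples x mtSNPs, haploid calls in
#'   \{0,1,NA\}.
#' @slot variants data.frame with columns \code{id}, \code{chrom} (1-22 or
#'   "MT"), \code{pos} (1-based, GRCh37 convention), \code{ref}, \code{alt},
#'   \code{maf}; nuclear rows first, then mitochondrial. \code{maf} is always
#'   recomputed from the genotype matrices, never trusted from input.
#' @slot samples data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{disease_status} (0 = unaffected, 1 = affected) followed by zero or
#'   more numeric covariate columns (e.g. principal-component scores).
#'
#' @seealso \code{\link{readCohort}}, \code{\link{simulateCohort}},
#'   \code{\link{nuclearGeno}}
#' @export
setClass("Cohort",
  representation(
    nuclear  = "matrix",
    mito     = "matrix",
    variants = "data.frame",
    samples  = "data.frame"
  )
)

.validCohort <- function(object) {
  msg <- character()
  nuc <- object@nuclear
  mit <- object@mito
  v <- object@variants
  s <- object@samples
  if (nrow(nuc) != nrow(s) || nrow(mit) != nrow(s))
    msg <- c(msg, "genotype matrix rows must match the sample table")
  if (ncol(nuc) + ncol(mit) != nrow(v))
    msg <- c(msg, "variant table rows must match total genotype columns")
  need <- c("id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variant table needs columns:",
                        paste(need, collapse = ", ")))
  sneed <- c("sample_id", "cohort", "disease_status")
  if (!all(sneed %in% names(s)[seq_len(min(3, ncol(s)))]))
    msg <- c(msg, "sample table must start with sample_id, cohort, disease_status")
  if (length(msg)) return(msg)

  if (nrow(v)) {
    if (any(v$pos < 1)) msg <- c(msg, "variant positions must be >= 1")
    isMT <- v$chrom == "MT"
    if (!identical(isMT, startsWith(v$id, "mt.")))
      msg <- c(msg, "chrom 'MT' iff id begins 'mt.'")
    if (ncol(mit) && !all(v$chrom[seq_len(nrow(v)) > ncol(nuc)] == "MT"))
      msg <- c(msg, "mitochondrial variants must follow nuclear variants")
    if (any(v$maf < 0 | v$maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (length(nuc) && !all(nuc %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "nuclear dosages must be 0, 1, 2 or NA")
  if (length(mit) && !all(mit %in% c(0L, 1L, NA)))
    msg <- c(msg, "mitochondrial calls must be 0, 1 or NA (haploid)")
  if (!all(s$disease_status %in% c(0L, 1L)))
    msg <- c(msg, "disease_status must be 0 or 1")
  if (ncol(s) > 3 && !all(vapply(s[-(1:3)], is.numeric, logical(1))))
    msg <- c(msg, "covariate columns must be numeric")
  if (length(msg)) msg else TRUE
}
setValidity("Cohort", .validCohort)

#' Construct a Cohort, recomputing allele frequencies
#'
#' @param nuclear samples x nSNP matrix of diploid ALT dosages.
#' @param mito samples x mtSNP matrix of haploid ALT calls.
#' @param variants variant metadata (nuclear rows first, then mito); any
#'   incoming \code{maf} column is discarded and recomputed from genotypes.
#' @param samples sample metadata.
#' @return A validated \code{\linkS4class{Cohort}}.
#' @export
Cohort <- function(nuclear, mito, variants, samples) {
  nuclear <- as.matrix(nuclear)
  mito <- as.matrix(mito)
  storage.mode(nuclear) <- "integer"
  storage.mode(mito) <- "integer"
  variants$maf <- c(.diploidMAFs(nuclear), .haploidMAFs(mito))
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  if (nrow(variants)) {
    nNuc <- ncol(nuclear)
    colnames(nuclear) <- variants$id[seq_len(nNuc)]
    colnames(mito) <- variants$id[seq_len(nrow(variants)) > nNuc]
  }
  rownames(nuclear) <- samples$sample_id
  rownames(mito) <- samples$sample_id
  new("Cohort", nuclear = nuclear, mito = mito,
      variants = variants, samples = samples)
}

.diploidMAFs <- function(m) {
  if (!ncol(m)) return(numeric(0))
  f <- colMeans(m, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

.haploidMAFs <- function(m) {
  if (!ncol(m)) return(numeric(0))
  f <- colMeans(m, na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Scan configuration
#'
#' Parameters shared by the association scan and the combined-cohort
#' interaction models.
#'
#' @slot covariateCount number of leading covariate columns of the sample
#'   table used as adjustment terms (typically principal-component scores).
#' @slot fdrThreshold q-value cutoff used when selecting combinations
#'   (default 0.05).
#' @slot alphaGenomewide nominal per-test significance level (default 5e-8).
#' @slot minCellCount minimum count for every observed genotype class of a
#'   test; smaller tests are skipped rather than fitted (default 5).
#' @slot coding genotype coding for the nuclear exposure: "additive"
#'   (per-minor-allele dosage, the default) or "dominant" (minor-allele
#'   carrier indicator, used by the closed-form and power oracles).
#' @export
setClass("ScanConfig",
  representation(
    covariateCount = "integer",
    fdrThreshold = "numeric",
    alphaGenomewide = "numeric",
    minCellCount = "integer",
    coding = "character"
  ),
  prototype(
    covariateCount = 0L,
    fdrThreshold = 0.05,
    alphaGenomewide = 5e-8,
    minCellCount = 5L,
    coding = "additive"
  )
)

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@covariateCount < 0) msg <- c(msg, "covariateCount must be >= 0")
  if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
    msg <- c(msg, "fdrThreshold must lie in (0,1)")
  if (!object@coding %in% c("additive", "dominant"))
    msg <- c(msg, "coding must be 'additive' or 'dominant'")
  if (length(msg)) msg else TRUE
})

#' @rdname ScanConfig-class
#' @param covariateCount,fdrThreshold,alphaGenomewide,minCellCount,coding
#'   see the corresponding slots.
#' @return A \code{ScanConfig} object.
#' @export
scanConfig <- function(covariateCount = 0, fdrThreshold = 0.05,
                       alphaGenomewide = 5e-8, minCellCount = 5,
                       coding = "additive") {
  new("ScanConfig",
      covariateCount = as.integer(covariateCount),
      fdrThreshold = fdrThreshold,
      alphaGenomewide = alphaGenomewide,
      minCellCount = as.integer(minCellCount),
      coding = coding)
}

#' Simulation configuration for synthetic stratified cohorts
#'
#' Full generative specification for \code{\link{simulateCohort}}: a
#' case/control cohort drawn from a mixture of subpopulations whose nuclear
#' allele frequencies diverge under the Balding-Nichols model, with nuclear
#' LD blocks generated by first-order haplotype copying, haploid mtSNPs with
#' subpopulation-specific frequencies, a logistic disease model with
#' optional nuclear, mitochondrial and mtSNP x nSNP interaction effects, and
#' an optional direct (disease-free) mt-nuclear coupling used for power
#' experiments.
#'
#' @slot nCases,nControls ascertained sample counts.
#' @slot nNuclear number of nuclear SNPs.
#' @slot blockSize SNPs per LD block.
#' @slot withinBlockCorr haplotype copying probability in [0,1): allele j of
#'   a haplotype copies allele j-1 with this probability, else is drawn
#'   fresh; blocks are independent.
#' @slot nMt number of mitochondrial SNPs.
#' @slot subpopWeights mixture weights over subpopulations (sum to 1).
#' @slot fst Balding-Nichols differentiation in [0, 0.5).
#' @slot baseFreqRange interval for ancestral nuclear ALT frequencies.
#' @slot mtFreqs optional subpopulations x mtSNPs matrix of mt ALT
#'   frequencies; when NULL, ancestral frequencies are drawn uniformly in
#'   (0.2, 0.8) (common variants) and diverged at \code{fst}.
#' @slot b0 disease-model intercept on the log-odds scale; the default gives
#'   population prevalence ~0.01, rare enough for the case-only identity.
#' @slot bN,bM per-allele nuclear / mitochondrial log-odds effects, named by
#'   1-based variant column index.
#' @slot bI data.frame(mt, n, beta): interaction effects on the log-odds of
#'   disease for mt call x nuclear dosage products.
#' @slot couplingOR optional direct odds ratio linking one mtSNP allele to
#'   carrier status at one nuclear SNP, independent of disease (NA = none).
#' @slot couplingPair integer pair (mt column, nuclear column) the coupling
#'   applies to.
#' @slot seed integer RNG seed; identical seeds give identical cohorts.
#' @export
setClass("SimConfig",
  representation(
    nCases = "integer", nControls = "integer",
    nNuclear = "integer", blockSize = "integer", withinBlockCorr = "numeric",
    nMt = "integer", subpopWeights = "numeric", fst = "numeric",
    baseFreqRange = "numeric", mtFreqs = "ANY",
    b0 = "numeric", bN = "numeric", bM = "numeric", bI = "data.frame",
    couplingOR = "numeric", couplingPair = "integer",
    seed = "integer"
  ),
  prototype(
    nCases = 1000L, nControls = 1000L,
    nNuclear = 100L, blockSize = 10L, withinBlockCorr = 0.8,
    nMt = 4L, subpopWeights = 1, fst = 0,
    baseFreqRange = c(0.1, 0.9), mtFreqs = NULL,
    b0 = stats::qlogis(0.01), bN = numeric(0), bM = numeric(0),
    bI = data.frame(mt = integer(0), n = integer(0), beta = numeric(0)),
    couplingOR = NA_real_, couplingPair = c(1L, 1L),
    seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nCases + object@nControls <= 0)
    msg <- c(msg, "nCases + nControls must be positive")
  if (abs(sum(object@subpopWeights) - 1) > 1e-8 || any(object@subpopWeights <= 0))
    msg <- c(msg, "subpopWeights must be positive and sum to 1")
  if (object@fst < 0 || object@fst >= 0.5)
    msg <- c(msg, "fst must lie in [0, 0.5)")
  if (object@withinBlockCorr < 0 || object@withinBlockCorr >= 1)
    msg <- c(msg, "withinBlockCorr must lie in [0, 1)")
  if (any(object@baseFreqRange <= 0) || any(object@baseFreqRange >= 1) ||
      diff(object@baseFreqRange) < 0)
    msg <- c(msg, "baseFreqRange must be an increasing interval inside (0,1)")
  if (!is.null(object@mtFreqs)) {
    mf <- object@mtFreqs
    if (!is.matrix(mf) || nrow(mf) != length(object@subpopWeights) ||
        ncol(mf) != object@nMt || any(mf <= 0) || any(mf >= 1))
      msg <- c(msg, "mtFreqs must be a subpop x mtSNP matrix of frequencies in (0,1)")
  }
  if (nrow(object@bI) &&
      !all(c("mt", "n", "beta") %in% names(object@bI)))
    msg <- c(msg, "bI needs columns mt, n, beta")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nCases,nControls,nNuclear,blockSize,withinBlockCorr,nMt,fst see
#'   the corresponding slots.
#' @param subpopWeights,baseFreqRange,mtFreqs,b0,bN,bM,bI see slots.
#' @param couplingOR,couplingPair,seed see slots.
#' @return A \code{SimConfig} object.
#' @export
simConfig <- function(nCases = 1000, nControls = 1000, nNuclear = 100,
                      blockSize = 10, withinBlockCorr = 0.8, nMt = 4,
                      subpopWeights = 1, fst = 0,
                      baseFreqRange = c(0.1, 0.9), mtFreqs = NULL,
                      b0 = stats::qlogis(0.01),
                      bN = numeric(0), bM = numeric(0),
                      bI = data.frame(mt = integer(0), n = integer(0),
                                      beta = numeric(0)),
                      couplingOR = NA_real_, couplingPair = c(1, 1),
                      seed = 1) {
  if (!is.null(mtFreqs)) mtFreqs <- as.matrix(mtFreqs)
  new("SimConfig",
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      nNuclear = as.integer(nNuclear), blockSize = as.integer(blockSize),
      withinBlockCorr = withinBlockCorr, nMt = as.integer(nMt),
      subpopWeights = subpopWeights, fst = fst,
      baseFreqRange = baseFreqRange, mtFreqs = mtFreqs,
      b0 = b0, bN = bN, bM = bM, bI = bI,
      couplingOR = couplingOR, couplingPair = as.integer(couplingPair),
      seed = as.integer(seed))
}
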