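#' Joint 2x2 cell probabilities with given margins and odds ratio
#'
#' Solves for the unique 2x2 probability table whose row margin, column
#' margin and cross-product (odds) ratio take the requested values: the
#' alternative hypothesis underlying the analytic power calculation. The
#' cell p11 is the admissible root of a quadratic (Plackett's construction);
#' the other cells follow from the margins.
#'
#' @param pRow row-margin probability in (0, 1), e.g. the mtSNP minor
#'   allele frequency.
#' @param pCol column-margin probability in (0, 1), e.g. the nuclear
#'   minor-allele carrier frequency.
#' @param oddsRatio target cross-product ratio, > 0.
#' @return Named numeric vector \code{c(p11, p10, p01, p00)}; all cells in
#'   (0, 1) and summing to 1.
#' @examples
#' solveJointDistribution(0.2, 0.1, 1.5)
#' @export
solveJointDistribution <- function(pRow, pCol, oddsRatio) {
  if (pRow <= 0 || pRow >= 1 || pCol <= 0 || pCol >= 1)
    stop("margins must lie strictly in (0, 1)")
  if (oddsRatio <= 0) stop("oddsRatio must be positive")
  if (abs(oddsRatio - 1) < 1e-12) {
    p11 <- pRow * pCol
  } else {
    th <- oddsRatio
    a <- th - 1
    b <- -((th - 1) * (pRow + pCol) + 1)
    cc <- th * pRow * pCol
    disc <- b * b - 4 * a * cc
    if (disc < 0) stop("margins incompatible with the requested odds ratio")
    lo <- max(0, pRow + pCol - 1)
    hi <- min(pRow, pCol)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    ok <- roots > lo & roots < hi
    if (!any(ok)) stop("margins incompatible with the requested odds ratio")
    p11 <- roots[ok][1]
  }
  tab <- c(p11 = p11, p10 = pRow - p11, p01 = pCol - p11,
           p00 = 1 - pRow - pCol + p11)
  if (any(tab <= 0))
    stop("margins incompatible with the requested odds ratio")
  tab
}

#' Analytic power for detecting a mitonuclear association
#'
#' Power of the two-sided Wald test of the log odds ratio in a
#' person-level 2x2 table crossing the mitochondrial allele indicator with
#' nuclear minor-allele carrier status (carrier frequency
#' \eqn{1 - (1 - maf_n)^2}, dominant dichotomisation). Under the
#' alternative built by \code{\link{solveJointDistribution}}, the log odds
#' ratio estimate is approximately normal with variance
#' \eqn{\sum_{ij} 1/(n p_{ij})}; no continuity correction is applied.
#' Power is monotone non-decreasing in \code{n} and in \eqn{|\log OR|}.
#'
#' @param n cohort size (individuals), >= 10.
#' @param mafMt mitochondrial minor allele frequency in (0, 0.5].
#' @param mafN nuclear minor allele frequency in (0, 0.5].
#' @param oddsRatio association odds ratio between the mt allele and
#'   nuclear carrier status, > 0.
#' @param alpha two-sided type-I error in (0, 1).
#' @return Power in [0, 1]; equals \code{alpha} when \code{oddsRatio} is 1.
#' @examples
#' associationPower(2000, 0.25, 0.10, 1.5, 0.05)
#' @export
associationPower <- function(n, mafMt, mafN, oddsRatio, alpha) {
  if (n < 10) stop("n must be at least 10")
  if (mafMt <= 0 || mafMt > 0.5 || mafN <= 0 || mafN > 0.5)
    stop("allele frequencies must lie in (0, 0.5]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  carrier <- 1 - (1 - mafN)^2
  tab <- solveJointDistribution(mafMt, carrier, oddsRatio)
  se <- sqrt(sum(1 / (n * tab)))
  delta <- abs(log(oddsRatio))
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(delta / se - zcrit) + stats::pnorm(-delta / se - zcrit)
}

#' Minimum mtSNP minor allele frequency achieving a target power
#'
#' Inverts \code{\link{associationPower}} over the mtSNP frequency by
#' bisection (tolerance 1e-4 on the frequency scale). When even
#' \code{mafMt = 0.5} falls short of the target, the threshold is reported
#' as unachievable together with the power attained at 0.5 — which is the
#' situation at genome-wide alpha = 5e-8 with n = 2000 and OR = 1.5 under
#' this approximation; a finite threshold exists at laxer alpha.
#'
#' @inheritParams associationPower
#' @param targetPower required power in (0, 1).
#' @return A list with elements \code{achievable} (logical), \code{mafMt}
#'   (the minimal frequency, or NA when unachievable) and \code{powerAtMax}
#'   (power at mafMt = 0.5).
#' @examples
#' minimumMtMAF(2000, 0.10, 1.5, alpha = 0.05, targetPower = 0.8)
#' @export
minimumMtMAF <- function(n, mafN, oddsRatio, alpha, targetPower = 0.8) {
  if (targetPower <= 0 || targetPower >= 1)
    stop("targetPower must lie in (0, 1)")
  pw <- function(f) associationPower(n, f, mafN, oddsRatio, alpha)
  pMax <- pw(0.5)
  if (pMax < targetPower)
    return(list(achievable = FALSE, mafMt = NA_real_, powerAtMax = pMax))
  lo <- 1e-6
  if (pw(lo) >= targetPower)
    return(list(achievable = TRUE, mafMt = lo, powerAtMax = pMax))
  hi <- 0.5
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= targetPower) hi <- mid else lo <- mid
  }
  list(achievable = TRUE, mafMt = hi, powerAtMax = pMax)
}
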