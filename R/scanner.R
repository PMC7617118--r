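#' Additive minor-allele dosage
#'
#' Recodes a diploid ALT-dosage vector so that it counts copies of the
#' cohort-minor allele: when the ALT allele frequency exceeds 0.5 the
#' dosages are flipped to \code{2 - x}. Minor/major orientation is always
#' defined within the analysis cohort.
#'
#' @param calls diploid dosage vector in \{0,1,2,NA\} counting ALT alleles.
#' @param verbose emit a message when the coding is flipped.
#' @return Dosage vector counting minor alleles, with attribute
#'   \code{flipped}.
#' @export
additiveDosage <- function(calls, verbose = FALSE) {
  f <- mean(calls, na.rm = TRUE) / 2
  flip <- !is.nan(f) && f > 0.5
  if (flip) {
    if (verbose) message("ALT allele is major; dosage flipped to minor allele")
    calls <- 2L - calls
  }
  structure(calls, flipped = flip)
}

# haploid analogue: minor-allele indicator for an mtSNP column
.minorIndicator <- function(calls) {
  f <- mean(calls, na.rm = TRUE)
  if (!is.nan(f) && f > 0.5) calls <- 1L - calls
  calls
}

#' Maximum-likelihood logistic regression with degeneracy reporting
#'
#' Thin wrapper around binomial IRLS (\code{stats::glm.fit}, deviance
#' tolerance 1e-8, at most 50 iterations) that reports Wald z statistics
#' and two-sided p-values per coefficient and classifies degenerate fits:
#' complete/quasi-separation (a fitted probability within 1e-8 of 0 or 1
#' together with a diverging coefficient) and non-convergence.
#'
#' @param y binary response vector (no missing values).
#' @param X design matrix including the intercept column.
#' @return List with \code{coef}, \code{se}, \code{z}, \code{p} (per
#'   column of \code{X}), \code{converged}, \code{status} one of "ok",
#'   "separation", "not_converged", and \code{n} the rows used.
#' @export
fitLogistic <- function(y, X) {
  if (length(unique(y)) < 2) stop("response is constant")
  out <- .fitLogisticW(y, as.matrix(X), rep(1, length(y)))
  out$n <- length(y)
  out
}

# weighted binomial fit shared by the per-sample and collapsed-table paths;
# y may be a per-row success proportion with prior weights w, which yields
# the identical MLE and Fisher information as the expanded 0/1 data
.fitLogisticW <- function(y, X, w) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  status <- "ok"
  if (!fit$converged) status <- "not_converged"
  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) &&
    max(abs(beta), na.rm = TRUE) > 15
  if (sep) status <- "separation"
  se <- rep(NA_real_, ncol(X))
  if (fit$rank < ncol(X)) {
    status <- "not_converged"
  } else {
    ww <- fit$weights
    info <- crossprod(X, X * ww)
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) status <- "not_converged" else se <- sqrt(diag(cov))
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = beta, se = se, z = z, p = p,
       converged = fit$converged, status = status, n = sum(w))
}

#' Case-only mitonuclear association scan
#'
#' For each requested mtSNP, regresses the mitochondrial minor-allele
#' indicator on each nuclear SNP's dosage plus the leading covariates
#' (logistic regression, complete-case per test). q-values are assigned by
#' Benjamini-Hochberg over all tests returned by the call — the family is
#' the full set of mtSNP x nSNP combinations examined in the run, not one
#' mtSNP at a time. Tests in which any observed genotype class (dosage or
#' response) has fewer than \code{minCellCount} members, or in which either
#' variable is constant on the complete cases, are skipped rather than
#' fitted, to avoid separation artifacts.
#'
#' @param cohort a \code{\linkS4class{Cohort}}; typically a single-cohort
#'   subset (e.g. affected individuals only).
#' @param mtIds character vector of mtSNP ids to scan (response variants);
#'   each must be polymorphic in the cohort.
#' @param nIds nuclear SNP ids to test; default all nuclear variants.
#' @param config a \code{\link{scanConfig}}.
#' @return data.frame with one row per mtSNP x nSNP test: \code{mtsnp_id},
#'   \code{nsnp_id}, \code{beta}, \code{se}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{q}, \code{n_used}, \code{status}.
#' @export
caseOnlyScan <- function(cohort, mtIds, nIds = NULL, config = scanConfig()) {
  if (is.null(nIds)) nIds <- colnames(cohort@nuclear)
  k <- config@covariateCount
  covs <- .covariates(cohort, k)
  covOK <- if (k > 0) stats::complete.cases(covs) else
    rep(TRUE, nSamples(cohort))
  nTot <- length(mtIds) * length(nIds)
  mtv <- nv <- stat <- character(nTot)
  beta <- se <- p <- rep(NA_real_, nTot)
  nUsed <- integer(nTot)
  minCell <- config@minCellCount
  r <- 0L
  for (mt in mtIds) {
    mcol <- cohort@mito[, .mustCol(cohort, mt, "mito")]
    y0 <- .minorIndicator(mcol)
    if (length(unique(y0[!is.na(y0)])) < 2)
      stop("mtSNP is monomorphic in this cohort: ", mt)
    for (nid in nIds) {
      d0 <- additiveDosage(cohort@nuclear[, .mustCol(cohort, nid, "nuclear")])
      if (config@coding == "dominant") d0 <- as.integer(d0 > 0)
      cc <- !is.na(y0) & !is.na(d0) & covOK
      r <- r + 1L
      mtv[r] <- mt; nv[r] <- nid
      nUsed[r] <- sum(cc)
      stat[r] <- "skipped_low_count"
      if (k == 0) {
        # no covariates: the likelihood depends on the data only through
        # the 2 x (dosage classes) table, so fit weighted IRLS on it
        y <- y0[cc]; d <- d0[cc]
        cnt <- tabulate(1L + y + 2L * d, nbins = 6L)
        dcls <- cnt[c(1, 3, 5)] + cnt[c(2, 4, 6)]
        ycls <- c(sum(cnt[c(1, 3, 5)]), sum(cnt[c(2, 4, 6)]))
        lev <- which(dcls > 0L)
        if (length(lev) < 2 || any(dcls[lev] < minCell) ||
            any(ycls == 0L) || any(ycls < minCell)) next
        dv <- lev - 1
        fit <- .fitLogisticW(cnt[2 * lev] / dcls[lev],
                             cbind(1, dv), dcls[lev])
      } else {
        y <- y0[cc]; d <- as.numeric(d0[cc])
        if (!.cellsOK(y, d, minCell)) next
        X <- cbind(1, d, covs[cc, , drop = FALSE])
        fit <- fitLogistic(y, X)
      }
      stat[r] <- fit$status
      if (fit$status == "ok") {
        beta[r] <- fit$coef[2]
        se[r] <- fit$se[2]
        p[r] <- fit$p[2]
      }
    }
  }
  out <- data.frame(mtsnp_id = mtv, nsnp_id = nv, beta = beta, se = se,
                    or = exp(beta), ci_lo = exp(beta - 1.96 * se),
                    ci_hi = exp(beta + 1.96 * se), p = p, q = NA_real_,
                    n_used = nUsed, status = stat,
                    stringsAsFactors = FALSE)
  ok <- out$status == "ok" & !is.na(out$p)
  if (any(ok)) out$q[ok] <- bhFDR(out$p[ok])
  out
}

.mustCol <- function(cohort, id, type) {
  m <- if (type == "mito") cohort@mito else cohort@nuclear
  j <- match(id, colnames(m))
  if (is.na(j)) stop(type, " variant not found: ", id)
  j
}

# every observed class of predictor and response must reach the minimum
.cellsOK <- function(y, d, minCell) {
  if (length(y) == 0) return(FALSE)
  ty <- table(y); td <- table(d)
  length(ty) >= 2 && length(td) >= 2 &&
    all(ty >= minCell) && all(td >= minCell)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment: for sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, clipped at 1 and mapped
#' back to input order. Controls the false discovery rate over the family
#' of all combinations examined.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in input order; empty input gives empty output.
#' @export
bhFDR <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in (0, 1]")
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Genomic inflation factor (lambda)
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the theoretical null median \code{qchisq(0.5, 1)}. Values
#' well above 1 signal confounding such as population stratification.
#'
#' @param p at least 20 p-values in (0, 1].
#' @return lambda.
#' @export
genomicInflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 20) stop("need at least 20 p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Q-Q plot coordinates for a set of p-values
#'
#' @param p non-empty vector of p-values.
#' @return data.frame with \code{expected} = -log10((i - 0.5)/m) for ranks
#'   i = 1..m and \code{observed} = sorted -log10 p, both in decreasing
#'   order so the most significant test comes first.
#' @export
qqData <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p)))
}
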