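# shared preparation for the combined-cohort models
.pairData <- function(cohort, mtId, nId, config) {
  mt <- .minorIndicator(cohort@mito[, .mustCol(cohort, mtId, "mito")])
  d <- additiveDosage(cohort@nuclear[, .mustCol(cohort, nId, "nuclear")])
  if (config@coding == "dominant") d <- as.integer(d > 0)
  dis <- cohort@samples$disease_status
  k <- config@covariateCount
  covs <- .covariates(cohort, k)
  cc <- !is.na(mt) & !is.na(d) & !is.na(dis) &
    (if (k > 0) stats::complete.cases(covs) else TRUE)
  list(mt = mt[cc], d = as.numeric(d[cc]), dis = dis[cc],
       covs = covs[cc, , drop = FALSE], n = sum(cc))
}

.termRow <- function(fit, j, n) {
  out <- list(beta = NA_real_, se = NA_real_, or = NA_real_,
              ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
              n_used = n, status = fit$status)
  if (fit$status == "ok") {
    b <- fit$coef[j]; s <- fit$se[j]
    out$beta <- b; out$se <- s; out$or <- exp(b)
    out$ci_lo <- exp(b - 1.96 * s); out$ci_hi <- exp(b + 1.96 * s)
    out$p <- fit$p[j]
  }
  out
}

#' Disease-status modulation of a mitonuclear association
#'
#' Tests whether the association between an mtSNP and a nuclear SNP
#' differs between affected and unaffected individuals: logistic
#' regression of the mitochondrial minor-allele indicator on nuclear
#' dosage, disease status, their interaction, and covariates, in the
#' pooled two-cohort data. The reported term is the disease x dosage
#' interaction; on saturated binary data its coefficient equals the
#' difference of the stratified log odds ratios.
#'
#' @param cohort pooled \code{\linkS4class{Cohort}} containing both
#'   disease strata.
#' @param mtId,nId variant identifiers.
#' @param config a \code{\link{scanConfig}}.
#' @return List with \code{beta}, \code{se}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{n_used}, \code{status} for the
#'   interaction term.
#' @export
modulationTest <- function(cohort, mtId, nId, config = scanConfig()) {
  pd <- .pairData(cohort, mtId, nId, config)
  if (length(unique(pd$dis)) < 2)
    stop("both disease strata must be present")
  X <- cbind(1, pd$d, pd$dis, pd$d * pd$dis, pd$covs)
  fit <- fitLogistic(pd$mt, X)
  .termRow(fit, 4, pd$n)
}

#' Effect of an mtSNP x nSNP interaction on disease risk
#'
#' Logistic regression of disease status on the mitochondrial indicator,
#' nuclear dosage, their product, and covariates, in the pooled
#' two-cohort data. The reported term is the mtSNP x nSNP product — the
#' effect of carrying the mitonuclear combination on disease risk beyond
#' the two marginal effects.
#'
#' @inheritParams modulationTest
#' @return List as in \code{\link{modulationTest}} for the product term.
#' @export
riskInteractionTest <- function(cohort, mtId, nId, config = scanConfig()) {
  pd <- .pairData(cohort, mtId, nId, config)
  if (length(unique(pd$dis)) < 2)
    stop("both disease strata must be present")
  X <- cbind(1, pd$mt, pd$d, pd$mt * pd$d, pd$covs)
  fit <- fitLogistic(pd$dis, X)
  .termRow(fit, 4, pd$n)
}

#' Marginal association of one variant with disease
#'
#' Logistic regression of disease status on a single variant (haploid
#' minor-allele indicator for mitochondrial variants, additive dosage for
#' nuclear ones) plus covariates.
#'
#' @param cohort pooled \code{\linkS4class{Cohort}}.
#' @param variantId mtSNP or nSNP identifier.
#' @param config a \code{\link{scanConfig}}.
#' @return List with \code{beta}, \code{se}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{n_used}, \code{status} for the variant
#'   term.
#' @export
marginalDiseaseAssociation <- function(cohort, variantId,
                                       config = scanConfig()) {
  loc <- .findVariant(cohort, variantId)
  g <- if (loc$type == "mito")
    .minorIndicator(cohort@mito[, loc$col])
  else {
    d <- additiveDosage(cohort@nuclear[, loc$col])
    if (config@coding == "dominant") as.integer(d > 0) else d
  }
  dis <- cohort@samples$disease_status
  if (length(unique(dis[!is.na(dis)])) < 2)
    stop("both disease strata must be present")
  k <- config@covariateCount
  covs <- .covariates(cohort, k)
  cc <- !is.na(g) & !is.na(dis) &
    (if (k > 0) stats::complete.cases(covs) else TRUE)
  X <- cbind(1, as.numeric(g[cc]), covs[cc, , drop = FALSE])
  fit <- fitLogistic(dis[cc], X)
  .termRow(fit, 2, sum(cc))
}

#' Assemble the per-combination report
#'
#' For each selected mitonuclear combination, assembles the five model
#' fits reported per combination: (1) the case-only association in the
#' affected cohort, (2) the disease-status modulation of that association
#' in the pooled data, (3) and (4) the marginal disease associations of
#' the mtSNP and the nSNP, and (5) the effect of the mtSNP x nSNP
#' interaction on disease risk. Case-only q-values are Benjamini-Hochberg
#' adjusted across the report's combinations. Any component failure is
#' recorded in-row through its status field, never raised.
#'
#' @param cohort pooled \code{\linkS4class{Cohort}} with both disease
#'   strata.
#' @param pairs data.frame with columns \code{mtsnp_id} and
#'   \code{nsnp_id}, e.g. combinations reaching the FDR threshold in a
#'   per-cohort scan.
#' @param config a \code{\link{scanConfig}}.
#' @return data.frame, one row per combination, in input order; columns
#'   prefixed \code{assoc_} (case-only association), \code{mod_}
#'   (modulation), \code{mt_}/\code{n_} (marginal disease associations)
#'   and \code{int_} (risk interaction).
#' @export
combinationReport <- function(cohort, pairs, config = scanConfig()) {
  cols <- c("mtsnp_id", "nsnp_id",
            "assoc_beta", "assoc_or", "assoc_ci_lo", "assoc_ci_hi",
            "assoc_p", "assoc_q", "assoc_status",
            "mod_beta", "mod_se", "mod_or", "mod_ci_lo", "mod_ci_hi",
            "mod_p", "mod_status",
            "mt_p", "mt_or", "n_p", "n_or",
            "int_beta", "int_se", "int_or", "int_ci_lo", "int_ci_hi",
            "int_p", "int_status")
  if (!nrow(pairs)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), logical(0), simplify = FALSE), cols))
    return(out)
  }
  affected <- subsetSamples(cohort, cohort@samples$disease_status == 1)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mt <- pairs$mtsnp_id[i]; nid <- pairs$nsnp_id[i]
    row <- list(mtsnp_id = mt, nsnp_id = nid)
    assoc <- .tryRow(function()
      caseOnlyScan(affected, mt, nid, config)[1, ])
    row$assoc_beta <- assoc$beta; row$assoc_or <- assoc$or
    row$assoc_ci_lo <- assoc$ci_lo; row$assoc_ci_hi <- assoc$ci_hi
    row$assoc_p <- assoc$p; row$assoc_q <- NA_real_
    row$assoc_status <- assoc$status
    mod <- .tryRow(function() modulationTest(cohort, mt, nid, config))
    row$mod_beta <- mod$beta; row$mod_se <- mod$se; row$mod_or <- mod$or
    row$mod_ci_lo <- mod$ci_lo; row$mod_ci_hi <- mod$ci_hi
    row$mod_p <- mod$p; row$mod_status <- mod$status
    mtm <- .tryRow(function()
      marginalDiseaseAssociation(cohort, mt, config))
    row$mt_p <- mtm$p; row$mt_or <- mtm$or
    nm <- .tryRow(function()
      marginalDiseaseAssociation(cohort, nid, config))
    row$n_p <- nm$p; row$n_or <- nm$or
    ri <- .tryRow(function() riskInteractionTest(cohort, mt, nid, config))
    row$int_beta <- ri$beta; row$int_se <- ri$se; row$int_or <- ri$or
    row$int_ci_lo <- ri$ci_lo; row$int_ci_hi <- ri$ci_hi
    row$int_p <- ri$p; row$int_status <- ri$status
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$assoc_p)
  if (any(ok)) out$assoc_q[ok] <- bhFDR(out$assoc_p[ok])
  out
}

.tryRow <- function(f) {
  tryCatch(f(), error = function(e)
    list(beta = NA_real_, se = NA_real_, or = NA_real_, ci_lo = NA_real_,
         ci_hi = NA_real_, p = NA_real_, q = NA_real_, n_used = NA_integer_,
         status = paste0("error: ", conditionMessage(e))))
}
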