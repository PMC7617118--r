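#' @rdname Cohort-class
#' @param object,x a \code{Cohort}.
#' @export
setGeneric("nuclearGeno", function(x) standardGeneric("nuclearGeno"))

#' @rdname Cohort-class
#' @export
setGeneric("mitoGeno", function(x) standardGeneric("mitoGeno"))

#' @rdname Cohort-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname Cohort-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname Cohort-class
#' @export
setMethod("nuclearGeno", "Cohort", function(x) x@nuclear)

#' @rdname Cohort-class
#' @export
setMethod("mitoGeno", "Cohort", function(x) x@mito)

#' @rdname Cohort-class
#' @export
setMethod("variantInfo", "Cohort", function(x) x@variants)

#' @rdname Cohort-class
#' @export
setMethod("sampleInfo", "Cohort", function(x) x@samples)

#' @rdname Cohort-class
#' @export
setMethod("show", "Cohort", function(object) {
  s <- object@samples
  cat("Cohort:", nrow(s), "samples,",
      ncol(object@nuclear), "nuclear SNPs,",
      ncol(object@mito), "mtSNPs\n")
  if (nrow(s)) {
    cat("  cohorts:", paste(sprintf("%s (n=%d)", names(table(s$cohort)),
                                    as.integer(table(s$cohort))),
                            collapse = ", "), "\n")
    cat("  affected:", sum(s$disease_status == 1), "of", nrow(s), "\n")
  }
  k <- ncol(s) - 3
  cat("  covariates:", if (k > 0) paste(names(s)[-(1:3)], collapse = ", ")
      else "none", "\n")
})

#' Number of samples in a cohort
#' @param x a \code{Cohort}.
#' @return integer sample count.
#' @export
nSamples <- function(x) nrow(x@samples)

#' Subset a cohort by sample index
#'
#' @param x a \code{Cohort}.
#' @param idx logical or integer index over samples.
#' @return A \code{Cohort} with the selected samples; allele frequencies are
#'   recomputed for the subset, so minor-allele coding is always relative to
#'   the analysis cohort.
#' @export
subsetSamples <- function(x, idx) {
  Cohort(x@nuclear[idx, , drop = FALSE],
         x@mito[idx, , drop = FALSE],
         x@variants,
         x@samples[idx, , drop = FALSE])
}

#' Stack two cohorts sharing the same variants
#'
#' Used to pool an affected and an unaffected cohort ahead of the
#' disease-modulation and risk-interaction models. Variant identities must
#' match exactly (same ids in the same order); allele frequencies are
#' recomputed on the pooled samples.
#'
#' @param x,y \code{Cohort} objects with identical variant tables (up to
#'   \code{maf}).
#' @return The combined \code{Cohort}.
#' @export
combineCohorts <- function(x, y) {
  if (!identical(x@variants$id, y@variants$id))
    stop("cohorts must share the same variants in the same order")
  kx <- names(x@samples)
  if (!identical(kx, names(y@samples)))
    stop("cohorts must share the same sample-table columns")
  Cohort(rbind(x@nuclear, y@nuclear),
         rbind(x@mito, y@mito),
         x@variants,
         rbind(x@samples, y@samples))
}

# internal: locate a variant id, returning list(type, col)
.findVariant <- function(cohort, id) {
  j <- match(id, colnames(cohort@nuclear))
  if (!is.na(j)) return(list(type = "nuclear", col = j))
  j <- match(id, colnames(cohort@mito))
  if (!is.na(j)) return(list(type = "mito", col = j))
  stop("variant not found in cohort: ", id)
}

# internal: first k covariate columns as a numeric matrix
.covariates <- function(cohort, k) {
  s <- cohort@samples
  avail <- ncol(s) - 3
  if (k > avail)
    stop("requested ", k, " covariates but sample table has ", avail)
  if (k == 0)
    return(matrix(numeric(0), nrow = nrow(s), ncol = 0))
  as.matrix(s[, 3 + seq_len(k), drop = FALSE])
}
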