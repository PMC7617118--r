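#' Read a cohort from a VCF and a sample table
#'
#' Parses a VCF 4.2 genotype file (via \code{VariantAnnotation::readVcf})
#' together with a tab-delimited sample table whose columns are
#' \code{sample_id}, \code{cohort}, \code{disease_status} and then any
#' number of numeric covariates. The cohort is restricted to the
#' intersection of sample IDs (in sample-table order); VCF variant order is
#' preserved. Records on contig "MT", "chrM" or "26" become haploid
#' mitochondrial columns: diploid homozygous calls 0/0 and 1/1 collapse to
#' 0 and 1, heterozygous mitochondrial calls become missing (heteroplasmy
#' is not representable). Non-biallelic records are skipped with a warning.
#' Minor allele frequencies are recomputed from the genotypes, never
#' trusted from the input.
#'
#' @param genotypePath path to a VCF file with GT fields.
#' @param samplePath path to the tab-delimited sample table.
#' @return A \code{\linkS4class{Cohort}}.
#' @export
readCohort <- function(genotypePath, samplePath) {
  samples <- .readSampleTable(samplePath)
  v <- VariantAnnotation::readVcf(genotypePath)

  nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  refs <- as.character(VariantAnnotation::ref(v))
  alts <- vapply(as.list(VariantAnnotation::alt(v)),
                 function(a) if (length(a)) as.character(a)[1] else "N",
                 character(1))
  bad <- which(nAlt != 1 | nchar(refs) != 1 | nchar(alts) != 1)
  if (length(bad)) {
    warning("skipping ", length(bad), " non-biallelic/non-SNP record(s): ",
            paste(utils::head(rownames(v)[bad], 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "")
  }
  keep <- setdiff(seq_len(nrow(v)), bad)

  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[keep]
  pos <- BiocGenerics::start(rr)[keep]
  ids <- rownames(v)[keep]
  gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]

  vcfSamples <- colnames(gt)
  common <- samples$sample_id[samples$sample_id %in% vcfSamples]
  if (!length(common))
    stop("no overlapping sample IDs between VCF and sample table")
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  gt <- gt[, match(common, vcfSamples), drop = FALSE]

  isMT <- chrom %in% c("MT", "chrM", "26")
  chrom[isMT] <- "MT"
  ids[isMT] <- paste0("mt.", pos[isMT])

  nuc <- .parseGTMatrix(gt[!isMT, , drop = FALSE], .parseDiploidGT,
                        length(common))
  mit <- .parseGTMatrix(gt[isMT, , drop = FALSE], .parseHaploidGT,
                        length(common))

  ord <- c(which(!isMT), which(isMT))
  variants <- data.frame(id = ids[ord], chrom = chrom[ord], pos = pos[ord],
                         ref = refs[keep][ord], alt = alts[keep][ord],
                         maf = NA_real_, stringsAsFactors = FALSE)
  Cohort(nuc, mit, variants, samples)
}

# variants x samples character GT -> samples x variants integer matrix
.parseGTMatrix <- function(gtSub, parser, nSamp) {
  if (nrow(gtSub) == 0)
    return(matrix(integer(0), nrow = nSamp, ncol = 0))
  vapply(seq_len(nrow(gtSub)), function(i) parser(gtSub[i, ]),
         integer(nSamp))
}

.parseDiploidGT <- function(g) {
  out <- rep(NA_integer_, length(g))
  clean <- gsub("\\|", "/", g)
  out[clean == "0/0"] <- 0L
  out[clean %in% c("0/1", "1/0")] <- 1L
  out[clean == "1/1"] <- 2L
  # haploid call in a nuclear record: count the single allele
  out[clean == "0"] <- 0L
  out[clean == "1"] <- 1L
  out
}

.parseHaploidGT <- function(g) {
  out <- rep(NA_integer_, length(g))
  clean <- gsub("\\|", "/", g)
  out[clean %in% c("0", "0/0")] <- 0L
  out[clean %in% c("1", "1/1")] <- 1L
  # heterozygous mito calls are unrepresentable -> missing
  out
}

.readSampleTable <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed sample table: ", conditionMessage(e)))
  need <- c("sample_id", "cohort", "disease_status")
  if (ncol(tab) < 3 || !identical(names(tab)[1:3], need))
    stop("malformed sample table at line 1: header must start with ",
         paste(need, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab$cohort <- as.character(tab$cohort)
  badDS <- which(!tab$disease_status %in% c(0, 1))
  if (length(badDS))
    stop("malformed sample table at line ", badDS[1] + 1,
         ": disease_status must be 0 or 1")
  tab$disease_status <- as.integer(tab$disease_status)
  if (ncol(tab) > 3) {
    for (j in 4:ncol(tab)) {
      suppressWarnings(num <- as.numeric(tab[[j]]))
      badCov <- which(is.na(num) & !is.na(tab[[j]]) & tab[[j]] != "NA")
      if (length(badCov))
        stop("malformed sample table at line ", badCov[1] + 1,
             ": non-numeric covariate in column ", names(tab)[j])
      tab[[j]] <- num
    }
  }
  tab
}

#' Write a cohort to a VCF and a sample table
#'
#' Emits a standards-conformant VCF 4.2 (GT-only FORMAT; mitochondrial
#' records on contig "MT" with haploid GT calls, missing calls as "./."
#' diploid and "." haploid) and the tab-delimited sample table.
#' \code{readCohort(writeCohort(x))} reproduces \code{x}.
#'
#' @param cohort a \code{\linkS4class{Cohort}}.
#' @param genotypePath output VCF path.
#' @param samplePath output sample-table path.
#' @return Invisibly, the genotype path.
#' @export
writeCohort <- function(cohort, genotypePath, samplePath) {
  v <- cohort@variants
  s <- cohort@samples
  contigs <- unique(v$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (length(contigs)) paste0("##contig=<ID=", contigs, ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", s$sample_id), collapse = "\t"))
  lines <- character(nrow(v))
  nNuc <- ncol(cohort@nuclear)
  for (i in seq_len(nrow(v))) {
    if (i <= nNuc) {
      d <- cohort@nuclear[, i]
      g <- c("0/0", "0/1", "1/1")[d + 1L]
      g[is.na(d)] <- "./."
    } else {
      d <- cohort@mito[, i - nNuc]
      g <- c("0", "1")[d + 1L]
      g[is.na(d)] <- "."
    }
    lines[i] <- paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i],
                        ".", ".", ".", "GT", g), collapse = "\t")
  }
  con <- tryCatch(file(genotypePath, "w"),
                  error = function(e) stop("cannot write VCF: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  utils::write.table(s, samplePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genotypePath)
}

#' Write association or combination results as a TSV
#'
#' One header line, one row per result in input order; floating-point
#' columns are written with 12 significant digits so p-values survive a
#' round trip to better than 1e-9 relative error.
#'
#' @param results a data.frame of results, e.g. from
#'   \code{\link{caseOnlyScan}} or \code{\link{combinationReport}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(results, path) {
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- sprintf("%.12g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
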