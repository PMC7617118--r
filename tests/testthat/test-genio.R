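fixtureVCF <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>", "##contig=<ID=MT>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"),
    "1\t100\trsA\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\trsB\tC\tT\t.\t.\t.\tGT\t0|1\t0/0\t0/1\t1/1",
    "2\t300\trsC\tG\tA\t.\t.\t.\tGT\t1/1\t0/1\t0/0\t0/0",
    "MT\t2706\tmtX\tT\tC\t.\t.\t.\tGT\t0\t1\t.\t0/1"), path)
}

fixtureSamples <- function(path, ids = paste0("S", 1:4)) {
  writeLines(c("sample_id\tcohort\tdisease_status\tpc1",
               paste(ids, c("case", "case", "control", "control"),
                     c(1, 1, 0, 0), c(0.1, -0.2, 0.3, 0), sep = "\t")),
             path)
}

test_that("readCohort parses a hand-counted fixture, haploid MT included", {
  v <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".tsv")
  fixtureVCF(v); fixtureSamples(s)
  ch <- readCohort(v, s)
  expect_identical(dim(nuclearGeno(ch)), c(4L, 3L))
  expect_identical(dim(mitoGeno(ch)), c(4L, 1L))
  expect_identical(unname(nuclearGeno(ch)[, "rsA"]), c(0L, 1L, 2L, NA))
  expect_identical(unname(nuclearGeno(ch)[, "rsB"]), c(1L, 0L, 1L, 2L))
  # MT record renamed by position; het mito call is unrepresentable -> NA
  expect_identical(colnames(mitoGeno(ch)), "mt.2706")
  expect_identical(unname(mitoGeno(ch)[, 1]), c(0L, 1L, NA, NA))
  vi <- variantInfo(ch)
  expect_identical(vi$chrom, c("1", "1", "2", "MT"))
  # MAF recomputed from genotypes, not trusted from input
  expect_equal(vi$maf[1], 0.5)  # dosages 0,1,2 over 3 non-missing
  expect_equal(vi$maf[4], 0.5)  # haploid 0,1
  expect_identical(sampleInfo(ch)$pc1, c(0.1, -0.2, 0.3, 0))
})

test_that("disjoint sample IDs are fatal and multiallelic records skipped", {
  v <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".tsv")
  fixtureVCF(v)
  fixtureSamples(s, ids = paste0("Z", 1:4))
  expect_error(readCohort(v, s), "no overlapping sample IDs")

  lines <- readLines(v)
  lines[7] <- "1\t200\trsB\tC\tT,G\t.\t.\t.\tGT\t0/1\t0/0\t0/1\t1/1"
  writeLines(lines, v)
  fixtureSamples(s)
  expect_warning(ch <- readCohort(v, s), "non-biallelic")
  expect_identical(ncol(nuclearGeno(ch)), 2L)
})

test_that("malformed sample tables fail naming the offending line", {
  v <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".tsv")
  fixtureVCF(v)
  writeLines(c("sample_id\tcohort\tdisease_status",
               "S1\tcase\t1", "S2\tcase\t7"), s)
  expect_error(readCohort(v, s), "line 3")
  writeLines(c("sample_id\tcohort\tdisease_status\tpc1",
               "S1\tcase\t1\t0.5", "S2\tcase\t1\tnot_a_number"), s)
  expect_error(readCohort(v, s), "line 3")
})

test_that("write/read round trip is the identity on a cohort with missing calls", {
  ch <- simulateCohort(simConfig(nCases = 40, nControls = 40, nNuclear = 6,
                                 nMt = 3, b0 = 0, seed = 3))
  nuc <- nuclearGeno(ch); mit <- mitoGeno(ch)
  nuc[1, 2] <- NA; mit[2, 1] <- NA
  ch <- Cohort(nuc, mit, variantInfo(ch), sampleInfo(ch))
  v <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(ch, v, s)
  txt <- readLines(v)
  expect_true(any(grepl("\\./\\.", txt)))           # missing diploid call
  mtLine <- grep("^MT", txt, value = TRUE)[1]
  expect_true(grepl("\t\\.($|\t)", mtLine))          # missing haploid call
  ch2 <- readCohort(v, s)
  expect_identical(nuclearGeno(ch2), nuclearGeno(ch))
  expect_identical(mitoGeno(ch2), mitoGeno(ch))
  expect_equal(variantInfo(ch2), variantInfo(ch))
  expect_equal(sampleInfo(ch2), sampleInfo(ch))
  # line count: header lines + one data line per variant
  expect_identical(sum(!startsWith(txt, "#")), nrow(variantInfo(ch)))
})

test_that("an empty cohort writes a valid header-only VCF", {
  ch <- toyCohort(matrix(integer(0), 2, 0), matrix(integer(0), 2, 0),
                  dis = c(0, 1))
  v <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(ch, v, s)
  txt <- readLines(v)
  expect_true(all(startsWith(txt, "#")))
  expect_identical(txt[1], "##fileformat=VCFv4.2")
})

test_that("writeResults emits header plus rows and round-trips p-values", {
  res <- data.frame(mtsnp_id = paste0("mt.", 1:5), nsnp_id = paste0("rs", 1:5),
                    p = c(1.234567891e-9, 0.5, 3.14159e-2, 1e-300, 0.9999),
                    or = exp(rnorm(5)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResults(res, f)
  expect_identical(length(readLines(f)), 6L)
  back <- read.delim(f)
  expect_equal(back$p, res$p, tolerance = 1e-9)
  expect_equal(back$or, res$or, tolerance = 1e-9)
  writeResults(res[0, ], f)
  expect_identical(length(readLines(f)), 1L)
})
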