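#' Haploid minor allele frequency
#'
#' @param calls haploid 0/1 vector, possibly with NA.
#' @return \code{min(f, 1 - f)} where f is the mean of non-missing calls.
#' @examples
#' haploidMAF(c(0, 1, 1, 1, 1, NA))  # 0.2
#' @export
haploidMAF <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop("all calls missing")
  f <- mean(calls[ok])
  min(f, 1 - f)
}

#' Pairwise haploid linkage disequilibrium (R-squared)
#'
#' Squared Pearson correlation of two haploid 0/1 call vectors over their
#' jointly non-missing entries — the standard composite measure of LD
#' between mitochondrial variants, which share a non-recombining molecule.
#'
#' @param x,y haploid 0/1 vectors of equal length.
#' @return R-squared in [0, 1]; NA (with a warning) when either vector is
#'   monomorphic on the joint support.
#' @examples
#' haploidR2(c(0, 0, 1, 1, 0, 1), c(0, 1, 1, 1, 0, 1))  # 0.5
#' @export
haploidR2 <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("need at least 2 jointly non-missing pairs")
  xs <- x[ok]; ys <- y[ok]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    warning("R-squared undefined: variant monomorphic on joint support")
    return(NA_real_)
  }
  stats::cor(xs, ys)^2
}

#' Select analysis-ready mtSNPs by MAF filtering and R-squared pruning
#'
#' Reduces a set of mitochondrial variants to the subset worth scanning:
#' variants below the frequency floor are dropped, then variants whose
#' pairwise haploid R-squared exceeds the threshold are clustered
#' (connected components of the R-squared > threshold graph) and each
#' cluster is represented by its highest-MAF member, ties broken by
#' smallest position. This mirrors the standard collapse of a trio of
#' mutually near-perfectly linked mtSNPs to a single representative.
#'
#' @param mito samples x mtSNPs haploid genotype matrix.
#' @param variants data.frame with at least \code{id} and \code{pos} rows
#'   matching the matrix columns.
#' @param mafMin minimum minor allele frequency to keep (default 0.2).
#' @param r2High R-squared above which two variants are considered
#'   redundant (strict inequality; default 0.9).
#' @return A list of class \code{MtSelection}: \code{retained} (ids kept),
#'   \code{clusters} (named list mapping each retained id to the ids it
#'   represents), \code{mafTable} (named MAF vector over all input
#'   variants) and \code{r2Matrix} (pairwise R-squared among MAF-passing
#'   variants).
#' @export
pruneMtSNPs <- function(mito, variants, mafMin = 0.2, r2High = 0.9) {
  ids <- variants$id
  if (!length(ids)) stop("need at least one mtSNP")
  maf <- vapply(seq_along(ids), function(j) haploidMAF(mito[, j]),
                numeric(1))
  names(maf) <- ids
  pass <- which(maf >= mafMin)
  m <- length(pass)
  r2 <- matrix(NA_real_, m, m, dimnames = list(ids[pass], ids[pass]))
  if (m) diag(r2) <- 1
  if (m > 1) {
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        val <- suppressWarnings(haploidR2(mito[, pass[a]], mito[, pass[b]]))
        r2[a, b] <- r2[b, a] <- val
      }
    }
  }
  adj <- !is.na(r2) & r2 > r2High
  comp <- .connectedComponents(adj)
  clusters <- list()
  for (cid in unique(comp)) {
    members <- pass[comp == cid]
    best <- members[order(-maf[members], variants$pos[members])][1]
    clusters[[ids[best]]] <- ids[members]
  }
  ord <- order(match(names(clusters), ids))
  clusters <- clusters[ord]
  structure(list(retained = names(clusters), clusters = clusters,
                 mafTable = maf, r2Matrix = r2),
            class = "MtSelection")
}

# BFS connected components of a logical adjacency matrix (diag ignored)
.connectedComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L & seq_len(n) != v)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.MtSelection <- function(x, ...) {
  cat("MtSelection:", length(x$retained), "retained of",
      length(x$mafTable), "mtSNPs\n")
  for (id in x$retained) {
    reps <- setdiff(x$clusters[[id]], id)
    cat(sprintf("  %s (MAF %.3f)%s\n", id, x$mafTable[id],
                if (length(reps)) paste0(" representing ",
                                         paste(reps, collapse = ", "))
                else ""))
  }
  invisible(x)
}
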