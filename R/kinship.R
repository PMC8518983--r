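#' Marker quality control
#'
#' Drops markers whose missing-call fraction exceeds \code{max_missing}
#' (strict) or whose minor allele frequency is below \code{min_maf}
#' (strict), in that order of accounting. The operation is idempotent.
#'
#' @param geno a \linkS4class{GenotypeData}
#' @param max_missing maximum tolerated missing fraction (default 0.5)
#' @param min_maf minimum tolerated minor allele frequency (default 0.05)
#' @return the filtered \linkS4class{GenotypeData}; drop counts are stored
#'   in \code{metadata(x)$filter} (n_missing_dropped, n_maf_dropped)
#' @export
filterMarkers <- function(geno, max_missing = 0.5, min_maf = 0.05) {
  stopifnot(is(geno, "GenotypeData"))
  d <- SummarizedExperiment::assay(geno, "dosage")
  miss <- rowMeans(is.na(d))
  maf <- .markerMaf(d)
  drop_miss <- miss > max_missing
  drop_maf <- !drop_miss & maf < min_maf
  keep <- !drop_miss & !drop_maf
  if (!any(keep)) stop("all markers removed by QC filters")
  out <- geno[keep, ]
  S4Vectors::metadata(out)$filter <- list(
    n_input = length(keep),
    n_missing_dropped = sum(drop_miss),
    n_maf_dropped = sum(drop_maf),
    n_kept = sum(keep),
    max_missing = max_missing, min_maf = min_maf
  )
  out
}

# mean-impute missing dosages per marker; markers x genotypes in, same out
.imputeDosage <- function(d) {
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx)) {
    mns <- rowMeans(d, na.rm = TRUE)
    d[na_idx] <- mns[na_idx[, 1L]]
  }
  d
}

#' Centered relatedness (kinship) matrix
#'
#' K = W W' / p, where W is the genotypes x markers dosage matrix with
#' missing calls mean-imputed per marker and each marker column centered on
#' its mean, and p is the number of markers. The mean of the diagonal of K
#' equals the mean per-marker dosage variance (an algebraic identity of this
#' estimator).
#'
#' @param geno a (QC-filtered) \linkS4class{GenotypeData}
#' @return symmetric positive semi-definite genotypes x genotypes matrix
#' @export
relatednessMatrix <- function(geno) {
  stopifnot(is(geno, "GenotypeData"))
  d <- SummarizedExperiment::assay(geno, "dosage")
  if (!nrow(d)) stop("no markers available for kinship")
  W <- t(.imputeDosage(d))              # genotypes x markers
  W <- sweep(W, 2L, colMeans(W))
  K <- tcrossprod(W) / ncol(W)
  (K + t(K)) / 2
}
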