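#' Accessors for GenotypeData
#'
#' \code{dosages} returns the additive dosage matrix in the conventional
#' genotypes x markers orientation; \code{markerMap} the marker coordinate
#' table; \code{mafs} the per-marker minor-allele frequencies computed on
#' non-missing calls (heterozygotes counted once).
#'
#' @param x a \linkS4class{GenotypeData} object
#' @return \code{dosages}: numeric matrix (genotypes x markers);
#'   \code{markerMap}: data.frame with marker_id, chromosome, position_bp;
#'   \code{mafs}: named numeric vector.
#' @name GenotypeData-accessors
#' @aliases dosages markerMap mafs
#' @examples
#' geno <- simulateGenotypes(SimulationConfig(n_genotypes = 5, n_markers = 4,
#'                                            seed = 7))
#' range(mafs(geno))
NULL

#' @rdname GenotypeData-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname GenotypeData-accessors
setMethod("dosages", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname GenotypeData-accessors
setMethod("markerMap", "GenotypeData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    marker_id = names(rr),
    chromosome = as.character(GenomicRanges::seqnames(rr)),
    position_bp = GenomicRanges::start(rr),
    stringsAsFactors = FALSE
  )
})

#' @rdname GenotypeData-accessors
setMethod("mafs", "GenotypeData", function(x) {
  setNames(SummarizedExperiment::rowData(x)$maf, rownames(x))
})
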