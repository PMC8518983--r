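#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowRanges rowData
#' @importFrom S4Vectors metadata
#' @importFrom stats coef lm pchisq pf pt pnorm qnorm optimize optim var sd
#'   cor median complete.cases p.adjust prcomp rnorm runif rbinom rbeta
#'   setNames aggregate quantile residuals anova as.formula predict qchisq
#' @importFrom utils read.csv write.csv read.delim head
NULL

#' Chamber configuration for CO2 flux measurements
#'
#' Physical constants and measurement-window settings of the closed chamber
#' in which root CO2 efflux is recorded. Defaults describe a 19 ml chamber at
#' 28 degrees C and standard pressure, with the first 20 s of each trace
#' discarded as an equilibration dead band and the regression window closing
#' at 90 s.
#'
#' @slot chamber_volume_ml chamber volume before root-volume correction (ml)
#' @slot pressure_kPa chamber air pressure (kPa)
#' @slot temperature_K chamber air temperature (K)
#' @slot gas_constant ideal gas constant (L kPa K-1 mol-1)
#' @slot dead_band_s initial seconds of each trace ignored before slope fitting
#' @slot window_end_s last second of the trace included in the slope fit
#'
#' @examples
#' ChamberConfig()
#' ChamberConfig(temperature_K = 298.15)
#' @export ChamberConfig
#' @exportClass ChamberConfig
ChamberConfig <- setClass(
  "ChamberConfig",
  representation(
    chamber_volume_ml = "numeric",
    pressure_kPa = "numeric",
    temperature_K = "numeric",
    gas_constant = "numeric",
    dead_band_s = "numeric",
    window_end_s = "numeric"
  ),
  prototype(
    chamber_volume_ml = 19,
    pressure_kPa = 101.325,
    temperature_K = 301.15,
    gas_constant = 8.31446,
    dead_band_s = 20,
    window_end_s = 90
  )
)

setValidity("ChamberConfig", function(object) {
  msgs <- character()
  for (s in c("chamber_volume_ml", "pressure_kPa", "temperature_K",
              "gas_constant")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive number", s))
  }
  if (object@dead_band_s >= object@window_end_s)
    msgs <- c(msgs, "'dead_band_s' must be smaller than 'window_end_s'")
  if (length(msgs)) msgs else TRUE
})

#' CO2 accumulation trace for one root sample
#'
#' A timestamped series of water-corrected CO2 molar fractions recorded while
#' a root system respires inside a closed chamber. The sample identity is the
#' barcode the file was saved under.
#'
#' @slot sample_id barcode string identifying the sample
#' @slot time_s observation times in seconds, strictly increasing
#' @slot co2_umol_mol water-corrected CO2 molar fraction (umol mol-1)
#' @slot h2o_mmol_mol optional water vapour trace (mmol mol-1); may be empty
#'
#' @examples
#' GasTrace("S001", time_s = 0:90, co2_umol_mol = 400 + 0.5 * (0:90))
#' @aliases GasTrace-class
#' @exportClass GasTrace
setClass(
  "GasTrace",
  representation(
    sample_id = "character",
    time_s = "numeric",
    co2_umol_mol = "numeric",
    h2o_mmol_mol = "numeric"
  ),
  prototype(h2o_mmol_mol = numeric())
)

#' @rdname GasTrace-class
#' @param sample_id,time_s,co2_umol_mol,h2o_mmol_mol see slot descriptions
#' @export
GasTrace <- function(sample_id, time_s, co2_umol_mol,
                     h2o_mmol_mol = numeric()) {
  new("GasTrace", sample_id = as.character(sample_id),
      time_s = as.numeric(time_s),
      co2_umol_mol = as.numeric(co2_umol_mol),
      h2o_mmol_mol = as.numeric(h2o_mmol_mol))
}

setValidity("GasTrace", function(object) {
  msgs <- character()
  if (length(object@sample_id) != 1L || is.na(object@sample_id))
    msgs <- c(msgs, "'sample_id' must be a single string")
  n <- length(object@time_s)
  if (n < 2L)
    msgs <- c(msgs, "a trace needs at least 2 readings")
  if (length(object@co2_umol_mol) != n)
    msgs <- c(msgs, "'time_s' and 'co2_umol_mol' lengths differ")
  if (n >= 2L && any(diff(object@time_s) <= 0))
    msgs <- c(msgs, "'time_s' must be strictly increasing")
  if (!all(is.finite(object@co2_umol_mol)) || any(object@co2_umol_mol <= 0))
    msgs <- c(msgs, "CO2 readings must be finite and positive")
  if (length(object@h2o_mmol_mol) && length(object@h2o_mmol_mol) != n)
    msgs <- c(msgs, "'h2o_mmol_mol' must be empty or match 'time_s' length")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GasTrace", function(object) {
  cat("GasTrace for sample", object@sample_id, "\n")
  cat("  ", length(object@time_s), " readings over t = [",
      min(object@time_s), ", ", max(object@time_s), "] s\n", sep = "")
  cat("  CO2 range: ", round(min(object@co2_umol_mol), 2), "-",
      round(max(object@co2_umol_mol), 2), " umol mol-1\n", sep = "")
})

setMethod("show", "ChamberConfig", function(object) {
  cat("ChamberConfig:",
      object@chamber_volume_ml, "ml,",
      object@pressure_kPa, "kPa,",
      object@temperature_K, "K;",
      "window [", object@dead_band_s, ",", object@window_end_s, "] s\n")
})

#' Dosage matrix with marker map and kinship
#'
#' Container for a diploid biallelic genotype panel: an additive minor-allele
#' dosage assay (markers in rows, genotypes in columns, values 0/1/2 or NA)
#' with marker coordinates as \code{rowRanges}. Built on
#' \linkS4class{RangedSummarizedExperiment} so the usual Bioconductor
#' accessors apply; \code{\link{dosages}}, \code{\link{markerMap}} and
#' \code{\link{mafs}} give the conventional views.
#'
#' @examples
#' geno <- simulateGenotypes(SimulationConfig(n_genotypes = 4, n_markers = 6,
#'                                            seed = 1))
#' dim(dosages(geno))
#' head(markerMap(geno))
#' @export
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  vals <- d[!is.na(d)]
  if (length(vals) && (any(vals < 0) || any(vals > 2)))
    msgs <- c(msgs, "dosages must lie in [0, 2] or be NA")
  rr <- SummarizedExperiment::rowRanges(object)
  if (any(GenomicRanges::start(rr) < 0))
    msgs <- c(msgs, "marker positions must be non-negative")
  pos <- split(GenomicRanges::start(rr),
               as.character(GenomicRanges::seqnames(rr)))
  if (any(vapply(pos, is.unsorted, logical(1))))
    msgs <- c(msgs, "marker positions must be sorted within chromosome")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of minor-allele dosages, genotypes x markers
#'   (the conventional GWAS orientation; it is stored transposed, markers x
#'   genotypes, following the assay convention). Entries 0/1/2 or NA.
#' @param map data.frame with columns \code{marker_id}, \code{chromosome},
#'   \code{position_bp}; one row per marker, same order as \code{dosage}
#'   columns.
#' @return a \linkS4class{GenotypeData} object
#' @export
makeGenotypeData <- function(dosage, map) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(map),
            all(c("marker_id", "chromosome", "position_bp") %in% names(map)))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("G%04d", seq_len(nrow(dosage)))
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(map$chromosome),
    ranges = IRanges::IRanges(start = map$position_bp, width = 1L),
    marker_id = as.character(map$marker_id)
  )
  names(rr) <- map$marker_id
  ord <- order(as.character(map$chromosome), map$position_bp)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)[ord, , drop = FALSE]),
    rowRanges = rr[ord]
  )
  obj <- methods::new("GenotypeData", se)
  SummarizedExperiment::rowData(obj)$maf <- .markerMaf(
    SummarizedExperiment::assay(obj, "dosage"))
  obj
}

# per-marker minor-allele frequency on non-missing calls (markers in rows)
.markerMaf <- function(d) {
  p <- rowMeans(d, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "genotypes x", nrow(object),
      "markers on", length(unique(as.character(
        GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object))))),
      "chromosomes\n")
  m <- SummarizedExperiment::rowData(object)$maf
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  MAF: %.3f-%.3f; missing: %.1f%%\n",
              min(m), max(m), 100 * mean(is.na(d))))
})
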