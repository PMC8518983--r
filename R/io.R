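# --- file formats ---------------------------------------------------------
# Genotypes: TSV with columns marker_id, chrom, pos, then one dosage column
# per genotype; missing calls are the literal string "NA". Features/masses/
# sample metadata: CSV. Annotation: TSV with gene_id, chromosome, start,
# end (1-based inclusive).

#' Read a genotype matrix from TSV
#'
#' @param path TSV file: marker_id, chrom, pos, then one dosage column per
#'   genotype ("NA" = missing call)
#' @return a \linkS4class{GenotypeData}
#' @export
readGenotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(d)))
  gcols <- setdiff(names(d), c("marker_id", "chrom", "pos"))
  if (!length(gcols)) stop("no genotype columns in ", path)
  dosage <- t(as.matrix(d[gcols]))          # genotypes x markers
  colnames(dosage) <- d$marker_id
  makeGenotypeData(dosage, data.frame(
    marker_id = d$marker_id, chromosome = d$chrom, position_bp = d$pos,
    stringsAsFactors = FALSE))
}

#' Write a genotype matrix to TSV
#'
#' @param geno a \linkS4class{GenotypeData}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeGenotypes <- function(geno, path) {
  map <- markerMap(geno)
  d <- SummarizedExperiment::assay(geno, "dosage")
  out <- data.frame(marker_id = map$marker_id, chrom = map$chromosome,
                    pos = map$position_bp, d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write one gas trace to a plain-text file
#'
#' The file is named after the trace's barcode: \code{<sample_id>.txt},
#' with a comment header and whitespace-delimited time/CO2 columns.
#'
#' @param trace a \linkS4class{GasTrace}
#' @param dir output directory
#' @return the file path, invisibly
#' @export
writeGasTrace <- function(trace, dir) {
  path <- file.path(dir, paste0(trace@sample_id, ".txt"))
  lines <- c("# time_s co2_umol_mol",
             sprintf("%g %.6f", trace@time_s, trace@co2_umol_mol))
  writeLines(lines, path)
  invisible(path)
}

#' Read the per-sample feature, mass, sample-metadata or annotation tables
#'
#' Thin CSV/TSV readers that validate the required columns.
#'
#' @param path input file
#' @return data.frame
#' @name table-readers
NULL

#' @rdname table-readers
#' @export
readFeatureTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tips", "branch_points", "total_root_length_mm",
            "axial_root_length_mm", "lateral_root_length_mm",
            "total_root_volume_mm3", "axial_root_volume_mm3",
            "lateral_root_volume_mm3")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("feature table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname table-readers
#' @export
readMassTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "shoot_dry_weight_g", "root_dry_weight_g"),
                  names(d))
  if (length(miss))
    stop("mass table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname table-readers
#' @export
readSampleInfo <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "genotype_id", "block_id"), names(d))
  if (length(miss))
    stop("sample table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname table-readers
#' @export
readAnnotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "chromosome", "start", "end"), names(d))
  if (length(miss))
    stop("annotation table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  d
}

#' Reference trait summary for a winter wheat diversity panel
#'
#' Genotype-mean summary statistics (mean, min, max, broad-sense
#' heritability) for the 26 traits of a 276-line winter wheat seedling
#' panel, shipped with the package. Used for unit-sanity checks and for
#' reconstructing fold-variation statements from printed summaries.
#'
#' @return data.frame with trait, abbreviation, unit, mean, min, max, h2
#' @export
referenceTraitSummary <- function() {
  read.csv(system.file("extdata", "wheat_trait_summary.csv",
                       package = "rootEconomics"),
           stringsAsFactors = FALSE)
}
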