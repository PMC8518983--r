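#' Names of the root economics traits
#'
#' The trait panel: shoot/root/total dry weight, total root respiration and
#' its mass-, length- and (later) architecture-normalized forms, specific
#' root length, mass fraction, the axial/lateral length, volume and surface
#' area decomposition at the 0.3 mm diameter threshold, branching counts and
#' densities, mean diameter and tissue density. SRR_R is appended by
#' \code{\link{residualTrait}} after the respiration partition is fitted.
#'
#' @param with_srr_r include the partition-residual trait SRR_R
#' @return character vector of trait column names
#' @export
traitNames <- function(with_srr_r = FALSE) {
  base <- c("SDW", "TDW", "RDW", "TRR", "SRR_L", "SRR_M", "SRL", "RMF",
            "TRL", "ARL", "LRL", "L_A_L", "TRV", "ARV", "LRV", "L_A_V",
            "TSA", "ASA", "LSA", "AvgD", "Tip", "BP", "BF", "BD", "RTD")
  if (with_srr_r) append(base, "SRR_R", after = 6L) else base
}

#' Derive the trait table from features, masses and fluxes
#'
#' Joins the per-sample root-architecture feature record, dry masses and
#' respiration flux by barcode and computes the derived economics traits:
#' \itemize{
#'   \item TDW = SDW + RDW (g); RMF = 100 RDW / TDW (percent)
#'   \item SRR_M = TRR / RDW (nmol g-1 s-1); SRR_L = TRR / (TRL/1000)
#'     (nmol m-1 s-1)
#'   \item SRL = (TRL/1000) / RDW (m g-1); RTD = RDW / (TRV/1000) (g cm-3)
#'   \item BF = BP / TRL (n mm-1); BD = Tip / (ARL/10) (n cm-1)
#'   \item L_A_L = LRL / ARL; L_A_V = LRV / ARV
#' }
#' Samples with a zero denominator (RDW, TRL, ARL, ARV, TRV, TDW) are
#' rejected with a reason rather than producing infinities.
#'
#' @param features data.frame of RootFeatureRecord columns (as produced by
#'   \code{\link{simulateRootSystems}} or read from the image-analysis CSV)
#' @param masses data.frame with sample_id, shoot_dry_weight_g,
#'   root_dry_weight_g
#' @param flux data.frame with sample_id, flux_nmol_s (from
#'   \code{\link{batchFlux}})
#' @param sample_info optional data.frame with sample_id, genotype_id,
#'   block_id carried through to the output
#' @return list with \code{traits} (plant-level trait table) and
#'   \code{rejects} (sample_id, reason)
#' @export
deriveTraits <- function(features, masses, flux, sample_info = NULL) {
  stopifnot(all(c("sample_id", "tips", "branch_points") %in% names(features)),
            all(c("sample_id", "shoot_dry_weight_g", "root_dry_weight_g")
                %in% names(masses)),
            all(c("sample_id", "flux_nmol_s") %in% names(flux)))
  d <- merge(merge(features, masses, by = "sample_id"),
             flux[, c("sample_id", "flux_nmol_s")], by = "sample_id")
  rejects <- data.frame(sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  bad_mass <- d$root_dry_weight_g <= 0 | d$shoot_dry_weight_g <= 0
  bad_len <- d$total_root_length_mm <= 0 | d$axial_root_length_mm <= 0
  bad_vol <- d$total_root_volume_mm3 <= 0 | d$axial_root_volume_mm3 <= 0
  bad <- bad_mass | bad_len | bad_vol
  if (any(bad)) {
    reason <- ifelse(bad_mass, "non-positive dry mass",
                     ifelse(bad_len, "non-positive root length",
                            "non-positive root volume"))
    rejects <- data.frame(sample_id = d$sample_id[bad],
                          reason = reason[bad], stringsAsFactors = FALSE)
    d <- d[!bad, , drop = FALSE]
  }
  tdw <- d$shoot_dry_weight_g + d$root_dry_weight_g
  out <- data.frame(
    sample_id = d$sample_id,
    SDW = d$shoot_dry_weight_g,
    TDW = tdw,
    RDW = d$root_dry_weight_g,
    TRR = d$flux_nmol_s,
    SRR_L = d$flux_nmol_s / (d$total_root_length_mm / 1000),
    SRR_M = d$flux_nmol_s / d$root_dry_weight_g,
    SRL = (d$total_root_length_mm / 1000) / d$root_dry_weight_g,
    RMF = 100 * d$root_dry_weight_g / tdw,
    TRL = d$total_root_length_mm,
    ARL = d$axial_root_length_mm,
    LRL = d$lateral_root_length_mm,
    L_A_L = d$lateral_root_length_mm / d$axial_root_length_mm,
    TRV = d$total_root_volume_mm3,
    ARV = d$axial_root_volume_mm3,
    LRV = d$lateral_root_volume_mm3,
    L_A_V = d$lateral_root_volume_mm3 / d$axial_root_volume_mm3,
    TSA = d$total_surface_area_mm2,
    ASA = d$axial_surface_area_mm2,
    LSA = d$lateral_surface_area_mm2,
    AvgD = d$avg_diameter_mm,
    Tip = d$tips,
    BP = d$branch_points,
    BF = d$branch_points / d$total_root_length_mm,
    BD = d$tips / (d$axial_root_length_mm / 10),
    RTD = d$root_dry_weight_g / (d$total_root_volume_mm3 / 1000),
    stringsAsFactors = FALSE
  )
  if (!is.null(sample_info))
    out <- merge(sample_info, out, by = "sample_id", sort = FALSE)
  list(traits = out, rejects = rejects)
}

#' Genotype means of a plant-level trait table
#'
#' Arithmetic mean of each trait per genotype, ignoring missing values; the
#' number of contributing replicates is retained as \code{n_reps}.
#'
#' @param traits plant-level trait table containing \code{genotype_id}
#' @param trait_cols trait columns to average (default: all numeric columns
#'   other than identifiers)
#' @return genotype-level trait table, one row per genotype
#' @export
genotypeMeans <- function(traits, trait_cols = NULL) {
  stopifnot("genotype_id" %in% names(traits))
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))],
                          c("block_id", "n_reps"))
  sp <- split(traits[trait_cols], traits$genotype_id)
  means <- do.call(rbind, lapply(sp, function(g)
    colMeans(as.matrix(g), na.rm = TRUE)))
  out <- data.frame(genotype_id = names(sp),
                    n_reps = vapply(sp, nrow, integer(1)),
                    means, stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$genotype_id), , drop = FALSE]
}

#' Per-trait summary with fold variation
#'
#' Mean, minimum, maximum and fold variation (max/min, reported to one
#' decimal) per trait over genotype means. A trait whose minimum is zero or
#' negative gets an undefined (NA) fold variation.
#'
#' @param traits genotype-level trait table
#' @param trait_cols trait columns to summarize
#' @return data.frame with trait, mean, min, max, fold_variation
#' @export
summarizeTraits <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))],
                          c("block_id", "n_reps"))
  stopifnot(nrow(traits) >= 2)
  rows <- lapply(trait_cols, function(tc) {
    v <- traits[[tc]]
    v <- v[is.finite(v)]
    fold <- if (min(v) > 0) round(max(v) / min(v), 1) else NA_real_
    data.frame(trait = tc, mean = mean(v), min = min(v), max = max(v),
               fold_variation = fold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
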