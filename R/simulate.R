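#' Configuration for the synthetic genotype panel
#'
#' Describes the simulated diversity panel: a randomized complete block
#' design (default 276 genotypes x 4 blocks, i.e. 1104 plants) genotyped on
#' a diploid biallelic array with a uniform MAF spectrum, i.i.d. missingness
#' and optionally two subpopulations (Balding-Nichols divergence).
#'
#' @slot n_genotypes number of genotypes in the panel
#' @slot n_blocks number of complete blocks (replicates per genotype)
#' @slot n_markers number of array markers
#' @slot n_chromosomes chromosomes markers are spread over
#' @slot maf_range lower/upper bound of per-marker allele frequencies, in
#'   (0, 0.5]
#' @slot missing_rate i.i.d. missing-call probability, in [0, 1)
#' @slot fst Balding-Nichols divergence between the two subpopulations;
#'   0 disables structure
#' @slot seed RNG seed; identical config + seed gives bit-identical output
#' @export SimulationConfig
#' @exportClass SimulationConfig
SimulationConfig <- setClass(
  "SimulationConfig",
  representation(
    n_genotypes = "integer", n_blocks = "integer", n_markers = "integer",
    n_chromosomes = "integer", maf_range = "numeric",
    missing_rate = "numeric", fst = "numeric", seed = "integer"
  ),
  prototype(
    n_genotypes = 276L, n_blocks = 4L, n_markers = 1000L,
    n_chromosomes = 21L, maf_range = c(0.05, 0.5), missing_rate = 0.02,
    fst = 0, seed = 1L
  )
)

setMethod("initialize", "SimulationConfig", function(.Object, ...) {
  args <- list(...)
  for (f in c("n_genotypes", "n_blocks", "n_markers", "n_chromosomes",
              "seed"))
    if (!is.null(args[[f]])) args[[f]] <- as.integer(args[[f]])
  do.call(callNextMethod, c(list(.Object), args))
})

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  for (f in c("n_genotypes", "n_blocks", "n_markers", "n_chromosomes"))
    if (slot(object, f) < 1L) msgs <- c(msgs, paste0("'", f, "' must be >= 1"))
  mr <- object@maf_range
  if (length(mr) != 2L || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    msgs <- c(msgs, "'maf_range' must be increasing within (0, 0.5]")
  if (object@missing_rate < 0 || object@missing_rate >= 1)
    msgs <- c(msgs, "'missing_rate' must be in [0, 1)")
  if (object@fst < 0 || object@fst >= 1)
    msgs <- c(msgs, "'fst' must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_genotypes, "genotypes x",
      object@n_blocks, "blocks;", object@n_markers, "markers on",
      object@n_chromosomes, "chromosomes; MAF in [",
      object@maf_range[1], ",", object@maf_range[2], "]; missing",
      object@missing_rate, "; Fst", object@fst, "; seed", object@seed, "\n")
})

#' Simulate an array-genotyped diversity panel
#'
#' Draws one allele frequency per marker uniformly from the configured MAF
#' range, samples diploid dosages under Hardy-Weinberg equilibrium, applies
#' i.i.d. missingness, and assigns markers to chromosomes in contiguous
#' blocks with ascending positions. When \code{fst > 0} the panel is split
#' into two equal subpopulations whose marker frequencies diverge under the
#' Balding-Nichols model, so that kinship correction in downstream scans has
#' structure to absorb.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{GenotypeData}; the subpopulation assignment (if
#'   any) is stored in \code{metadata(x)$population}
#' @export
simulateGenotypes <- function(config = SimulationConfig()) {
  validObject(config)
  set.seed(config@seed)
  ng <- config@n_genotypes; nm <- config@n_markers
  p_anc <- runif(nm, config@maf_range[1], config@maf_range[2])
  pop <- rep_len(1:2, ng)
  if (config@fst > 0) {
    a <- (1 - config@fst) / config@fst
    p1 <- rbeta(nm, p_anc * a, (1 - p_anc) * a)
    p2 <- rbeta(nm, p_anc * a, (1 - p_anc) * a)
    # keep markers polymorphic after divergence
    p1 <- pmin(pmax(p1, 0.01), 0.99)
    p2 <- pmin(pmax(p2, 0.01), 0.99)
    pmat <- rbind(p1, p2)[pop, , drop = FALSE]
    dosage <- matrix(rbinom(ng * nm, 2L, pmat), nrow = ng)
  } else {
    dosage <- matrix(rbinom(ng * nm, 2L, rep(p_anc, each = ng)), nrow = ng)
  }
  if (config@missing_rate > 0)
    dosage[runif(ng * nm) < config@missing_rate] <- NA_integer_
  storage.mode(dosage) <- "numeric"
  rownames(dosage) <- sprintf("G%04d", seq_len(ng))
  chrom <- sort(rep_len(seq_len(config@n_chromosomes), nm))
  pos <- unlist(lapply(split(seq_len(nm), chrom), function(ix)
    sort(sample.int(5e8, length(ix)))), use.names = FALSE)
  map <- data.frame(
    marker_id = sprintf("M%05d", seq_len(nm)),
    chromosome = sprintf("chr%02d", chrom),
    position_bp = pos, stringsAsFactors = FALSE
  )
  colnames(dosage) <- map$marker_id
  geno <- makeGenotypeData(dosage, map)
  S4Vectors::metadata(geno)$population <- pop
  S4Vectors::metadata(geno)$true_frequency <- p_anc
  geno
}

#' Simulate replicated traits over a randomized complete block design
#'
#' Generates plant-level observations y_ij = mu + b_j + g_i + sum(x_i beta) +
#' e_ij for each genotype i and block j: genotype effects are multivariate
#' normal across traits with covariance sigma_g2 * genetic_corr, block
#' effects are fixed, marker (QTL) effects are additive in the dosage, and
#' residuals are i.i.d. per plant and trait. The returned truth record holds
#' everything needed to score downstream recovery (true genetic values,
#' variance components, the implied broad-sense heritability).
#'
#' @param genotypes a \linkS4class{GenotypeData}
#' @param sigma_g2 genotypic variance (per trait)
#' @param sigma_e2 residual (plant-level) variance
#' @param block_effects numeric vector of fixed block effects, one per block
#' @param qtl list of planted marker effects, each a list with elements
#'   \code{marker} (marker id), \code{effect} (per-dosage-unit effect) and
#'   optionally \code{trait} (index, default 1)
#' @param n_traits number of traits to simulate
#' @param genetic_corr genetic correlation matrix among traits (positive
#'   semi-definite); default identity
#' @param mu grand mean
#' @param seed RNG seed
#' @return list with \code{plants} (genotype_id, block_id, trait columns) and
#'   \code{truth} (genetic values, components, qtl, true H2)
#' @export
simulateTraits <- function(genotypes, sigma_g2 = 1, sigma_e2 = 3,
                           block_effects = NULL, qtl = list(),
                           n_traits = 1, genetic_corr = NULL, mu = 0,
                           seed = 1) {
  ng <- nrow(dosages(genotypes))
  if (is.null(genetic_corr)) genetic_corr <- diag(n_traits)
  stopifnot(nrow(genetic_corr) == n_traits, ncol(genetic_corr) == n_traits)
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'genetic_corr' is not positive semi-definite")
  if (is.null(block_effects)) block_effects <- numeric(4)
  r <- length(block_effects)
  set.seed(seed)
  # genetic values: ng x n_traits, covariance sigma_g2 * genetic_corr
  L <- chol(genetic_corr + diag(1e-10, n_traits))
  g <- matrix(rnorm(ng * n_traits, sd = sqrt(sigma_g2)), ng) %*% L
  W <- dosages(genotypes)
  qtl_part <- matrix(0, ng, n_traits)
  for (q in qtl) {
    tr <- if (is.null(q$trait)) 1L else q$trait
    x <- W[, q$marker]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    qtl_part[, tr] <- qtl_part[, tr] + x * q$effect
  }
  gv <- g + qtl_part
  plants <- expand.grid(block_id = seq_len(r), genotype_row = seq_len(ng))
  y <- mu + block_effects[plants$block_id] + gv[plants$genotype_row, ,
                                               drop = FALSE] +
    matrix(rnorm(nrow(plants) * n_traits, sd = sqrt(sigma_e2)), nrow(plants))
  colnames(y) <- sprintf("trait_%02d", seq_len(n_traits))
  out <- data.frame(
    genotype_id = rownames(W)[plants$genotype_row],
    block_id = plants$block_id, y, stringsAsFactors = FALSE
  )
  list(
    plants = out,
    truth = list(
      genetic_values = gv, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
      block_effects = block_effects, qtl = qtl,
      h2_true = sigma_g2 / (sigma_g2 + sigma_e2 / r)
    )
  )
}

#' Simulate one chamber CO2 accumulation trace
#'
#' Inverts the ideal-gas flux relation to turn a true respiration rate into
#' a linear CO2 accumulation slope, superimposes an exponentially decaying
#' transient (the chamber-equilibration artifact that motivates the dead
#' band) and i.i.d. Gaussian instrument noise, and samples 91 readings at
#' 1 Hz over t = 0..90 s.
#'
#' @param true_flux true respiration of the sample (nmol CO2 s-1)
#' @param chamber a \linkS4class{ChamberConfig}
#' @param corrected_volume_ml effective chamber volume (chamber minus root
#'   volume); defaults to the nominal chamber volume
#' @param noise_sd instrument noise standard deviation (umol mol-1)
#' @param transient_amplitude amplitude of the initial transient (umol mol-1)
#' @param transient_halflife transient half-life (s); the default 4 s decays
#'   to ~3\% of its amplitude by the 20 s dead band
#' @param baseline_co2 CO2 concentration at t = 0 (umol mol-1)
#' @param sample_id barcode for the generated trace
#' @param seed RNG seed
#' @return a \linkS4class{GasTrace}
#' @export
simulateGasTrace <- function(true_flux, chamber = ChamberConfig(),
                             corrected_volume_ml = chamber@chamber_volume_ml,
                             noise_sd = 0, transient_amplitude = 0,
                             transient_halflife = 4, baseline_co2 = 400,
                             sample_id = "SIM0001", seed = 1) {
  stopifnot(true_flux >= 0, corrected_volume_ml > 0)
  set.seed(seed)
  tm <- seq(0, chamber@window_end_s, by = 1)
  mol_air <- chamber@pressure_kPa * (corrected_volume_ml / 1000) /
    (chamber@gas_constant * chamber@temperature_K)
  slope <- true_flux / (mol_air * 1e3)  # nmol/s -> umol mol-1 s-1
  co2 <- baseline_co2 + slope * tm +
    transient_amplitude * exp(-log(2) * tm / transient_halflife) +
    rnorm(length(tm), sd = noise_sd)
  GasTrace(sample_id = sample_id, time_s = tm, co2_umol_mol = co2)
}

#' Simulate root systems with a known respiration partition
#'
#' Generates per-sample root-architecture feature records (tip counts,
#' axial/lateral lengths, volumes and surface areas with allometric noise
#' around realistic seedling values) and a true total respiration that is a
#' volume-weighted sum over the three tissue classes: axial root volume,
#' lateral-root axis volume (lateral volume minus tip volume) and
#' lateral-root tip volume, using the same tip-volume convention as
#' \code{\link{partitionVolumes}}.
#'
#' @param n number of root systems
#' @param srr_axial,srr_lateral_axis,srr_tip specific respiration rates per
#'   tissue class (nmol s-1 mm-3), all >= 0
#' @param size_factor per-sample multiplicative size factor (length 1 or n);
#'   lets callers impose genotype/block structure on architecture
#' @param allometric_sd log-scale standard deviation of the within-sample
#'   feature noise
#' @param respiration_noise_sd additive noise on observed respiration
#'   (nmol s-1)
#' @param respiration_offset per-sample additive metabolic offset
#'   (nmol s-1), length 1 or n; respiration below zero is truncated at zero
#' @param seminal_count,tip_unit_volume_mm3 tip-volume convention (see
#'   \code{\link{partitionVolumes}})
#' @param seed RNG seed
#' @return list with \code{features} (RootFeatureRecord data.frame),
#'   \code{respiration} (sample_id, flux_nmol_s with noise/offset applied)
#'   and \code{truth} (noise-free respiration and the rates used)
#' @export
simulateRootSystems <- function(n, srr_axial = 8e-4,
                                srr_lateral_axis = 8e-4 * 30.5 / 8.1,
                                srr_tip = 8e-4 * 30.5,
                                size_factor = 1, allometric_sd = 0.15,
                                respiration_noise_sd = 0,
                                respiration_offset = 0,
                                seminal_count = 4,
                                tip_unit_volume_mm3 = 0.01, seed = 1) {
  stopifnot(srr_axial >= 0, srr_lateral_axis >= 0, srr_tip >= 0, n >= 1)
  set.seed(seed)
  s <- rep_len(size_factor, n)
  off <- rep_len(respiration_offset, n)
  ln <- function(mu) mu * s * exp(rnorm(n, sd = allometric_sd))
  tips <- pmax(round(ln(400)), seminal_count + 1)
  bp <- pmax(round(ln(930)), 1)
  arl <- ln(1456); lrl <- ln(2670)
  arv <- ln(244); lrv <- ln(85.6)
  asa <- ln(2034); lsa <- ln(1647)
  avgd <- 0.29 * exp(rnorm(n, sd = allometric_sd / 3))
  feats <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    tips = tips, branch_points = bp,
    total_root_length_mm = arl + lrl,
    axial_root_length_mm = arl, lateral_root_length_mm = lrl,
    total_root_volume_mm3 = arv + lrv,
    axial_root_volume_mm3 = arv, lateral_root_volume_mm3 = lrv,
    total_surface_area_mm2 = asa + lsa,
    axial_surface_area_mm2 = asa, lateral_surface_area_mm2 = lsa,
    avg_diameter_mm = avgd, stringsAsFactors = FALSE
  )
  n_lat <- pmax(tips - seminal_count, 0)
  tipv <- n_lat * tip_unit_volume_mm3
  latax <- pmax(lrv - tipv, 0)
  true_resp <- srr_axial * arv + srr_lateral_axis * latax + srr_tip * tipv
  obs <- pmax(true_resp + off + rnorm(n, sd = respiration_noise_sd), 0)
  list(
    features = feats,
    respiration = data.frame(sample_id = feats$sample_id,
                             flux_nmol_s = obs, stringsAsFactors = FALSE),
    truth = list(true_respiration = true_resp,
                 rates = c(axial = srr_axial, lateral_axis = srr_lateral_axis,
                           tip = srr_tip))
  )
}
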