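#' Default multi-trait GWAS sets
#'
#' The six functional trait groupings used for multivariate association:
#' biomass, root respiration, morphology, topology, construction and
#' allocation.
#'
#' @return named list of trait-name vectors
#' @export
defaultTraitSets <- function() {
  list(
    biomass = c("RDW", "SDW"),
    root_respiration = c("TRR", "RDW", "RMF", "Tip", "ARL", "BD"),
    morphology = c("ARL", "LRL", "ARV", "LRV", "ASA", "LSA"),
    topology = c("BP", "BF", "BD"),
    construction = c("SRL", "RTD", "AvgD"),
    allocation = c("RMF", "L_A_L", "L_A_V")
  )
}

#' Generate a complete synthetic input set on disk
#'
#' Builds every file the pipeline consumes, with known ground truth: a
#' genotyped diversity panel over a randomized complete block design,
#' per-plant root architecture whose size is heritable (with one planted
#' size QTL), dry masses, chamber CO2 traces whose underlying flux is the
#' tissue-volume-weighted respiration (tip rate 30.5x axial, 8.1x lateral
#' axis) plus a heritable metabolic offset (with one planted respiration
#' QTL), and a gene annotation table with genes placed near the planted
#' QTL. The "tiny" preset (50 genotypes x 4 blocks, 500 markers) runs the
#' whole pipeline in well under a minute; "paper-scale" is 276 genotypes x
#' 4 blocks and 5000 markers.
#'
#' @param dir output directory (created if needed)
#' @param preset "tiny" or "paper-scale"
#' @param seed root RNG seed for every generator
#' @param trace_noise_sd instrument noise on the CO2 traces (umol mol-1)
#' @return invisibly, a list with the file paths, the written config path
#'   and the ground-truth record
#' @export
makeFixture <- function(dir, preset = c("tiny", "paper-scale"), seed = 1,
                        trace_noise_sd = 0.05) {
  preset <- match.arg(preset)
  dims <- switch(preset,
                 tiny = list(ng = 50L, nb = 4L, nm = 500L, nc = 5L),
                 `paper-scale` = list(ng = 276L, nb = 4L, nm = 5000L,
                                      nc = 21L))
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  cfg <- SimulationConfig(n_genotypes = dims$ng, n_blocks = dims$nb,
                          n_markers = dims$nm, n_chromosomes = dims$nc,
                          missing_rate = 0.02, fst = 0.05, seed = seed)
  geno <- simulateGenotypes(cfg)
  maf <- mafs(geno)
  set.seed(seed + 1L)
  common <- names(maf)[maf >= 0.2]
  qtl_size <- sample(common, 1)
  qtl_met <- sample(setdiff(common, qtl_size), 1)
  ng <- dims$ng; nb <- dims$nb; n <- ng * nb
  gid <- rownames(dosages(geno))
  # latent genetic effects: log-size (H2_true = 0.04/(0.04+0.12/4) = 0.571
  # before the QTL) and an additive metabolic offset on respiration
  sg_size <- 0.04; se_size <- 0.12
  sg_met <- 0.0025; se_met <- 0.0009   # nmol^2 s^-2
  g_size <- rnorm(ng, sd = sqrt(sg_size))
  g_met <- rnorm(ng, sd = sqrt(sg_met))
  W <- dosages(geno)
  xs <- W[, qtl_size]; xs[is.na(xs)] <- mean(xs, na.rm = TRUE)
  xm <- W[, qtl_met]; xm[is.na(xm)] <- mean(xm, na.rm = TRUE)
  beta_size <- sqrt(0.15 * (sg_size + se_size / nb) /
                      (2 * maf[qtl_size] * (1 - maf[qtl_size])))
  beta_met <- sqrt(0.25 * (sg_met + se_met / nb) /
                     (2 * maf[qtl_met] * (1 - maf[qtl_met])))
  g_size <- g_size + xs * beta_size
  g_met <- g_met + xm * beta_met
  block_eff <- seq(-0.05, 0.05, length.out = nb)
  plants <- expand.grid(block_id = seq_len(nb), genotype_row = seq_len(ng))
  size <- exp(block_eff[plants$block_id] + g_size[plants$genotype_row] +
                rnorm(n, sd = sqrt(se_size)))
  sample_id <- sprintf("S%05d", seq_len(n))
  samples <- data.frame(sample_id = sample_id,
                        genotype_id = gid[plants$genotype_row],
                        block_id = plants$block_id,
                        stringsAsFactors = FALSE)
  # architecture + true respiration from the tissue partition
  rs <- simulateRootSystems(
    n, size_factor = size, allometric_sd = 0.20,
    respiration_noise_sd = 0,
    respiration_offset = g_met[plants$genotype_row] +
      rnorm(n, sd = sqrt(se_met)),
    seed = seed + 2L)
  rs$features$sample_id <- sample_id
  rs$respiration$sample_id <- sample_id
  masses <- data.frame(
    sample_id = sample_id,
    shoot_dry_weight_g = 0.039 * size * exp(rnorm(n, sd = 0.08)),
    root_dry_weight_g = 0.014 * size * exp(rnorm(n, sd = 0.05)),
    stringsAsFactors = FALSE)
  chamber <- ChamberConfig()
  for (i in seq_len(n)) {
    vol <- correctedChamberVolume(chamber@chamber_volume_ml,
                                  rs$features$total_root_volume_mm3[i])
    tr <- simulateGasTrace(rs$respiration$flux_nmol_s[i], chamber,
                           corrected_volume_ml = vol,
                           noise_sd = trace_noise_sd,
                           transient_amplitude = 5,
                           sample_id = sample_id[i],
                           seed = seed + 10L + i)
    writeGasTrace(tr, file.path(dir, "traces"))
  }
  # annotation: genes near the two planted QTL plus random background genes
  map <- markerMap(geno)
  set.seed(seed + 3L)
  bg <- map[sample.int(nrow(map), min(40L, nrow(map))), ]
  mk2 <- map[map$marker_id %in% c(qtl_size, qtl_met), ]
  ann <- rbind(
    data.frame(gene_id = paste0("GENE_", mk2$marker_id),
               chromosome = mk2$chromosome,
               start = pmax(mk2$position_bp - 5000L, 1L),
               end = mk2$position_bp + 5000L, stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("GENE_BG%03d", seq_len(nrow(bg))),
               chromosome = bg$chromosome,
               start = pmax(bg$position_bp + 400000L, 1L),
               end = bg$position_bp + 410000L, stringsAsFactors = FALSE))
  paths <- list(
    traces = file.path(dir, "traces"),
    features = file.path(dir, "features.csv"),
    masses = file.path(dir, "masses.csv"),
    samples = file.path(dir, "samples.csv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    annotation = file.path(dir, "annotation.tsv"))
  write.csv(rs$features, paths$features, row.names = FALSE)
  write.csv(masses, paths$masses, row.names = FALSE)
  write.csv(samples, paths$samples, row.names = FALSE)
  writeGenotypes(geno, paths$genotypes)
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config <- c(paths, list(out_dir = file.path(dir, "results"), seed = seed))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  qtl_var_size <- 2 * maf[qtl_size] * (1 - maf[qtl_size]) * beta_size^2
  qtl_var_met <- 2 * maf[qtl_met] * (1 - maf[qtl_met]) * beta_met^2
  # observed-scale H2 of a trait C exp(g + e), g ~ N(0, sg), e ~ N(0, se):
  # genotypic variance (exp(sg)-1) exp(sg) exp(se), residual
  # exp(2 sg) exp(se) (exp(se)-1)
  h2_obs <- function(sg, se, r)
    (1 - exp(-sg)) / ((1 - exp(-sg)) + (exp(se) - 1) / r)
  truth <- list(
    qtl = list(size = list(marker = qtl_size, effect = beta_size),
               respiration = list(marker = qtl_met, effect = beta_met)),
    h2_size_true = (sg_size + qtl_var_size) /
      (sg_size + qtl_var_size + se_size / nb),
    h2_sdw_true = h2_obs(sg_size + qtl_var_size, se_size + 0.08^2, nb),
    h2_rdw_true = h2_obs(sg_size + qtl_var_size, se_size + 0.05^2, nb),
    h2_srr_r_true = (sg_met + qtl_var_met) /
      (sg_met + qtl_var_met + se_met / nb),
    rates = as.list(rs$truth$rates),
    sigma = list(sg_size = sg_size, se_size = se_size, sg_met = sg_met,
                 se_met = se_met))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(list(paths = paths, config = config_path, truth = truth))
}

# fill defaults and validate a pipeline configuration
.normalizeConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    chamber = list(), seed = 1,
    partition = list(seminal_count = 4, tip_unit_volume_mm3 = 0.01),
    network = list(cutoff = 0.15),
    gwas = list(modes = c("univariate", "multivariate", "pc"),
                traits = NULL, n_pcs = 10, logp_threshold = 3.5,
                fdr_q = 0.05, window_bp = 250000,
                max_missing = 0.5, min_maf = 0.05,
                trait_sets = NULL))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(config[[k]][[kk]]))
          config[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  if (is.null(config$gwas$trait_sets))
    config$gwas$trait_sets <- defaultTraitSets()
  want_gwas <- length(config$gwas$modes) > 0
  need <- c("traces", "features", "masses", "samples",
            if (want_gwas) "genotypes")
  for (p in need) {
    if (is.null(config[[p]]))
      stop("pipeline config lacks required path '", p, "'")
    if (!file.exists(config[[p]]))
      stop("configured path does not exist: ", p, " = ", config[[p]])
  }
  known <- traitNames(with_srr_r = TRUE)
  for (s in names(config$gwas$trait_sets)) {
    bad <- setdiff(config$gwas$trait_sets[[s]], known)
    if (length(bad))
      stop("trait set '", s, "' names unknown traits: ",
           paste(bad, collapse = ", "))
  }
  config
}

#' Run the full root-economics analysis
#'
#' Orchestrates flux extraction, trait derivation, respiration
#' partitioning, heritability, trait networks/PCA and association scans
#' from a single configuration (a YAML path or an equivalent list), writing
#' every stage's table as CSV into the configured output directory plus a
#' machine-readable \code{summary.json}. Identical config and seed give an
#' identical summary.
#'
#' @param config YAML file path or list; see \code{\link{makeFixture}} for
#'   the generated template. Required paths: traces, features, masses,
#'   samples; genotypes (+ optionally annotation) when GWAS modes are
#'   requested.
#' @return invisibly, a list with all stage outputs and the summary
#' @export
runPipeline <- function(config) {
  config <- .normalizeConfig(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("pipeline config lacks 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chamber <- do.call(ChamberConfig, config$chamber)
  features <- readFeatureTable(config$features)
  masses <- readMassTable(config$masses)
  samples <- readSampleInfo(config$samples)

  ## stage 1: flux
  flux <- batchFlux(config$traces, data.frame(
    sample_id = features$sample_id,
    total_root_volume_mm3 = features$total_root_volume_mm3), chamber)
  write.csv(flux$results, file.path(out_dir, "flux.csv"),
            row.names = FALSE)

  ## stage 2: traits
  der <- deriveTraits(features, masses, flux$results, samples)
  plant <- der$traits

  ## stage 3: respiration partition + SRR_R
  vols <- partitionVolumes(features,
                           config$partition$seminal_count,
                           config$partition$tip_unit_volume_mm3)
  pm <- fitPartitionModel(vols, flux$results)
  step <- stepwiseAIC(vols, flux$results)
  srr_r <- residualTrait(pm, vols, flux$results)
  plant <- merge(plant, srr_r[c("sample_id", "SRR_R")], by = "sample_id")
  write.csv(plant, file.path(out_dir, "traits_plant.csv"),
            row.names = FALSE)
  gmeans <- genotypeMeans(plant)
  write.csv(gmeans, file.path(out_dir, "traits_genotype.csv"),
            row.names = FALSE)
  write.csv(summarizeTraits(gmeans),
            file.path(out_dir, "trait_summary.csv"), row.names = FALSE)
  write.csv(pm$coefficients, file.path(out_dir, "partition_model.csv"),
            row.names = FALSE)

  ## stage 4: heritability
  h2 <- heritabilityTable(plant)
  write.csv(h2, file.path(out_dir, "heritability.csv"), row.names = FALSE)

  ## stage 5: correlations, PCA, network
  pear <- pearsonMatrix(gmeans)
  write.csv(data.frame(trait = rownames(pear$r), pear$r,
                       check.names = FALSE),
            file.path(out_dir, "pearson_r.csv"), row.names = FALSE)
  pca <- pcaTraits(gmeans)
  write.csv(data.frame(pc = colnames(pca$scores),
                       explained_pct = pca$explained_variance_pct),
            file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
  write.csv(data.frame(trait = rownames(pca$contributions_pct),
                       pca$contributions_pct, check.names = FALSE),
            file.path(out_dir, "pca_contributions.csv"), row.names = FALSE)
  net <- ggmNetwork(gmeans)
  cen <- networkCentrality(net, config$network$cutoff)
  write.csv(cen$edges, file.path(out_dir, "network_edges.csv"),
            row.names = FALSE)
  write.csv(cen$centrality, file.path(out_dir, "network_centrality.csv"),
            row.names = FALSE)

  ## stage 6: association
  scans <- NULL; windows <- NULL; qc <- NULL
  if (length(config$gwas$modes)) {
    geno <- readGenotypes(config$genotypes)
    geno <- filterMarkers(geno, config$gwas$max_missing,
                          config$gwas$min_maf)
    qc <- S4Vectors::metadata(geno)$filter
    K <- relatednessMatrix(geno)
    trait_cols <- config$gwas$traits
    if (is.null(trait_cols))
      trait_cols <- intersect(traitNames(with_srr_r = TRUE), names(gmeans))
    res <- list()
    if ("univariate" %in% config$gwas$modes) {
      for (tc in trait_cols) {
        y <- setNames(gmeans[[tc]], gmeans$genotype_id)
        res[[paste0("uni_", tc)]] <- lmmScan(y, geno, K = K, trait = tc)
      }
    }
    if ("multivariate" %in% config$gwas$modes) {
      for (s in names(config$gwas$trait_sets)) {
        cols <- intersect(config$gwas$trait_sets[[s]], names(gmeans))
        if (length(cols) < 2) next
        Y <- as.matrix(gmeans[cols])
        rownames(Y) <- gmeans$genotype_id
        res[[paste0("mv_", s)]] <- mvLmmScan(Y, geno, K = K,
                                             trait_set = s)
      }
    }
    if ("pc" %in% config$gwas$modes)
      res[["pc"]] <- pcGwas(pca, geno, K = K, n_pcs = config$gwas$n_pcs)
    common <- c("marker_id", "chromosome", "position_bp", "maf", "stat",
                "p_value", "minus_log10_p", "trait", "model")
    scans <- do.call(rbind, lapply(res, function(r) r[common]))
    rownames(scans) <- NULL
    scans <- declareSignificant(scans, config$gwas$logp_threshold,
                                config$gwas$fdr_q)
    write.csv(scans, file.path(out_dir, "gwas.csv"), row.names = FALSE)
    if (!is.null(config$annotation) && file.exists(config$annotation)) {
      sig <- scans[scans$raw_pass, , drop = FALSE]
      sig <- sig[!duplicated(sig$marker_id), , drop = FALSE]
      windows <- candidateWindows(sig, readAnnotation(config$annotation),
                                  config$gwas$window_bp)
      write.csv(windows, file.path(out_dir, "candidate_genes.csv"),
                row.names = FALSE)
    }
  }

  summary <- list(
    n_samples = nrow(samples),
    n_flux_ok = nrow(flux$results),
    n_flux_rejected = nrow(flux$rejects),
    n_trait_rejected = nrow(der$rejects),
    partition = list(r_squared = round(pm$r_squared, 6),
                     ratio_tip_axial = round(pm$ratio_tip_axial, 4),
                     ratio_tip_lateral = round(pm$ratio_tip_lateral, 4),
                     stepwise_terms = step$terms,
                     n_clamped = pm$n_clamped),
    heritability = setNames(as.list(round(h2$H2, 4)), h2$trait),
    pca_explained_pct = round(pca$explained_variance_pct[
      seq_len(min(10, length(pca$explained_variance_pct)))], 3),
    marker_qc = qc,
    n_raw_significant = if (!is.null(scans)) sum(scans$raw_pass) else NULL,
    n_fdr_significant = if (!is.null(scans)) sum(scans$fdr_pass) else NULL,
    n_candidate_genes = if (!is.null(windows)) nrow(windows) else NULL,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rejects <- rbind(
    if (nrow(flux$rejects)) cbind(stage = "flux", flux$rejects),
    if (nrow(der$rejects)) cbind(stage = "traits", der$rejects))
  if (!is.null(rejects))
    write.csv(rejects, file.path(out_dir, "qc_rejects.csv"),
              row.names = FALSE)
  invisible(list(flux = flux, plant_traits = plant,
                 genotype_traits = gmeans, partition = pm,
                 stepwise = step, heritability = h2, pearson = pear,
                 pca = pca, network = net, centrality = cen,
                 gwas = scans, candidate_genes = windows,
                 summary = summary))
}
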