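#' REML variance components for a randomized complete block design
#'
#' Fits the mixed model value ~ block (fixed) + genotype (random) by REML
#' and returns the genotypic and residual variance components. On balanced
#' data the REML genotypic variance equals the ANOVA moment estimator
#' (MS_genotype - MS_error) / r, truncated at zero.
#'
#' @param plants data.frame with columns genotype_id, block_id and the
#'   response
#' @param trait name of the response column
#' @return object of class \code{variance_components}: sigma_g2, sigma_e2,
#'   n_reps (harmonic-mean replicates per genotype), reml_loglik
#' @export
fitRcbdReml <- function(plants, trait = "value") {
  stopifnot(all(c("genotype_id", "block_id", trait) %in% names(plants)))
  d <- plants[!is.na(plants[[trait]]), , drop = FALSE]
  if (!nrow(d)) stop("trait '", trait, "' has no non-missing values")
  if (length(unique(d$genotype_id)) < 2 || length(unique(d$block_id)) < 2)
    stop("need at least 2 genotypes and 2 blocks")
  d$.y <- d[[trait]]
  fit <- lme4::lmer(.y ~ factor(block_id) + (1 | genotype_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sg2 <- vc$vcov[vc$grp == "genotype_id"]
  se2 <- vc$vcov[vc$grp == "Residual"]
  reps <- table(d$genotype_id)
  structure(list(
    sigma_g2 = sg2,
    sigma_e2 = se2,
    n_reps = length(reps) / sum(1 / reps),  # harmonic mean
    reml_loglik = as.numeric(stats::logLik(fit)),
    trait = trait
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s): sigma_g2 = %.4g, sigma_e2 = %.4g, r = %.2f, H2 = %.3f\n",
    x$trait, x$sigma_g2, x$sigma_e2, x$n_reps, broadSenseH2(x)))
  invisible(x)
}

#' Broad-sense heritability on a genotype-mean basis
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_e2 / r): the fraction of the variance
#' of genotype means attributable to genotypic variance, with the residual
#' variance shrunk by the number of replicates r.
#'
#' @param vc a \code{variance_components} object (or a list with sigma_g2,
#'   sigma_e2, n_reps)
#' @return H2 in [0, 1]
#' @examples
#' broadSenseH2(list(sigma_g2 = 1, sigma_e2 = 3, n_reps = 4))  # 0.5714
#' @export
broadSenseH2 <- function(vc) {
  stopifnot(vc$sigma_g2 >= 0, vc$sigma_e2 >= 0, vc$n_reps >= 1)
  denom <- vc$sigma_g2 + vc$sigma_e2 / vc$n_reps
  if (denom == 0) return(0)
  vc$sigma_g2 / denom
}

#' Heritability of every trait in a plant-level table
#'
#' @param plants plant-level trait table with genotype_id and block_id
#' @param trait_cols trait columns (default: all numeric except identifiers)
#' @return data.frame with trait, sigma_g2, sigma_e2, n_reps, H2
#' @export
heritabilityTable <- function(plants, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(plants)[vapply(plants, is.numeric,
                                               logical(1))],
                          c("block_id", "n_reps"))
  rows <- lapply(trait_cols, function(tc) {
    vc <- fitRcbdReml(plants, tc)
    data.frame(trait = tc, sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
               n_reps = vc$n_reps, H2 = broadSenseH2(vc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
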