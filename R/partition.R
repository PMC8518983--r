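#' Split root volume into axial, lateral-axis and lateral-tip compartments
#'
#' The number of lateral root tips is the total tip count minus the assumed
#' number of seminal (axial) roots, floored at zero; each lateral tip is
#' assigned a small nominal volume, and the lateral-root axis volume is the
#' total lateral volume minus the tip volume (also floored at zero, with
#' clamping flagged).
#'
#' @param features RootFeatureRecord data.frame (needs sample_id, tips,
#'   axial_root_volume_mm3, lateral_root_volume_mm3)
#' @param seminal_count assumed seminal roots per seedling (default 4)
#' @param tip_unit_volume_mm3 nominal volume per lateral tip (default
#'   0.01 mm3)
#' @return data.frame with sample_id, axial_volume_mm3,
#'   lateral_axis_volume_mm3, tip_volume_mm3, n_lateral_tips, clamped
#' @examples
#' partitionVolumes(data.frame(sample_id = "a", tips = 404,
#'                             axial_root_volume_mm3 = 244,
#'                             lateral_root_volume_mm3 = 85.6))
#' @export
partitionVolumes <- function(features, seminal_count = 4,
                             tip_unit_volume_mm3 = 0.01) {
  stopifnot(all(c("sample_id", "tips", "axial_root_volume_mm3",
                  "lateral_root_volume_mm3") %in% names(features)))
  n_lat <- pmax(features$tips - seminal_count, 0)
  tipv <- n_lat * tip_unit_volume_mm3
  raw_axis <- features$lateral_root_volume_mm3 - tipv
  data.frame(
    sample_id = features$sample_id,
    axial_volume_mm3 = features$axial_root_volume_mm3,
    lateral_axis_volume_mm3 = pmax(raw_axis, 0),
    tip_volume_mm3 = tipv,
    n_lateral_tips = n_lat,
    clamped = (features$tips < seminal_count) | (raw_axis < 0),
    stringsAsFactors = FALSE
  )
}

#' Regress total respiration on tissue-compartment volumes
#'
#' Multiple linear regression of total root respiration on the three
#' tissue-compartment volumes (axial, lateral axis, lateral tips), with
#' intercept. The fitted slopes are the average specific respiration rates
#' per unit volume of each tissue class; their ratios (tip over axial, tip
#' over lateral axis) summarize how much more metabolically active the tips
#' are.
#'
#' @param volumes output of \code{\link{partitionVolumes}}
#' @param respiration data.frame with sample_id, flux_nmol_s
#' @return object of class \code{partition_model}: coefficient table
#'   (estimate, se, p), r_squared, model p-value, slope ratios, the fitted
#'   \code{lm}, and the clamp count
#' @export
fitPartitionModel <- function(volumes, respiration) {
  d <- merge(volumes, respiration, by = "sample_id")
  d <- d[complete.cases(d[c("axial_volume_mm3", "lateral_axis_volume_mm3",
                            "tip_volume_mm3", "flux_nmol_s")]), ]
  if (nrow(d) < 5) stop("need at least 5 complete cases")
  X <- as.matrix(d[c("axial_volume_mm3", "lateral_axis_volume_mm3",
                     "tip_volume_mm3")])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 4) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, 4)] - 1L]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }
  fit <- lm(flux_nmol_s ~ axial_volume_mm3 + lateral_axis_volume_mm3 +
              tip_volume_mm3, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  slopes <- co[-1L, 1L]
  fstat <- sm$fstatistic
  structure(list(
    coefficients = data.frame(
      term = rownames(co), estimate = co[, 1L], se = co[, 2L],
      p_value = co[, 4L], row.names = NULL, stringsAsFactors = FALSE),
    r_squared = sm$r.squared,
    model_p = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                        lower.tail = FALSE)),
    ratio_tip_axial = if (slopes[1L] > 0)
      unname(slopes[3L] / slopes[1L]) else NA_real_,
    ratio_tip_lateral = if (slopes[2L] > 0)
      unname(slopes[3L] / slopes[2L]) else NA_real_,
    n = nrow(d),
    n_clamped = sum(volumes$clamped),
    fit = fit
  ), class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat("Respiration partition model (n =", x$n, ")\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("R2 = %.3f, model p = %.3g\n", x$r_squared, x$model_p))
  cat(sprintf("slope ratios  tip:axial = %.2f  tip:lateral = %.2f\n",
              x$ratio_tip_axial, x$ratio_tip_lateral))
  if (x$n_clamped > 0)
    cat(x$n_clamped, "sample(s) had clamped compartment volumes\n")
  invisible(x)
}

#' Bidirectional stepwise model selection by AIC
#'
#' Stepwise search over the partition-model terms minimizing
#' AIC = n log(RSS/n) + 2k, starting from the full three-compartment model
#' and allowing both dropping and re-adding of terms.
#'
#' @param volumes output of \code{\link{partitionVolumes}}
#' @param respiration data.frame with sample_id, flux_nmol_s
#' @return list with \code{terms} (selected predictors), \code{aic},
#'   \code{trace} (the step history) and the selected \code{lm} fit
#' @export
stepwiseAIC <- function(volumes, respiration) {
  d <- merge(volumes, respiration, by = "sample_id")
  full <- lm(flux_nmol_s ~ axial_volume_mm3 + lateral_axis_volume_mm3 +
               tip_volume_mm3, data = d)
  sel <- MASS::stepAIC(full, direction = "both", trace = 0)
  list(
    terms = attr(terms(sel), "term.labels"),
    aic = stats::extractAIC(sel)[2L],
    trace = sel$anova,
    fit = sel
  )
}

#' Residual respiration trait (SRR_R)
#'
#' SRR_R is the observed minus the partition-model-predicted total root
#' respiration: the respiration a root system performs beyond (positive) or
#' below (negative) what its tissue-compartment volumes predict. By OLS
#' construction its mean over the fitting set is zero.
#'
#' @param model a \code{partition_model}
#' @param volumes compartment volumes for the samples to score
#' @param respiration observed respiration for the same samples
#' @return data.frame with sample_id, predicted_nmol_s, SRR_R
#' @export
residualTrait <- function(model, volumes, respiration) {
  stopifnot(inherits(model, "partition_model"))
  d <- merge(volumes, respiration, by = "sample_id")
  pred <- predict(model$fit, newdata = d)
  data.frame(sample_id = d$sample_id,
             predicted_nmol_s = unname(pred),
             SRR_R = d$flux_nmol_s - unname(pred),
             stringsAsFactors = FALSE)
}
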