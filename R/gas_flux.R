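#' Read one chamber CO2 trace file
#'
#' Parses a plain-text infrared-gas-analyzer trace: optional leading header
#' lines (starting with '#' or containing non-numeric tokens) followed by
#' whitespace- or comma-delimited columns time_s, co2_umol_mol and optionally
#' h2o_mmol_mol. The sample barcode is taken from the filename stem.
#' Unparseable data rows are skipped with a warning.
#'
#' @param path path to the trace file (filename = barcode + ".txt")
#' @return a \linkS4class{GasTrace}
#' @export
readGasTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty trace file: ", path)
  fields <- strsplit(lines, "[,\t ]+")
  nums <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  is_data <- vapply(nums, function(v) {
    length(v) >= 2L && !any(is.na(v[1:2]))
  }, logical(1)) & !startsWith(lines, "#")
  # header block: leading non-data lines; interior bad rows are warned about
  first_data <- which(is_data)[1]
  if (is.na(first_data)) stop("no parseable data rows in: ", path)
  body <- is_data & seq_along(lines) >= first_data
  n_bad <- sum(!is_data[seq_along(lines) >= first_data &
                          !startsWith(lines, "#")])
  if (n_bad > 0)
    warning(sprintf("%d unparseable row(s) skipped in %s", n_bad, path))
  vals <- nums[body]
  tm <- vapply(vals, `[`, numeric(1), 1L)
  co2 <- vapply(vals, `[`, numeric(1), 2L)
  h2o <- vapply(vals, function(v) if (length(v) >= 3L) v[3L] else NA_real_,
                numeric(1))
  if (length(tm) < 2L)
    stop("fewer than 2 valid readings in trace file: ", path)
  GasTrace(
    sample_id = sub("\\.[^.]*$", "", basename(path)),
    time_s = tm,
    co2_umol_mol = co2,
    h2o_mmol_mol = if (all(is.na(h2o))) numeric() else h2o
  )
}

#' Slope of CO2 accumulation over the measurement window
#'
#' Ordinary-least-squares slope of CO2 concentration on time over the
#' retained window (both endpoints inclusive), after discarding the
#' equilibration dead band.
#'
#' @param trace a \linkS4class{GasTrace}
#' @param dead_band_s seconds at the start of the trace to ignore
#' @param window_end_s last second included in the fit
#' @return list with \code{slope} (umol mol-1 s-1), \code{r_squared} and
#'   \code{n_points}
#' @export
estimateSlope <- function(trace, dead_band_s = 20, window_end_s = 90) {
  stopifnot(is(trace, "GasTrace"), dead_band_s < window_end_s)
  keep <- trace@time_s >= dead_band_s & trace@time_s <= window_end_s
  if (sum(keep) < 2L)
    stop("fewer than 2 readings in the [", dead_band_s, ", ", window_end_s,
         "] s window for sample ", trace@sample_id)
  tt <- trace@time_s[keep]
  cc <- trace@co2_umol_mol[keep]
  fit <- lm(cc ~ tt)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((cc - mean(cc))^2)
  list(
    slope = unname(coef(fit)[2L]),
    r_squared = if (sst > 0) 1 - ssr / sst else 1,
    n_points = length(tt)
  )
}

#' Chamber volume corrected for the volume occupied by the roots
#'
#' @param chamber_volume_ml nominal chamber volume (ml)
#' @param root_volume_mm3 total root volume of the sample (mm3)
#' @return corrected chamber volume in ml
#' @export
correctedChamberVolume <- function(chamber_volume_ml, root_volume_mm3) {
  stopifnot(root_volume_mm3 >= 0)
  v <- chamber_volume_ml - root_volume_mm3 / 1000
  if (v <= 0)
    stop("root volume (", root_volume_mm3,
         " mm3) meets or exceeds chamber volume (", chamber_volume_ml, " ml)")
  v
}

#' CO2 flux from the accumulation slope via the ideal gas law
#'
#' F = P V / (R T) * dC/dt, with the chamber volume in litres and the slope
#' converted from umol mol-1 s-1 to mole fraction per second; the resulting
#' molar flux is reported in nmol CO2 s-1. Negative slopes are propagated
#' as-is.
#'
#' @param slope_umol_mol_s CO2 accumulation slope (umol mol-1 s-1)
#' @param chamber a \linkS4class{ChamberConfig} supplying P, T and R
#' @param corrected_volume_ml chamber volume after root-volume correction (ml)
#' @return flux in nmol CO2 s-1
#' @examples
#' computeFlux(0.5, ChamberConfig(), 19)  # ~0.384 nmol s-1
#' @export
computeFlux <- function(slope_umol_mol_s, chamber = ChamberConfig(),
                        corrected_volume_ml = chamber@chamber_volume_ml) {
  stopifnot(is.finite(slope_umol_mol_s), corrected_volume_ml > 0)
  mol_air <- chamber@pressure_kPa * (corrected_volume_ml / 1000) /
    (chamber@gas_constant * chamber@temperature_K)
  # slope [umol/mol/s] * 1e-6 -> mol fraction/s; * mol air -> mol/s; *1e9 -> nmol/s
  slope_umol_mol_s * 1e-6 * mol_air * 1e9
}

#' Flux for every trace file in a directory
#'
#' Applies the dead-band slope fit and ideal-gas flux computation to each
#' trace, matching samples to their root volumes (needed for the chamber
#' volume correction) by barcode. Per-sample failures are collected in a
#' rejects table rather than aborting the batch.
#'
#' @param trace_dir directory of trace files, one per sample
#' @param root_volume_table data.frame with columns \code{sample_id} and
#'   \code{total_root_volume_mm3}
#' @param chamber a \linkS4class{ChamberConfig}
#' @return list with \code{results} (one row per successful sample:
#'   sample_id, slope, r2, n_points, corrected_volume_ml, flux_nmol_s,
#'   negative_flux flag) and \code{rejects} (sample_id, reason)
#' @export
batchFlux <- function(trace_dir, root_volume_table,
                      chamber = ChamberConfig()) {
  files <- list.files(trace_dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no trace files found in ", trace_dir)
  res <- list(); rej <- list()
  for (f in files) {
    sid <- sub("\\.[^.]*$", "", basename(f))
    row <- tryCatch({
      tr <- suppressWarnings(readGasTrace(f))
      idx <- match(tr@sample_id, root_volume_table$sample_id)
      if (is.na(idx))
        stop("barcode not present in root volume table")
      vol <- correctedChamberVolume(
        chamber@chamber_volume_ml,
        root_volume_table$total_root_volume_mm3[idx])
      sl <- estimateSlope(tr, chamber@dead_band_s, chamber@window_end_s)
      flux <- computeFlux(sl$slope, chamber, vol)
      data.frame(sample_id = tr@sample_id, slope = sl$slope,
                 r2 = sl$r_squared, n_points = sl$n_points,
                 corrected_volume_ml = vol, flux_nmol_s = flux,
                 negative_flux = flux < 0, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(
        sample_id = sid, reason = conditionMessage(row),
        stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <- row
    }
  }
  list(
    results = if (length(res)) do.call(rbind, res) else
      data.frame(sample_id = character(), slope = numeric(),
                 r2 = numeric(), n_points = integer(),
                 corrected_volume_ml = numeric(), flux_nmol_s = numeric(),
                 negative_flux = logical()),
    rejects = if (length(rej)) do.call(rbind, rej) else
      data.frame(sample_id = character(), reason = character())
  )
}
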