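# Forward model: per-detector dose for each dwell position.
#
# Heterogeneity enters as primary-photon attenuation scaling: the TG-43
# water dose is multiplied by exp(-mu_eff * (WEPL - d_geom)), with a single
# effective attenuation coefficient for water at Ir-192 energies. Compton
# dominance at ~0.38 MeV makes density (electron-density) scaling a standard
# first-order model; material labels are not used for attenuation.

#' Heterogeneity (attenuation-scaling) model
#'
#' @param mu_eff Effective linear attenuation coefficient of water at
#'   Ir-192 energies, 1/cm (default 0.111).
#' @param enabled If `FALSE`, heterogeneity is ignored even when a phantom
#'   is supplied.
#' @return An object of class `heterogeneity_model`.
#' @export
heterogeneity_model <- function(mu_eff = 0.111, enabled = TRUE) {
  stop_if_not_number(mu_eff, "mu_eff", positive = TRUE)
  structure(list(mu_eff = mu_eff, enabled = isTRUE(enabled)),
            class = "heterogeneity_model")
}

# polar angle (deg, from the source long axis = +y) and |cos incidence|
# (vs the array normal = +z) of rays from source_pos to detector rows
ray_angles <- function(source_pos, detector_pos) {
  v <- sweep(detector_pos, 2, source_pos)
  r <- sqrt(rowSums(v^2))
  list(r = r,
       theta = acos(pmin(pmax(v[, 2] / r, -1), 1)) * 180 / pi,
       cos_inc = abs(v[, 3]) / r)
}

#' Dose to one or more detectors from a single dwell
#'
#' Evaluates `dose_rate(r, theta)` for each source-detector ray (the
#' source long axis is fixed along y, the catheter direction), multiplied
#' by the heterogeneity attenuation factor
#' `exp(-mu_eff * (wepl - d_geom) / 10)` when a phantom is supplied and by
#' the detector's directional response.
#'
#' @param source_pos Dwell position, mm (3-vector).
#' @param detector_pos A 3-vector or n x 3 matrix of detector positions,
#'   mm.
#' @param source A [source_model()].
#' @param phantom Optional [voxel_phantom()]; `NULL` means water
#'   everywhere (attenuation factor 1).
#' @param het A [heterogeneity_model()].
#' @param array Optional [build_magic_plate()] array supplying the
#'   directional response (unity response when `NULL`).
#' @return Dose value(s), arbitrary units.
#' @export
detector_dose <- function(source_pos, detector_pos, source = source_model(),
                          phantom = NULL, het = heterogeneity_model(),
                          array = NULL) {
  stop_if_not_point(source_pos, "source_pos")
  if (!is.matrix(detector_pos)) detector_pos <- matrix(detector_pos, nrow = 1)
  ang <- ray_angles(source_pos, detector_pos)
  dose <- dose_rate(ang$r, ang$theta, source)
  if (!is.null(phantom) && het$enabled) {
    w <- wepl(phantom, source_pos, detector_pos)
    dose <- dose * exp(-het$mu_eff * (w - ang$r) / 10)
  }
  if (!is.null(array))
    dose <- dose * angular_response_factor(array, ang$cos_inc)
  dose
}

#' Reference calibration dose D_10
#'
#' The noiseless dose to a single detector placed 10 mm from the source on
#' its transverse axis in a water phantom. By the TG-43 normalization this
#' equals the source's `strength_scale`; it is the denominator of the
#' relative dose alpha_i = D_i / D_10.
#'
#' @param source A [source_model()].
#' @return Dose in the same arbitrary units as [detector_dose()].
#' @export
calibrate_D10 <- function(source = source_model()) {
  dose_rate(source$ref_radius, source$ref_angle, source)
}

# noiseless dwell x detector dose matrix
score_array_noiseless <- function(plan, array, source = source_model(),
                                  phantom = NULL,
                                  het = heterogeneity_model()) {
  pos <- dwell_positions(plan)
  t(vapply(seq_len(nrow(pos)), function(i)
    detector_dose(pos[i, ], array$positions, source, phantom, het, array),
    numeric(nrow(array$positions))))
}

#' Score the detector array over a dwell plan
#'
#' Computes the noiseless dose to every detector for every dwell, then
#' applies independent multiplicative Gaussian noise `N(1, noise_sigma^2)`
#' per reading (the k = 1 relative measurement uncertainty). The
#' calibration dose D_10 is computed noiselessly. Negative noisy readings
#' are clamped to zero and counted.
#'
#' @param plan A [make_dwell_plan()] plan.
#' @param array A [build_magic_plate()] array.
#' @param source A [source_model()].
#' @param phantom Optional [voxel_phantom()].
#' @param het A [heterogeneity_model()].
#' @param noise_sigma Relative standard deviation of the multiplicative
#'   noise (default 0.01 = 1 percent).
#' @param seed Optional integer seed; readings are reproducible given it.
#' @return An object of class `dose_readings`: list with `doses`
#'   (n_dwells x n_detectors matrix), `d10`, `noise_sigma`, `seed`,
#'   `n_clamped`, and the `plan` and `array` used.
#' @export
score_array <- function(plan, array, source = source_model(),
                        phantom = NULL, het = heterogeneity_model(),
                        noise_sigma = 0.01, seed = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  clean <- score_array_noiseless(plan, array, source, phantom, het)
  if (!is.null(seed)) set.seed(seed)
  doses <- if (noise_sigma > 0)
    clean * matrix(rnorm(length(clean), 1, noise_sigma), nrow = nrow(clean))
  else clean
  n_clamped <- sum(doses < 0)
  if (n_clamped > 0) {
    warning(sprintf("%d noisy readings fell below zero and were clamped",
                    n_clamped))
    doses[doses < 0] <- 0
  }
  structure(list(doses = doses, d10 = calibrate_D10(source),
                 noise_sigma = noise_sigma, seed = seed,
                 n_clamped = n_clamped, plan = plan, array = array),
            class = "dose_readings")
}

#' @export
print.dose_readings <- function(x, ...) {
  cat(sprintf("Dose readings: %d dwells x %d detectors\n",
              nrow(x$doses), ncol(x$doses)))
  cat(sprintf("  D_10 = %g (arb.), noise sigma = %g, seed = %s\n",
              x$d10, x$noise_sigma,
              if (is.null(x$seed)) "none" else as.character(x$seed)))
  if (x$n_clamped > 0)
    cat(sprintf("  %d readings clamped at zero\n", x$n_clamped))
  invisible(x)
}

#' Write / read dose readings
#'
#' CSV with columns `dwell,row,col,dose` plus a JSON sidecar
#' (`<path>.json`) holding `d10`, `noise_sigma`, `seed` and `n_clamped`.
#'
#' @param readings A `dose_readings` object.
#' @param path CSV output path.
#' @return `path` invisibly (write); for read, a list with `doses` matrix
#'   and the sidecar metadata.
#' @export
write_readings <- function(readings, path) {
  arr <- readings$array
  idx <- expand.grid(col = seq_len(arr$n_cols), row = seq_len(arr$n_rows))
  df <- do.call(rbind, lapply(seq_len(nrow(readings$doses)), function(dw)
    data.frame(dwell = dw, row = idx$row, col = idx$col,
               dose = readings$doses[dw, ])))
  write.csv(df, path, row.names = FALSE)
  meta <- list(d10 = readings$d10, noise_sigma = readings$noise_sigma,
               seed = readings$seed, n_clamped = readings$n_clamped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_readings
#' @export
read_readings <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n_dwell <- max(df$dwell)
  n_det <- nrow(df) / n_dwell
  doses <- matrix(NA_real_, n_dwell, n_det)
  ncols <- max(df$col)
  doses[cbind(df$dwell, (df$row - 1) * ncols + df$col)] <- df$dose
  c(list(doses = doses), meta)
}
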