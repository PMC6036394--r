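# Source localization: dose normalization, distance inversion, detector
# subset selection, linearized multilateration and iterative refinement
# with angular-dependence correction, plus the CT-density (WEPL) correction.

VALID_SUBSETS <- c(9, 25, 49, 81, 121)

#' Relative detector dose alpha_i = D_i / D_10
#'
#' @param doses Per-detector dose vector, arbitrary units.
#' @param d10 Calibration dose at 10 mm ([calibrate_D10()]), > 0.
#' @return Numeric alpha vector with logical attribute `"usable"` marking
#'   detectors with strictly positive dose.
#' @export
relative_dose <- function(doses, d10) {
  if (!is.numeric(d10) || length(d10) != 1L || d10 <= 0)
    stop("d10 must be a single positive dose", call. = FALSE)
  structure(doses / d10, usable = doses > 0)
}

#' Select the top-n detectors by deposited dose
#'
#' When fewer than all detectors are used for localization, the detectors
#' with the highest deposited dose are chosen. Ties are broken by
#' ascending detector index, making the selection deterministic.
#'
#' @param doses Per-detector dose vector for one dwell (or a
#'   `dose_readings` object together with `dwell`).
#' @param n Subset size; one of 9, 25, 49, 81, 121.
#' @param dwell Dwell row used when `doses` is a `dose_readings` object.
#' @return Integer vector of `n` detector indices, highest dose first.
#' @export
select_top_n <- function(doses, n, dwell = 1L) {
  if (inherits(doses, "dose_readings")) doses <- doses$doses[dwell, ]
  if (!n %in% VALID_SUBSETS)
    stop("n must be one of ", paste(VALID_SUBSETS, collapse = ", "),
         call. = FALSE)
  usable <- which(doses > 0)
  if (n > length(usable))
    stop("fewer than n detectors have usable (positive) dose", call. = FALSE)
  ord <- order(-doses, seq_along(doses))
  ord[seq_len(n)]
}

#' Initial source estimate by linearized multilateration
#'
#' Differences of squared-distance equations
#' `|x - p_i|^2 = r_i^2` yield a linear system in the source coordinates,
#' solved in least squares. For a coplanar detector array the out-of-plane
#' coordinate drops out of the linear system; it is recovered as the
#' median of `sqrt(r_i^2 - rho_i^2)` (lateral distances rho_i from the
#' in-plane solution) and the sign ambiguity is resolved to the +z
#' (patient) side of the plane. A rank-deficient system falls back to a
#' dose-weighted centroid with z from the smallest inferred distance; the
#' result then carries attribute `fallback = TRUE`.
#'
#' @param detector_positions n x 3 matrix of detector positions, mm
#'   (n >= 4, non-collinear).
#' @param distances Inferred source-detector distances, mm.
#' @param doses Optional dose weights for the centroid fallback.
#' @return Estimated position, mm 3-vector.
#' @export
initial_estimate <- function(detector_positions, distances, doses = NULL) {
  P <- as.matrix(detector_positions)
  r <- as.numeric(distances)
  if (nrow(P) < 4L) stop("need >= 4 detectors", call. = FALSE)
  if (nrow(P) != length(r)) stop("one distance per detector", call. = FALSE)
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
    stop("detectors are collinear", call. = FALSE)
  plane_z <- min(P[, 3])

  A <- 2 * sweep(P[-1, , drop = FALSE], 2, P[1, ])
  b <- (rowSums(P[-1, , drop = FALSE]^2) - sum(P[1, ]^2)) - (r[-1]^2 - r[1]^2)
  qa <- qr(A)
  if (qa$rank == 3L) {
    est <- as.numeric(qr.coef(qa, b))
    if (est[3] < plane_z) est[3] <- plane_z + abs(est[3] - plane_z)
    return(est)
  }
  A2 <- A[, 1:2, drop = FALSE]
  if (qr(A2)$rank == 2L) {
    xy <- as.numeric(qr.coef(qr(A2), b))
    rho2 <- (P[, 1] - xy[1])^2 + (P[, 2] - xy[2])^2
    h2 <- r^2 - rho2
    z <- if (any(h2 > 0)) plane_z + median(sqrt(h2[h2 > 0]))
         else plane_z + min(r)
    return(c(xy, z))
  }
  # degenerate geometry: dose-weighted (or inverse-square) centroid
  w <- if (!is.null(doses)) pmax(doses, 0) else 1 / r^2
  xy <- colSums(P[, 1:2, drop = FALSE] * w) / sum(w)
  structure(c(xy, plane_z + min(r)), fallback = TRUE)
}

localization_result <- function(position, n_detectors, iterations,
                                final_rms_residual, converged, detector_ids) {
  structure(list(position = as.numeric(position), n_detectors = n_detectors,
                 iterations = iterations,
                 final_rms_residual = final_rms_residual,
                 converged = converged, detector_ids = detector_ids),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("Source estimate: (%.3f, %.3f, %.3f) mm\n",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  %d detectors, %d iterations, RMS residual %.4f mm, %s\n",
              x$n_detectors, x$iterations, x$final_rms_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# weighted nonlinear least squares over the multilateration objective
solve_multilateration <- function(P, r, w, start, plane_z) {
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) sqrt(w) * (sqrt(colSums((p - t(P))^2)) - r),
    lower = c(-Inf, -Inf, plane_z + 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 100))
  as.numeric(fit$par)
}

# single-dwell localization loop
locate_single <- function(D, d10, array, source, n_detectors, max_iter, tol,
                          inverter) {
  sel <- select_top_n(D, n_detectors)
  P <- array$positions[sel, , drop = FALSE]
  Ds <- D[sel]
  plane_z <- array$plane_origin[3]

  alpha <- relative_dose(Ds, d10)
  r0 <- inverter(pmax(alpha, 1e-12))
  w <- ifelse(attr(r0, "clamped"), 0.1, 1)
  est <- as.numeric(initial_estimate(P, as.numeric(r0), doses = Ds))
  if (est[3] <= plane_z) est[3] <- plane_z + 1

  iterations <- 0L; converged <- FALSE
  r <- as.numeric(r0)
  for (k in seq_len(max_iter)) {
    ang <- ray_angles(est, P)
    rc <- pmin(pmax(ang$r, 1), 200)
    corr <- angular_dose_profile(rc, ang$theta, source) *
      angular_response_factor(array, ang$cos_inc)
    a <- pmax(Ds / corr, 1e-12) / d10
    ri <- inverter(a)
    r <- as.numeric(ri)
    w <- ifelse(attr(ri, "clamped"), 0.1, 1)
    new <- solve_multilateration(P, r, w, est, plane_z)
    delta <- sqrt(sum((new - est)^2))
    est <- new
    iterations <- k
    if (delta < tol) { converged <- TRUE; break }
  }
  res <- sqrt(colSums((est - t(P))^2)) - r
  localization_result(est, n_detectors, iterations,
                      sqrt(sum(w * res^2) / sum(w)), converged, sel)
}

#' Iterative source localization with angular-dependence correction
#'
#' The reconstruction loop: normalize the selected detectors' doses by
#' D_10, invert the transverse TG-43 curve to source-detector distances,
#' form an initial estimate by linearized multilateration, then iterate --
#' (1) from the current estimate compute each detector's polar angle and
#' incidence angle, (2) divide each dose by the angular dose profile
#' (geometry-function anisotropy x F(r,theta)) and the detector's
#' directional response, (3) re-invert the corrected relative doses and
#' re-solve the nonlinear least-squares multilateration -- until the
#' position update falls below `tol` or `max_iter` is reached. Detectors
#' whose relative dose falls outside the invertible range are clamped and
#' down-weighted (weight 0.1) rather than dropped.
#'
#' @param readings A [score_array()] `dose_readings` object, or a numeric
#'   dose vector for a single dwell.
#' @param source A [source_model()].
#' @param array A [build_magic_plate()] array (taken from `readings` when
#'   available).
#' @param n_detectors Detector subset size: 9, 25, 49, 81 or 121.
#' @param max_iter Maximum refinement iterations.
#' @param tol Convergence tolerance on the position update, mm.
#' @param d10 Calibration dose (taken from `readings` when available).
#' @param inverter Optional prebuilt [distance_inverter()].
#' @return For a dose vector: a `localization_result` (position,
#'   n_detectors, iterations, final RMS residual in mm, convergence flag,
#'   detector ids). For a `dose_readings` object: a list of one result per
#'   dwell, class `localization_set`.
#' @export
refine_position <- function(readings, source = source_model(), array = NULL,
                            n_detectors = 121, max_iter = 50, tol = 0.01,
                            d10 = NULL, inverter = NULL) {
  inv <- inverter %||% distance_inverter(source)
  if (inherits(readings, "dose_readings")) {
    array <- array %||% readings$array
    d10 <- d10 %||% readings$d10
    out <- lapply(seq_len(nrow(readings$doses)), function(i)
      locate_single(readings$doses[i, ], d10, array, source, n_detectors,
                    max_iter, tol, inv))
    class(out) <- "localization_set"
    return(out)
  }
  if (is.null(array) || is.null(d10))
    stop("array and d10 are required when readings is a plain dose vector",
         call. = FALSE)
  locate_single(as.numeric(readings), d10, array, source, n_detectors,
                max_iter, tol, inv)
}

#' @export
print.localization_set <- function(x, ...) {
  cat(sprintf("Localization results for %d dwells\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  dwell %2d: (%.2f, %.2f, %.2f) mm, %d iter%s\n", i,
                x[[i]]$position[1], x[[i]]$position[2], x[[i]]$position[3],
                x[[i]]$iterations, if (x[[i]]$converged) "" else " (!)"))
  invisible(x)
}

#' CT-density (WEPL) correction of a localization
#'
#' Uses the phantom density grid to undo the heterogeneity attenuation:
#' from the current position estimate, each detector's dose is multiplied
#' by `exp(+mu_eff * (wepl_i - d_geom_i) / 10)` and the localization is
#' re-run, for up to `outer_iter` outer rounds or until the estimate
#' stops moving. In a uniform water phantom the correction is the
#' identity. When the forward heterogeneity model and the correction share
#' the density grid, noiseless localizations are restored to the
#' homogeneous-case accuracy.
#'
#' @param readings Dose vector for one dwell, or a `dose_readings` object
#'   (all dwells corrected; pass `dwell` to pick one).
#' @param phantom The [voxel_phantom()] holding the CT density grid.
#' @param result The uncorrected [refine_position()] result to start from
#'   (`localization_result`, or list of them matching `readings`).
#' @param source,array,n_detectors,max_iter,tol,d10,inverter As in
#'   [refine_position()].
#' @param het [heterogeneity_model()] supplying mu_eff.
#' @param outer_iter Maximum outer correction rounds.
#' @param dwell Dwell row when `readings` is a `dose_readings` object and a
#'   single dwell is wanted.
#' @return Corrected `localization_result` (or `localization_set`).
#' @export
wepl_correct <- function(readings, phantom, result, source = source_model(),
                         array = NULL, n_detectors = 121, max_iter = 50,
                         tol = 0.01, d10 = NULL, het = heterogeneity_model(),
                         outer_iter = 5, inverter = NULL, dwell = NULL) {
  if (!inherits(phantom, "voxel_phantom"))
    stop("'phantom' must be a voxel_phantom", call. = FALSE)
  inv <- inverter %||% distance_inverter(source)
  if (inherits(readings, "dose_readings")) {
    array <- array %||% readings$array
    d10 <- d10 %||% readings$d10
    if (is.null(dwell)) {
      stopifnot(length(result) == nrow(readings$doses))
      out <- lapply(seq_len(nrow(readings$doses)), function(i)
        wepl_correct_single(readings$doses[i, ], phantom, result[[i]],
                            source, array, n_detectors, max_iter, tol, d10,
                            het, outer_iter, inv))
      class(out) <- "localization_set"
      return(out)
    }
    readings <- readings$doses[dwell, ]
    if (inherits(result, "localization_set")) result <- result[[dwell]]
  }
  if (is.null(array) || is.null(d10))
    stop("array and d10 are required when readings is a plain dose vector",
         call. = FALSE)
  wepl_correct_single(as.numeric(readings), phantom, result, source, array,
                      n_detectors, max_iter, tol, d10, het, outer_iter, inv)
}

wepl_correct_single <- function(D, phantom, result, source, array,
                                n_detectors, max_iter, tol, d10, het,
                                outer_iter, inverter) {
  est <- result$position
  res <- result
  for (j in seq_len(outer_iter)) {
    v <- sweep(array$positions, 2, est)
    d_geom <- sqrt(rowSums(v^2))
    w_i <- wepl(phantom, est, array$positions)
    Dcorr <- D * exp(het$mu_eff * (w_i - d_geom) / 10)
    res <- locate_single(Dcorr, d10, array, source, n_detectors, max_iter,
                         tol, inverter)
    if (sqrt(sum((res$position - est)^2)) < tol) { est <- res$position; break }
    est <- res$position
  }
  res
}

#' Localization errors against the planned dwell positions
#'
#' @param results A `localization_set` (or list of `localization_result`).
#' @param plan The `dwell_plan` holding the true positions.
#' @return data.frame with one row per dwell: estimated and true
#'   coordinates, signed per-axis errors `dx, dy, dz` (estimate minus
#'   truth), the 3D error `d3d`, iterations and convergence flag.
#' @export
localization_errors <- function(results, plan) {
  truth <- dwell_positions(plan)
  stopifnot(length(results) == nrow(truth))
  do.call(rbind, lapply(seq_along(results), function(i) {
    p <- results[[i]]$position
    e <- p - truth[i, ]
    data.frame(dwell = i, est_x = p[1], est_y = p[2], est_z = p[3],
               true_x = truth[i, 1], true_y = truth[i, 2],
               true_z = truth[i, 3],
               dx = e[1], dy = e[2], dz = e[3], d3d = sqrt(sum(e^2)),
               iterations = results[[i]]$iterations,
               converged = results[[i]]$converged)
  }))
}
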