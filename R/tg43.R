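# TG-43U1 analytic dose model for an Ir-192 line source.
#
# All user-facing lengths are in millimetres and angles in degrees; the
# geometry function works in centimetres internally and is returned in 1/cm^2.

#' Ir-192 line-source model
#'
#' Bundles the parameters of the TG-43 line-source dose model: the active
#' length used by the geometry function, the reference point
#' (r0 = 10 mm on the transverse axis, theta0 = 90 degrees) at which the
#' dose rate equals `strength_scale`, and the radial-dose / anisotropy
#' tables used by [dose_rate()]. Only dose ratios matter in this package,
#' so `strength_scale` is an arbitrary unit.
#'
#' @param active_length Active source length L in mm (default 3.5).
#' @param ref_radius Reference radius r0 in mm (TG-43 normalization point).
#' @param ref_angle Reference polar angle theta0 in degrees.
#' @param strength_scale Dose rate at the reference point, arbitrary units.
#' @param radial_table A [radial_dose_table()]; defaults to the bundled
#'   synthetic Ir-192-like table.
#' @param anisotropy_table An [anisotropy_table()]; defaults to the bundled
#'   synthetic table.
#' @return An object of class `source_model`.
#' @examples
#' src <- source_model()
#' dose_rate(10, 90, src)  # equals strength_scale
#' @export
source_model <- function(active_length = 3.5, ref_radius = 10, ref_angle = 90,
                         strength_scale = 1,
                         radial_table = default_radial_dose_table(),
                         anisotropy_table = default_anisotropy_table()) {
  stop_if_not_number(active_length, "active_length", positive = TRUE)
  stop_if_not_number(ref_radius, "ref_radius", positive = TRUE)
  stop_if_not_number(strength_scale, "strength_scale", positive = TRUE)
  if (ref_radius <= active_length / 2)
    stop("ref_radius must exceed active_length/2", call. = FALSE)
  structure(list(active_length = active_length, ref_radius = ref_radius,
                 ref_angle = ref_angle, strength_scale = strength_scale,
                 radial_table = radial_table,
                 anisotropy_table = anisotropy_table),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat("Ir-192 line-source model\n")
  cat(sprintf("  active length : %.2f mm\n", x$active_length))
  cat(sprintf("  reference     : r0 = %g mm, theta0 = %g deg\n",
              x$ref_radius, x$ref_angle))
  cat(sprintf("  strength scale: %g (arb.)\n", x$strength_scale))
  cat(sprintf("  g_L table     : %d knots over [%g, %g] mm (%s)\n",
              length(x$radial_table$radii), min(x$radial_table$radii),
              max(x$radial_table$radii), x$radial_table$method))
  cat(sprintf("  F table       : %d x %d grid\n",
              length(x$anisotropy_table$radii),
              length(x$anisotropy_table$angles)))
  invisible(x)
}

#' Line-source geometry function G_L(r, theta)
#'
#' The spatial falloff term of the TG-43 formalism for a line source of
#' active length `L`: `beta / (L * r * sin(theta))` off-axis, where `beta`
#' is the angle subtended by the active length at the field point, and
#' `1 / (r^2 - L^2/4)` on the long axis. Reduces to the point-source
#' inverse-square law `1/r^2` as `L -> 0` or `r >> L`.
#'
#' @param r Radial distance(s) from the source centre, mm.
#' @param theta Polar angle(s) from the source long axis, degrees in
#'   \[0, 180\].
#' @param L Active length, mm.
#' @return Geometry function value(s) in 1/cm^2.
#' @examples
#' geometry_function_line(10, 90)            # ~0.9900 cm^-2
#' geometry_function_line(1000, 37) * 100^2  # ~1: point-source limit r^2 * G -> 1
#' @export
geometry_function_line <- function(r, theta, L = 3.5) {
  stop_if_not_number(L, "L", positive = TRUE)
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n); theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive and finite", call. = FALSE)
  if (any(theta < 0 | theta > 180))
    stop("theta must lie in [0, 180] degrees", call. = FALSE)
  rc <- r / 10; Lc <- L / 10
  th <- theta * pi / 180
  s <- sin(th); z <- rc * cos(th)
  out <- numeric(n)
  on_axis <- s < 1e-12
  if (any(on_axis)) {
    if (any(rc[on_axis] <= Lc / 2))
      stop("on-axis field point inside the active segment (r <= L/2)",
           call. = FALSE)
    out[on_axis] <- 1 / (rc[on_axis]^2 - Lc^2 / 4)
  }
  if (any(!on_axis)) {
    d <- rc[!on_axis] * s[!on_axis]
    zz <- z[!on_axis]
    beta <- atan((zz + Lc / 2) / d) - atan((zz - Lc / 2) / d)
    out[!on_axis] <- beta / (Lc * d)
  }
  out
}

# ---------------------------------------------------------------------------
# Radial dose function g_L(r)

#' Radial dose function table and fitted model
#'
#' Builds the smooth radial dose function g_L(r) from a table of knots.
#' The fitted curve is renormalized so that g_L(10 mm) = 1 exactly (the
#' TG-43 normalization point). Two fitting modes are available: a
#' polynomial fit (TG-43 practice; default degree 5, reduced when fewer
#' knots are supplied) and a shape-preserving monotone cubic interpolant
#' through the knots.
#'
#' @param radii Knot radii in mm, strictly increasing.
#' @param values Dimensionless g values at the knots, all positive.
#' @param method `"poly"` or `"interp"`.
#' @param degree Polynomial degree for `method = "poly"`.
#' @return An object of class `radial_dose_table` with elements `radii`,
#'   `values`, `fit_coefficients` (polynomial mode only), `method`, and the
#'   evaluable function `fun`.
#' @export
radial_dose_table <- function(radii, values, method = c("poly", "interp"),
                              degree = 5) {
  method <- match.arg(method)
  if (length(radii) != length(values) || length(radii) < 2L)
    stop("radii and values must be equal-length vectors (>= 2 knots)",
         call. = FALSE)
  if (any(diff(radii) <= 0))
    stop("radii must be strictly increasing", call. = FALSE)
  if (any(values <= 0)) stop("g values must be positive", call. = FALSE)
  if (min(radii) > 10 || max(radii) < 10)
    stop("the table must bracket the 10 mm normalization point",
         call. = FALSE)
  craw <- NULL
  if (method == "poly") {
    deg <- min(degree, length(radii) - 1L)
    fit <- lm(values ~ poly(radii, deg, raw = TRUE))
    craw <- unname(stats::coef(fit))
    raw <- function(r) {
      acc <- rep(craw[1], length(r))
      for (k in seq_len(deg)) acc <- acc + craw[k + 1] * r^k
      acc
    }
  } else {
    raw <- splinefun(radii, values, method = "monoH.FC")
  }
  norm <- raw(10)
  fun <- function(r) raw(r) / norm
  coef <- if (is.null(craw)) NULL else craw / norm
  rng <- c(max(1, min(radii)), min(200, max(radii)))
  grid <- seq(rng[1], rng[2], length.out = 512L)
  if (any(fun(grid) <= 0))
    stop("fitted radial dose function is not positive over its domain",
         call. = FALSE)
  structure(list(radii = radii, values = values, fit_coefficients = coef,
                 method = method, domain = rng, fun = fun),
            class = "radial_dose_table")
}

#' Bundled synthetic radial dose table
#'
#' Loads the radial dose function table shipped with the package. The table
#' is a synthetic stand-in with the qualitative shape of published Ir-192
#' consensus data (near unity over 1--100 mm, slow falloff beyond); it is
#' not a published dataset. Substitute consensus values via
#' [read_radial_dose_table()].
#'
#' @param method Fit mode passed to [radial_dose_table()].
#' @return A `radial_dose_table`.
#' @export
default_radial_dose_table <- function(method = "poly") {
  read_radial_dose_table(system.file("extdata", "radial_dose_synthetic.txt",
                                     package = "mplocate", mustWork = TRUE),
                         method = method)
}

#' Read a radial dose table from a two-column text file
#'
#' Expects whitespace-separated columns `r_mm g`; lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @inheritParams radial_dose_table
#' @return A `radial_dose_table`.
#' @export
read_radial_dose_table <- function(path, method = "poly") {
  tab <- read.table(path, comment.char = "#", col.names = c("r", "g"))
  radial_dose_table(tab$r, tab$g, method = method)
}

#' Evaluate the radial dose function g_L(r)
#'
#' @param r Radial distance(s) in mm; must lie inside the table's domain
#'   (at most \[1, 200\] mm). Extrapolation is refused.
#' @param table A [radial_dose_table()].
#' @return Dimensionless g_L(r), exactly 1 at r = 10 mm.
#' @export
radial_dose_function <- function(r, table = default_radial_dose_table()) {
  if (!inherits(table, "radial_dose_table"))
    stop("'table' must be a radial_dose_table", call. = FALSE)
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r < table$domain[1] - 1e-9) ||
      any(r > table$domain[2] + 1e-9))
    stop(sprintf("r outside the table domain [%g, %g] mm; extrapolation refused",
                 table$domain[1], table$domain[2]), call. = FALSE)
  table$fun(r)
}

# ---------------------------------------------------------------------------
# 2D anisotropy function F(r, theta)

#' 2D anisotropy table
#'
#' Stores F(r, theta) on a rectangular (radius x polar angle) grid,
#' renormalized row-wise so that F(r, 90 deg) = 1 exactly for every
#' tabulated radius. Evaluation is by bilinear interpolation.
#'
#' @param radii Grid radii in mm, strictly increasing.
#' @param angles Grid polar angles in degrees over \[0, 180\], strictly
#'   increasing and bracketing 90.
#' @param values Matrix of F values, `length(radii)` rows by
#'   `length(angles)` columns, all positive.
#' @return An object of class `anisotropy_table`.
#' @export
anisotropy_table <- function(radii, angles, values) {
  values <- as.matrix(values)
  if (any(diff(radii) <= 0) || any(diff(angles) <= 0))
    stop("radii and angles must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(radii) || ncol(values) != length(angles))
    stop("values must be a length(radii) x length(angles) matrix",
         call. = FALSE)
  if (any(values <= 0)) stop("F values must be positive", call. = FALSE)
  if (min(angles) > 90 || max(angles) < 90)
    stop("angle grid must bracket the 90 degree normalization angle",
         call. = FALSE)
  # exact normalization at theta = 90 for every radius
  at90 <- vapply(seq_along(radii), function(i)
    approx(angles, values[i, ], xout = 90)$y, numeric(1))
  values <- values / at90
  structure(list(radii = radii, angles = angles, values = values),
            class = "anisotropy_table")
}

#' Bundled synthetic anisotropy table
#'
#' Synthetic stand-in for a published Ir-192 anisotropy dataset: unity on
#' the transverse axis with a smooth dip toward the source long axis.
#'
#' @return An `anisotropy_table`.
#' @export
default_anisotropy_table <- function() {
  read_anisotropy_table(system.file("extdata", "anisotropy_synthetic.txt",
                                    package = "mplocate", mustWork = TRUE))
}

#' Read an anisotropy table from a three-column text file
#'
#' Expects whitespace-separated columns `r_mm theta_deg F`, one grid point
#' per line covering a full rectangular grid; `#` lines are comments.
#'
#' @param path File path.
#' @return An `anisotropy_table`.
#' @export
read_anisotropy_table <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("r", "theta", "F"))
  radii <- sort(unique(tab$r)); angles <- sort(unique(tab$theta))
  vals <- matrix(NA_real_, length(radii), length(angles))
  vals[cbind(match(tab$r, radii), match(tab$theta, angles))] <- tab$F
  if (anyNA(vals)) stop("file does not cover a full r x theta grid",
                        call. = FALSE)
  anisotropy_table(radii, angles, vals)
}

#' Evaluate the anisotropy function F(r, theta)
#'
#' Bilinear interpolation on the table grid; out-of-range queries are a
#' domain error.
#'
#' @param r Radial distance(s), mm.
#' @param theta Polar angle(s) from the source long axis, degrees.
#' @param table An [anisotropy_table()].
#' @return Dimensionless F(r, theta), exactly 1 at theta = 90.
#' @export
anisotropy_function <- function(r, theta, table = default_anisotropy_table()) {
  if (!inherits(table, "anisotropy_table"))
    stop("'table' must be an anisotropy_table", call. = FALSE)
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n); theta <- rep_len(as.numeric(theta), n)
  eps <- 1e-9
  if (any(r < min(table$radii) - eps) || any(r > max(table$radii) + eps) ||
      any(theta < min(table$angles) - eps) ||
      any(theta > max(table$angles) + eps))
    stop("(r, theta) outside the anisotropy table range", call. = FALSE)
  r <- pmin(pmax(r, min(table$radii)), max(table$radii))
  theta <- pmin(pmax(theta, min(table$angles)), max(table$angles))
  pracma::interp2(x = table$angles, y = table$radii, Z = table$values,
                  xp = theta, yp = r, method = "linear")
}

# ---------------------------------------------------------------------------
# Assembled dose rate and the transverse inversion curve

#' TG-43 relative dose rate
#'
#' The assembled line-source dose rate
#' `strength_scale * [G_L(r,theta)/G_L(r0,theta0)] * g_L(r) * F(r,theta)`,
#' normalized so the value at the reference point (10 mm, 90 deg) equals
#' `strength_scale`.
#'
#' @param r Radial distance(s), mm.
#' @param theta Polar angle(s), degrees.
#' @param source A [source_model()].
#' @return Relative dose rate(s), arbitrary units.
#' @export
dose_rate <- function(r, theta, source = source_model()) {
  g_ref <- geometry_function_line(source$ref_radius, source$ref_angle,
                                  source$active_length)
  source$strength_scale *
    geometry_function_line(r, theta, source$active_length) / g_ref *
    radial_dose_function(r, source$radial_table) *
    anisotropy_function(r, theta, source$anisotropy_table)
}

#' Transverse-axis dose ratio alpha(r)
#'
#' The forward curve used for dose-to-distance inversion:
#' `dose_rate(r, 90) / dose_rate(10, 90)`, i.e. the dose at distance `r`
#' on the source's transverse axis relative to the 10 mm calibration
#' point. Strictly decreasing in `r` over the model domain.
#'
#' @param r Radial distance(s), mm.
#' @param source A [source_model()].
#' @return Dimensionless ratio(s), equal to 1 at r = 10 mm.
#' @export
transverse_dose_ratio <- function(r, source = source_model()) {
  # F(r, 90) = 1 exactly by table normalization, so it is omitted
  g_ref <- geometry_function_line(source$ref_radius, 90, source$active_length)
  geometry_function_line(r, 90, source$active_length) / g_ref *
    radial_dose_function(r, source$radial_table)
}

#' Angular dose profile relative to the transverse axis
#'
#' `dose_rate(r, theta) / dose_rate(r, 90)` =
#' `[G_L(r,theta)/G_L(r,90)] * F(r,theta)`. This is the factor by which a
#' detector off the transverse plane reads high or low relative to the
#' transverse inversion curve, and is what the localization loop divides
#' out of each reading.
#'
#' @inheritParams dose_rate
#' @return Dimensionless factor(s), 1 at theta = 90.
#' @export
angular_dose_profile <- function(r, theta, source = source_model()) {
  geometry_function_line(r, theta, source$active_length) /
    geometry_function_line(r, 90, source$active_length) *
    anisotropy_function(r, theta, source$anisotropy_table)
}

#' Build a fast inverse of the transverse dose ratio
#'
#' Precomputes the strictly monotone forward curve on a fine grid, builds a
#' monotone-cubic inverse interpolant in log(alpha), and sharpens each query
#' with safeguarded Newton iterations, giving round-trip accuracy well below
#' 1e-6 mm. Queries outside the attainable ratio range are clamped to the
#' nearest domain bound and flagged.
#'
#' @param source A [source_model()].
#' @param r_range Invertible distance range, mm (default \[1, 200\]).
#' @param grid_step Forward-curve tabulation step, mm.
#' @param newton_iter Number of Newton refinement sweeps.
#' @return A function `f(alpha)` returning distances in mm with a logical
#'   attribute `"clamped"`.
#' @export
distance_inverter <- function(source = source_model(), r_range = c(1, 200),
                              grid_step = 0.05, newton_iter = 4L) {
  rg <- seq(r_range[1], r_range[2], by = grid_step)
  ag <- transverse_dose_ratio(rg, source)
  if (any(diff(ag) >= 0))
    stop("transverse dose ratio is not strictly decreasing on r_range",
         call. = FALSE)
  guess <- splinefun(rev(log(ag)), rev(rg), method = "monoH.FC")
  a_max <- ag[1]; a_min <- ag[length(ag)]
  h <- 1e-4
  function(alpha) {
    if (any(!is.finite(alpha)) || any(alpha <= 0))
      stop("alpha must be positive and finite", call. = FALSE)
    clamped <- alpha > a_max | alpha < a_min
    a <- pmin(pmax(alpha, a_min), a_max)
    r <- guess(log(a))
    for (k in seq_len(newton_iter)) {
      lo <- pmax(r - h, r_range[1]); hi <- pmin(r + h, r_range[2])
      f <- transverse_dose_ratio(r, source) - a
      fp <- (transverse_dose_ratio(hi, source) -
             transverse_dose_ratio(lo, source)) / (hi - lo)
      r <- pmin(pmax(r - f / fp, r_range[1]), r_range[2])
    }
    structure(r, clamped = clamped)
  }
}

#' Invert a relative dose to a source-detector distance
#'
#' Solves `transverse_dose_ratio(r) = alpha` for `r` on \[1, 200\] mm.
#' Ratios outside the attainable range are clamped to the nearest bound and
#' flagged via the `"clamped"` attribute (used detectors with clamped
#' distances are down-weighted, not dropped, by the localization loop).
#'
#' @param alpha Relative dose(s) D_i / D_10, positive.
#' @param source A [source_model()].
#' @param inverter Optional prebuilt [distance_inverter()] (reuse it when
#'   inverting many readings against the same source model).
#' @return Distance(s) in mm with attribute `"clamped"`.
#' @examples
#' invert_distance(1)                  # 10 mm, the calibration point
#' invert_distance(c(0.5, 0.1, 0.01))
#' @export
invert_distance <- function(alpha, source = source_model(), inverter = NULL) {
  (inverter %||% distance_inverter(source))(alpha)
}
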