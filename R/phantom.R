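# Synthetic study geometry: voxel density phantoms and the CT-number
# calibration used to label them.
#
# Coordinate convention (right-handed): x = patient left-right,
# y = superior-inferior (catheter direction), z = anterior-posterior with the
# detector plane at low z. The origin is the corner diode of the array.

WATER_DENSITY <- 0.998  # g/cm^3, liquid water at 22 C

#' CT-number calibration curve
#'
#' Piecewise-linear HU-to-mass-density calibration. The default anchors are
#' a standard-shaped CT calibration (air at -1000 HU, water at 0 HU, dense
#' bone beyond +1000 HU); scanner-specific curves can be supplied as a
#' two-column matrix of (HU, density) control points.
#'
#' @param control_points Two-column matrix or data.frame of (HU, density
#'   g/cm^3) pairs with HU strictly increasing and density non-decreasing.
#' @return An object of class `hu_curve`.
#' @export
hu_curve <- function(control_points = default_hu_anchors()) {
  cp <- as.matrix(control_points)
  if (ncol(cp) != 2L || nrow(cp) < 2L)
    stop("control_points must have >= 2 rows of (HU, density)", call. = FALSE)
  if (any(diff(cp[, 1]) <= 0))
    stop("HU values must be strictly increasing", call. = FALSE)
  if (any(diff(cp[, 2]) < 0))
    stop("density must be non-decreasing in HU", call. = FALSE)
  structure(list(hu = cp[, 1], density = cp[, 2]), class = "hu_curve")
}

default_hu_anchors <- function() {
  cbind(hu = c(-1000, -100, 0, 1000, 2000),
        density = c(0.00121, 0.93, 1.000, 1.59, 2.2))
}

#' Convert CT numbers to mass density
#'
#' Linear interpolation between the curve's control points, clamped to the
#' end densities outside the tabulated HU range.
#'
#' @param hu CT number(s), HU.
#' @param curve An [hu_curve()].
#' @return Mass density in g/cm^3.
#' @examples
#' hu_to_density(c(-1000, 0, 500))
#' @export
hu_to_density <- function(hu, curve = hu_curve()) {
  if (!inherits(curve, "hu_curve")) stop("'curve' must be an hu_curve",
                                         call. = FALSE)
  approx(curve$hu, curve$density, xout = hu, rule = 2)$y
}

#' Density-to-material look-up table
#'
#' Contiguous half-open density bins `[low, high)` covering `[0, Inf)`,
#' mapping mass density to a tissue label. The default bins follow the
#' TG-186-style tissue set (air, lung, adipose, soft tissue, cartilage,
#' bone); a density on a bin boundary belongs to the upper bin. Materials
#' only label voxels in this package -- attenuation uses density alone.
#'
#' @param breaks Increasing interior bin boundaries in g/cm^3 (the first
#'   bin starts at 0, the last extends to Inf).
#' @param labels One more label than `breaks`, from
#'   air/lung/adipose/soft_tissue/cartilage/bone/carbon.
#' @return An object of class `material_lut`.
#' @export
material_lut <- function(breaks = c(0.05, 0.6, 0.97, 1.1, 1.35),
                         labels = c("air", "lung", "adipose", "soft_tissue",
                                    "cartilage", "bone")) {
  if (length(labels) != length(breaks) + 1L)
    stop("need exactly one more label than breaks", call. = FALSE)
  if (any(diff(breaks) <= 0) || any(breaks <= 0))
    stop("breaks must be positive and strictly increasing", call. = FALSE)
  known <- c("air", "lung", "adipose", "soft_tissue", "cartilage", "bone",
             "carbon")
  if (any(!labels %in% known))
    stop("labels must be drawn from: ", paste(known, collapse = ", "),
         call. = FALSE)
  structure(list(breaks = breaks, labels = labels), class = "material_lut")
}

#' Map mass density to a material label
#'
#' @param rho Density value(s), g/cm^3, non-negative.
#' @param lut A [material_lut()].
#' @return Character vector of material labels.
#' @examples
#' density_to_material(c(0.0012, 1.0, 1.85))
#' @export
density_to_material <- function(rho, lut = material_lut()) {
  if (!inherits(lut, "material_lut")) stop("'lut' must be a material_lut",
                                           call. = FALSE)
  if (any(rho < 0)) stop("density must be >= 0", call. = FALSE)
  # findInterval with half-open [low, high) bins: boundary -> upper bin
  lut$labels[findInterval(rho, lut$breaks) + 1L]
}

# ---------------------------------------------------------------------------
# Voxel phantoms

#' Voxel phantom container
#'
#' A regular 3D mass-density grid with an origin (position of the corner of
#' voxel \[1,1,1\]), isotropic or anisotropic spacing, and a parallel
#' material-label grid.
#'
#' @param density 3D numeric array of densities, g/cm^3, all >= 0.
#' @param origin Grid corner position, mm (3-vector).
#' @param spacing Voxel edge length(s), mm; scalar or 3-vector.
#' @param material Optional 3D character array of labels; derived from
#'   `density` via `lut` when omitted.
#' @param lut [material_lut()] used when deriving labels.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(density, origin = c(0, 0, 0), spacing = 3,
                          material = NULL, lut = material_lut()) {
  if (!is.array(density) || length(dim(density)) != 3L)
    stop("density must be a 3D array", call. = FALSE)
  if (any(density < 0)) stop("density must be >= 0 everywhere", call. = FALSE)
  stop_if_not_point(origin, "origin")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (is.null(material)) {
    material <- array(density_to_material(density, lut), dim = dim(density))
  } else if (!identical(dim(material), dim(density))) {
    stop("material grid shape must match density grid", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = dim(density), density = density,
                 material = material),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("Voxel phantom: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin  : (%g, %g, %g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density : %.4g - %.4g g/cm^3\n",
              min(x$density), max(x$density)))
  tb <- sort(table(x$material), decreasing = TRUE)
  cat("  material:", paste(sprintf("%s (%d)", names(tb), tb),
                           collapse = ", "), "\n")
  invisible(x)
}

# voxel centre coordinates along one axis
axis_centres <- function(phantom, k) {
  phantom$origin[k] + (seq_len(phantom$shape[k]) - 0.5) * phantom$spacing[k]
}

#' Uniform water phantom
#'
#' All voxels at liquid-water density (0.998 g/cm^3).
#'
#' @param shape Voxel counts, 3 positive integers.
#' @param spacing Voxel edge length(s), mm.
#' @param origin Grid corner, mm.
#' @return A `voxel_phantom`.
#' @export
make_water_phantom <- function(shape = c(48, 48, 40), spacing = 3,
                               origin = c(-20, -20, -12)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0))
    stop("shape must be 3 positive integers", call. = FALSE)
  voxel_phantom(array(WATER_DENSITY, dim = shape), origin = origin,
                spacing = spacing)
}

#' Override every voxel to water density
#'
#' The water-override experiment: keeps the grid geometry of a
#' (heterogeneous) phantom but forces every voxel to 0.998 g/cm^3,
#' isolating the effect of inhomogeneities on localization.
#'
#' @param phantom A `voxel_phantom`.
#' @return A uniform-water `voxel_phantom` on the same grid.
#' @export
override_to_water <- function(phantom) {
  if (!inherits(phantom, "voxel_phantom"))
    stop("'phantom' must be a voxel_phantom", call. = FALSE)
  voxel_phantom(array(WATER_DENSITY, dim = phantom$shape),
                origin = phantom$origin, spacing = phantom$spacing)
}

#' Parameters of the synthetic pelvic phantom
#'
#' Geometry of the heterogeneous stand-in for a male pelvis CT resting on a
#' carbon-fibre couch: an elliptical soft-tissue body (cross-section in the
#' x-z plane, extruded along y) with seeded density jitter, two bone
#' ellipsoids at the lateral extremes (femoral-head-like), an optional gas
#' pocket (rectum-like), air elsewhere, and a carbon couch slab whose
#' anterior surface sits 5 mm above the detector plane.
#'
#' @param body_centre,body_semiaxes Body ellipse centre and semi-axes in the
#'   x-z plane, mm.
#' @param soft_tissue_range Soft-tissue density range for the seeded
#'   uniform jitter, g/cm^3.
#' @param bone_centres List of bone ellipsoid centres (mm, 3-vectors); use
#'   `list()` for none.
#' @param bone_semiaxes,bone_density Bone ellipsoid semi-axes (mm) and
#'   density (g/cm^3).
#' @param gas_centre Gas pocket centre (mm) or `NULL` for none.
#' @param gas_semiaxes,gas_density Gas pocket semi-axes and density.
#' @param couch_top_z Anterior couch surface height above the detector
#'   plane, mm.
#' @param couch_thickness,couch_density Couch slab thickness (mm; clipped
#'   to the grid) and carbon density (g/cm^3).
#' @param air_density Density outside the body, g/cm^3.
#' @return A parameter list for [make_pelvic_phantom()].
#' @export
pelvic_params <- function(body_centre = c(50, 52),
                          body_semiaxes = c(70, 48),
                          soft_tissue_range = c(1.00, 1.06),
                          bone_centres = list(c(8, 50, 40), c(92, 50, 40)),
                          bone_semiaxes = c(13, 20, 13),
                          bone_density = 1.85,
                          gas_centre = c(38, 50, 18),
                          gas_semiaxes = c(10, 12, 7),
                          gas_density = 0.0012,
                          couch_top_z = 5, couch_thickness = 120,
                          couch_density = 1.7, air_density = 0.0012) {
  list(body_centre = body_centre, body_semiaxes = body_semiaxes,
       soft_tissue_range = soft_tissue_range, bone_centres = bone_centres,
       bone_semiaxes = bone_semiaxes, bone_density = bone_density,
       gas_centre = gas_centre, gas_semiaxes = gas_semiaxes,
       gas_density = gas_density, couch_top_z = couch_top_z,
       couch_thickness = couch_thickness, couch_density = couch_density,
       air_density = air_density)
}

#' Synthetic heterogeneous pelvic phantom
#'
#' Builds the heterogeneous voxel phantom described by [pelvic_params()]
#' on a regular grid. Deterministic given `seed` (the seed drives only the
#' soft-tissue density jitter). Bone and gas structures must lie inside
#' the grid; the couch slab is clipped to it.
#'
#' @inheritParams make_water_phantom
#' @param seed Integer seed for the soft-tissue jitter.
#' @param params A [pelvic_params()] list.
#' @param lut [material_lut()] used to label voxels (couch voxels are
#'   relabelled `carbon`).
#' @return A `voxel_phantom`.
#' @export
make_pelvic_phantom <- function(shape = c(48, 48, 40), spacing = 3,
                                origin = c(-20, -20, -12), seed = 1,
                                params = pelvic_params(),
                                lut = material_lut()) {
  ph <- make_water_phantom(shape, spacing, origin)
  xs <- axis_centres(ph, 1); ys <- axis_centres(ph, 2); zs <- axis_centres(ph, 3)
  hi <- ph$origin + ph$shape * ph$spacing
  inside_grid <- function(centre, semi) {
    all(centre - semi >= ph$origin) && all(centre + semi <= hi)
  }
  for (bc in params$bone_centres)
    if (!inside_grid(bc, params$bone_semiaxes))
      stop("bone ellipsoid extends outside the phantom grid", call. = FALSE)
  if (!is.null(params$gas_centre) &&
      !inside_grid(params$gas_centre, params$gas_semiaxes))
    stop("gas pocket extends outside the phantom grid", call. = FALSE)

  nx <- ph$shape[1]; ny <- ph$shape[2]; nz <- ph$shape[3]
  X <- array(xs, dim = ph$shape)
  Y <- array(rep(ys, each = nx), dim = ph$shape)
  Z <- array(rep(zs, each = nx * ny), dim = ph$shape)

  set.seed(seed)
  body <- ((X - params$body_centre[1]) / params$body_semiaxes[1])^2 +
          ((Z - params$body_centre[2]) / params$body_semiaxes[2])^2 <= 1
  dens <- array(params$air_density, dim = ph$shape)
  dens[body] <- runif(sum(body), params$soft_tissue_range[1],
                      params$soft_tissue_range[2])
  for (bc in params$bone_centres) {
    inb <- ((X - bc[1]) / params$bone_semiaxes[1])^2 +
           ((Y - bc[2]) / params$bone_semiaxes[2])^2 +
           ((Z - bc[3]) / params$bone_semiaxes[3])^2 <= 1
    dens[inb] <- params$bone_density
  }
  if (!is.null(params$gas_centre)) {
    gc <- params$gas_centre
    ing <- ((X - gc[1]) / params$gas_semiaxes[1])^2 +
           ((Y - gc[2]) / params$gas_semiaxes[2])^2 +
           ((Z - gc[3]) / params$gas_semiaxes[3])^2 <= 1
    dens[ing] <- params$gas_density
  }
  couch <- Z <= params$couch_top_z &
           Z >= params$couch_top_z - params$couch_thickness
  dens[couch] <- params$couch_density
  out <- voxel_phantom(dens, origin = ph$origin, spacing = ph$spacing,
                       lut = lut)
  out$material[couch] <- "carbon"
  out
}

# ---------------------------------------------------------------------------
# Plain-text phantom I/O: one JSON header line, then the density grid and the
# material-code grid (x fastest, then y, then z), one x-row per line.

#' Write a voxel phantom to a plain-text file
#'
#' Format: a `#voxel-phantom v1` marker line, a JSON header (origin,
#' spacing, shape, material legend, value order), the density grid at full
#' precision and the material-code grid, x varying fastest.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  if (!inherits(phantom, "voxel_phantom"))
    stop("'phantom' must be a voxel_phantom", call. = FALSE)
  legend <- sort(unique(as.vector(phantom$material)))
  header <- jsonlite::toJSON(list(origin = phantom$origin,
                                  spacing = phantom$spacing,
                                  shape = phantom$shape,
                                  materials = legend,
                                  order = "x-fastest"),
                             auto_unbox = FALSE, digits = NA)
  nx <- phantom$shape[1]
  dlines <- apply(matrix(sprintf("%.17g", phantom$density), nrow = nx), 2,
                  paste, collapse = " ")
  codes <- match(phantom$material, legend)
  mlines <- apply(matrix(codes, nrow = nx), 2, paste, collapse = " ")
  writeLines(c("#voxel-phantom v1", as.character(header), dlines, mlines),
             path)
  invisible(path)
}

#' Read a voxel phantom written by [write_phantom()]
#'
#' @param path File path.
#' @return A `voxel_phantom`.
#' @export
read_phantom <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#voxel-phantom v1")
    stop("not a voxel-phantom v1 file", call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[2])
  shape <- as.integer(hdr$shape)
  nrow_grid <- shape[2] * shape[3]
  body <- lines[-(1:2)]
  if (length(body) != 2L * nrow_grid)
    stop("unexpected number of grid rows", call. = FALSE)
  dens <- array(as.numeric(unlist(strsplit(body[seq_len(nrow_grid)], " ",
                                           fixed = TRUE))), dim = shape)
  codes <- array(as.integer(unlist(strsplit(body[nrow_grid + seq_len(nrow_grid)],
                                            " ", fixed = TRUE))), dim = shape)
  mat <- array(hdr$materials[codes], dim = shape)
  voxel_phantom(dens, origin = as.numeric(hdr$origin),
                spacing = as.numeric(hdr$spacing), material = mat)
}
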