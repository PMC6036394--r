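# Dwell-plan generation: clinically-shaped stand-in for a TPS plan export.

#' Generate an HDR dwell plan
#'
#' Emulates the dwell positions of a prostate HDR plan: catheters run
#' along y (superior-inferior) and are placed at the corners of the
#' requested lateral (x) and height (z, above the detector plane) extents,
#' so consecutive dwells within a catheter are exactly `step` apart. The
#' default 4 catheters x 3 dwells at a 3 mm step gives the 12 positions
#' spanning the minimum and maximum clinically plausible source-to-array
#' distances.
#'
#' @param n_catheters Number of catheters (1--4; 1 is placed at the extent
#'   centre, 2 at opposite corners).
#' @param n_dwells Consecutive dwells per catheter.
#' @param step Dwell step along the catheter, mm.
#' @param lateral_extent Range of catheter x positions, mm.
#' @param height_range Range of catheter z positions above the detector
#'   plane, mm.
#' @param y_centre Centre of the dwell run along y, mm.
#' @param jitter_sd Optional seeded Gaussian jitter of catheter (x, z)
#'   positions, mm (0 = none).
#' @param seed Seed for the jitter (ignored when `jitter_sd = 0`).
#' @return A `dwell_plan`: data.frame with columns `catheter`, `index`,
#'   `x_mm`, `y_mm`, `z_mm` and attribute `step`.
#' @examples
#' plan <- make_dwell_plan()
#' nrow(plan)  # 12
#' @export
make_dwell_plan <- function(n_catheters = 4, n_dwells = 3, step = 3,
                            lateral_extent = c(30, 70),
                            height_range = c(30, 60),
                            y_centre = 50, jitter_sd = 0, seed = NULL) {
  if (diff(lateral_extent) < 0 || diff(height_range) < 0)
    stop("extents must be non-decreasing ranges", call. = FALSE)
  stop_if_not_number(step, "step", positive = TRUE)
  if (!n_catheters %in% 1:4)
    stop("n_catheters must be between 1 and 4", call. = FALSE)
  corners <- rbind(c(lateral_extent[1], height_range[1]),
                   c(lateral_extent[2], height_range[2]),
                   c(lateral_extent[1], height_range[2]),
                   c(lateral_extent[2], height_range[1]))
  xz <- if (n_catheters == 1)
    rbind(c(mean(lateral_extent), mean(height_range)))
  else corners[seq_len(n_catheters), , drop = FALSE]
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    xz <- xz + matrix(rnorm(length(xz), sd = jitter_sd), ncol = 2)
  }
  ys <- y_centre + (seq_len(n_dwells) - (n_dwells + 1) / 2) * step
  plan <- do.call(rbind, lapply(seq_len(nrow(xz)), function(ci) {
    data.frame(catheter = ci, index = seq_len(n_dwells),
               x_mm = xz[ci, 1], y_mm = ys, z_mm = xz[ci, 2])
  }))
  structure(plan, step = step, class = c("dwell_plan", "data.frame"))
}

#' Dwell positions as a matrix
#'
#' @param plan A `dwell_plan`.
#' @return Numeric n x 3 matrix of (x, y, z) in mm.
#' @export
dwell_positions <- function(plan) {
  as.matrix(plan[, c("x_mm", "y_mm", "z_mm")])
}

#' Write / read a dwell plan as CSV
#'
#' Columns `catheter,index,x_mm,y_mm,z_mm`; the step size is recovered from
#' consecutive dwell spacing on read.
#'
#' @param plan A `dwell_plan`.
#' @param path File path.
#' @return `path` invisibly (write); a `dwell_plan` (read).
#' @export
write_dwell_plan <- function(plan, path) {
  write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwell_plan
#' @export
read_dwell_plan <- function(path) {
  df <- read.csv(path)
  need <- c("catheter", "index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("dwell plan CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  step <- NA_real_
  for (ci in unique(df$catheter)) {
    d <- diff(df$y_mm[df$catheter == ci])
    if (length(d)) step <- abs(d[1])
  }
  structure(df, step = step, class = c("dwell_plan", "data.frame"))
}
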