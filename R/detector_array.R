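# Virtual 2D diode array ("Magic Plate" style).

#' Build the 11 x 11 diode array
#'
#' A planar square grid of 121 epitaxial-diode positions at a regular
#' pitch, lying in a z = const plane with its normal along +z (toward the
#' patient). The corner diode sits at `plane_origin`, which is also the
#' study's coordinate origin. The 10 mm pitch is adopted from the array's
#' design literature and is configurable.
#'
#' @param pitch Diode spacing, mm.
#' @param plane_origin Position of the corner diode, mm.
#' @param angular_response Detector directional response model:
#'   `list(model = "unity")` (ideal, default) or
#'   `list(model = "cospower", p = ...)` for a cos^p falloff with the
#'   incidence angle from the array normal.
#' @param n_rows,n_cols Grid dimensions (11 x 11 for the Magic Plate).
#' @return An object of class `detector_array` with a 121 x 3 `positions`
#'   matrix (row-major detector ids: id = (row - 1) * n_cols + col).
#' @examples
#' mp <- build_magic_plate()
#' nrow(mp$positions)  # 121
#' @export
build_magic_plate <- function(pitch = 10, plane_origin = c(0, 0, 0),
                              angular_response = list(model = "unity"),
                              n_rows = 11, n_cols = 11) {
  stop_if_not_number(pitch, "pitch", positive = TRUE)
  stop_if_not_point(plane_origin, "plane_origin")
  if (!angular_response$model %in% c("unity", "cospower"))
    stop("angular_response model must be 'unity' or 'cospower'",
         call. = FALSE)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  pos <- cbind(plane_origin[1] + (grid$col - 1) * pitch,
               plane_origin[2] + (grid$row - 1) * pitch,
               plane_origin[3])
  colnames(pos) <- c("x", "y", "z")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 plane_origin = as.numeric(plane_origin),
                 normal = c(0, 0, 1),
                 angular_response = angular_response,
                 positions = pos),
            class = "detector_array")
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf("Diode array: %d x %d detectors, %g mm pitch\n",
              x$n_rows, x$n_cols, x$pitch))
  cat(sprintf("  corner diode at (%g, %g, %g) mm, normal +z\n",
              x$plane_origin[1], x$plane_origin[2], x$plane_origin[3]))
  cat(sprintf("  angular response: %s\n", x$angular_response$model))
  invisible(x)
}

#' Detector directional response factor
#'
#' @param array A `detector_array`.
#' @param cos_incidence |cosine| of the ray's incidence angle from the
#'   array normal.
#' @return Multiplicative response factor(s); 1 for the unity model.
#' @export
angular_response_factor <- function(array, cos_incidence) {
  switch(array$angular_response$model,
         unity = rep(1, length(cos_incidence)),
         cospower = pmax(abs(cos_incidence), 1e-6)^array$angular_response$p)
}
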