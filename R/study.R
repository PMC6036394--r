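# Study driver: runs the heterogeneous and water-override experiments over
# repeats and detector-subset sizes and aggregates per-axis error statistics.

#' Study configuration
#'
#' Bundles everything [run_study()] needs. The defaults reproduce the
#' study conditions: the 12-dwell plan (4 catheters x 3 dwells at a 3 mm
#' step), 1 percent multiplicative dose noise, 20 repeats per dwell,
#' detector subsets of 9/25/49/81/121, and both the heterogeneous pelvic
#' phantom and its water override.
#'
#' @param seed Master seed; the study is deterministic given it.
#' @param noise_sigma Relative dose noise SD (k = 1).
#' @param n_repeats Noise realizations per dwell (>= 1).
#' @param detector_counts Subset sizes, drawn from 9/25/49/81/121.
#' @param phantoms Which experiments to run: subset of
#'   `c("pelvic", "water")` (`"water"` is the water-override of the pelvic
#'   grid).
#' @param correction Apply the CT-density ([wepl_correct()]) stage.
#' @param plan A [make_dwell_plan()] plan.
#' @param phantom Optional prebuilt heterogeneous phantom (defaults to
#'   [make_pelvic_phantom()] seeded by `seed`).
#' @param array A [build_magic_plate()] array.
#' @param source A [source_model()].
#' @param het A [heterogeneity_model()].
#' @param max_iter,tol Localization loop controls.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, noise_sigma = 0.01, n_repeats = 20,
                         detector_counts = c(9, 25, 49, 81, 121),
                         phantoms = c("pelvic", "water"),
                         correction = FALSE,
                         plan = make_dwell_plan(), phantom = NULL,
                         array = build_magic_plate(),
                         source = source_model(),
                         het = heterogeneity_model(),
                         max_iter = 50, tol = 0.01) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (!all(detector_counts %in% VALID_SUBSETS))
    stop("detector_counts must be drawn from ",
         paste(VALID_SUBSETS, collapse = ", "), call. = FALSE)
  phantoms <- match.arg(phantoms, c("pelvic", "water"), several.ok = TRUE)
  structure(list(seed = seed, noise_sigma = noise_sigma,
                 n_repeats = n_repeats, detector_counts = detector_counts,
                 phantoms = phantoms, correction = correction, plan = plan,
                 phantom = phantom, array = array, source = source,
                 het = het, max_iter = max_iter, tol = tol),
            class = "study_config")
}

#' Run the source-verification study
#'
#' For every cell of (phantom type x repeat x detector count x dwell):
#' score the array under the forward model, apply the seeded noise
#' realization, localize, and record signed per-axis errors and the 3D
#' error. Non-converged localizations are recorded, not fatal. The whole
#' study is deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `study_result`: list with `results` (long
#'   data.frame: phantom, repeat, n_detectors, dwell, estimates, truth,
#'   dx/dy/dz/d3d, iterations, converged) and `table`
#'   ([error_table()] aggregation).
#' @export
run_study <- function(config = study_config()) {
  pelvic <- config$phantom %||% make_pelvic_phantom(seed = config$seed)
  phantom_of <- list(pelvic = pelvic, water = override_to_water(pelvic))
  inv <- distance_inverter(config$source)
  d10 <- calibrate_D10(config$source)
  set.seed(config$seed)

  rows <- vector("list", 0L)
  for (ptype in config$phantoms) {
    ph <- phantom_of[[ptype]]
    clean <- score_array_noiseless(config$plan, config$array, config$source,
                                   ph, config$het)
    for (rep_i in seq_len(config$n_repeats)) {
      noisy <- if (config$noise_sigma > 0)
        pmax(clean * matrix(rnorm(length(clean), 1, config$noise_sigma),
                            nrow = nrow(clean)), 0)
      else clean
      for (nd in config$detector_counts) {
        res <- lapply(seq_len(nrow(noisy)), function(i)
          locate_single(noisy[i, ], d10, config$array, config$source, nd,
                        config$max_iter, config$tol, inv))
        if (config$correction) {
          res <- lapply(seq_along(res), function(i)
            wepl_correct_single(noisy[i, ], ph, res[[i]], config$source,
                                config$array, nd, config$max_iter,
                                config$tol, d10, config$het, 5, inv))
        }
        err <- localization_errors(res, config$plan)
        err$phantom <- ptype
        err$repeat_i <- rep_i
        err$n_detectors <- nd
        rows[[length(rows) + 1L]] <- err
      }
    }
  }
  results <- do.call(rbind, rows)
  results <- results[, c("phantom", "repeat_i", "n_detectors", "dwell",
                         "est_x", "est_y", "est_z", "true_x", "true_y",
                         "true_z", "dx", "dy", "dz", "d3d", "iterations",
                         "converged")]
  structure(list(results = results, table = error_table(results),
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Source-verification study: %d localizations (%s)\n",
              nrow(x$results), paste(unique(x$results$phantom),
                                     collapse = " + ")))
  if (any(!x$results$converged))
    cat(sprintf("  %d localizations did not converge\n",
                sum(!x$results$converged)))
  print(x$table)
  invisible(x)
}

#' Aggregate localization errors into a Table-1-style summary
#'
#' Per (phantom, detector count, axis): mean and SD (k = 1) over all
#' dwells and repeats of both the absolute and the signed per-axis error;
#' the `3D` axis row summarizes the 3D difference vector.
#'
#' @param results The long results data.frame from [run_study()].
#' @return data.frame of class `error_table` with columns `phantom`,
#'   `n_detectors`, `axis`, `mean_abs`, `sd_abs`, `mean_signed`,
#'   `sd_signed`.
#' @export
error_table <- function(results) {
  cells <- expand.grid(axis = c("X", "Y", "Z", "3D"),
                       n_detectors = sort(unique(results$n_detectors)),
                       phantom = unique(results$phantom),
                       stringsAsFactors = FALSE)
  col_of <- c(X = "dx", Y = "dy", Z = "dz", `3D` = "d3d")
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$phantom == cells$phantom[i] &
                   results$n_detectors == cells$n_detectors[i],
                   col_of[[cells$axis[i]]]]
    data.frame(phantom = cells$phantom[i],
               n_detectors = cells$n_detectors[i], axis = cells$axis[i],
               mean_abs = mean(abs(sub)), sd_abs = sd(abs(sub)),
               mean_signed = mean(sub), sd_signed = sd(sub))
  }))
  class(out) <- c("error_table", "data.frame")
  out
}

#' Format a mean +/- SD cell
#'
#' One-decimal "mean ± SD" formatting used by the report.
#'
#' @param m,s Mean and standard deviation.
#' @return Character scalar, e.g. `"1.9 ± 0.5"`.
#' @export
format_pm <- function(m, s) sprintf("%.1f ± %.1f", m, s)

#' Write the error-table report
#'
#' Writes the full aggregation as CSV (`<path>.csv`) and a markdown
#' rendering (`<path>.md`) with rows X/Y/Z/3D and one column per detector
#' count, cells formatted "mean ± SD" to one decimal place. Absolute and
#' signed per-axis summaries are both emitted.
#'
#' @param table An [error_table()].
#' @param path Output path stem (extensions are appended).
#' @return Character vector of the files written, invisibly.
#' @export
report <- function(table, path) {
  if (!inherits(table, "error_table") || nrow(table) == 0L)
    stop("'table' must be a non-empty error_table", call. = FALSE)
  csv <- paste0(path, ".csv"); md <- paste0(path, ".md")
  write.csv(as.data.frame(table), csv, row.names = FALSE)

  lines <- character(0)
  counts <- sort(unique(table$n_detectors))
  for (ptype in unique(table$phantom)) {
    for (kind in c("abs", "signed")) {
      mcol <- paste0("mean_", kind); scol <- paste0("sd_", kind)
      lines <- c(lines, sprintf("## %s phantom, %s per-axis error (mm, k = 1)",
                                ptype, if (kind == "abs") "absolute"
                                       else "signed"),
                 "",
                 paste(c("| Number of detectors used |",
                         sprintf(" %d |", counts)), collapse = ""),
                 paste(c("|---|", rep("---|", length(counts))),
                       collapse = ""))
      for (ax in c("X", "Y", "Z", "3D")) {
        cells <- vapply(counts, function(nd) {
          row <- table[table$phantom == ptype & table$n_detectors == nd &
                       table$axis == ax, ]
          format_pm(row[[mcol]], row[[scol]])
        }, character(1))
        lines <- c(lines, paste(c(sprintf("| %s |", ax),
                                  sprintf(" %s |", cells)), collapse = ""))
      }
      lines <- c(lines, "")
    }
  }
  writeLines(lines, md)
  invisible(c(csv, md))
}

#' Read back a report CSV as an error table
#'
#' @param path The `<path>.csv` written by [report()].
#' @return An `error_table`.
#' @export
read_error_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("error_table", "data.frame")
  out
}
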