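# Shared fixtures and independent oracles for the test suite.

# flat (identity) TG-43 tables: g == 1 and F == 1 everywhere
flat_radial_table <- function() radial_dose_table(c(1, 200), c(1, 1))

flat_anisotropy_table <- function() {
  anisotropy_table(c(1, 200), c(0, 90, 180), matrix(1, 2, 3))
}

# near-point source with identity tables: dose is pure inverse square
point_source <- function(strength_scale = 1) {
  source_model(active_length = 1e-4, strength_scale = strength_scale,
               radial_table = flat_radial_table(),
               anisotropy_table = flat_anisotropy_table())
}

# independent subtense oracle: beta as the angle between the vectors from
# the field point to the two ends of the active segment (vector geometry,
# no atan-difference identity)
beta_subtense_oracle <- function(r_mm, theta_deg, L_mm) {
  r <- r_mm / 10; L <- L_mm / 10
  th <- theta_deg * pi / 180
  p <- c(r * sin(th), r * cos(th))          # field point, source along 2nd axis
  v1 <- c(0, -L / 2) - p; v2 <- c(0, L / 2) - p
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
}

# brute-force WEPL oracle: fixed fine-step midpoint sampling of the density
wepl_sampling_oracle <- function(phantom, a, b, step = 0.01) {
  len <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(len / step))
  t_mid <- (seq_len(n) - 0.5) / n
  pts <- cbind(a[1] + t_mid * (b[1] - a[1]),
               a[2] + t_mid * (b[2] - a[2]),
               a[3] + t_mid * (b[3] - a[3]))
  idx <- sapply(1:3, function(k)
    floor((pts[, k] - phantom$origin[k]) / phantom$spacing[k]))
  inside <- idx[, 1] >= 0 & idx[, 1] < phantom$shape[1] &
            idx[, 2] >= 0 & idx[, 2] < phantom$shape[2] &
            idx[, 3] >= 0 & idx[, 3] < phantom$shape[3]
  dens <- rep(0.998, n)
  dens[inside] <- phantom$density[idx[inside, , drop = FALSE] + 1L]
  sum(dens / 0.998) * len / n
}

# coarse-to-fine exhaustive search of the weighted multilateration
# objective: 1 mm sweep over a 20 mm cube around `centre`, then a 0.05 mm
# sweep over the surrounding 2 mm cube
grid_search_oracle <- function(P, r, centre, w = rep(1, length(r))) {
  objective <- function(G) {
    acc <- 0
    for (i in seq_len(nrow(P))) {
      d <- sqrt((G[, 1] - P[i, 1])^2 + (G[, 2] - P[i, 2])^2 +
                (G[, 3] - P[i, 3])^2)
      acc <- acc + w[i] * (d - r[i])^2
    }
    acc
  }
  sweep_at <- function(c0, half, step) {
    ax <- lapply(1:3, function(k) seq(c0[k] - half, c0[k] + half, by = step))
    G <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    unname(G[which.min(objective(G)), ])
  }
  fine <- sweep_at(sweep_at(centre, 10, 1), 1, 0.05)
  fine
}

# small reusable scene
tiny_plan <- function() make_dwell_plan(n_catheters = 1, n_dwells = 1)
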