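# Forward model: array geometry, WEPL ray tracing, detector dose, noise.

test_that("diode array geometry follows the design", {
  mp <- build_magic_plate()
  expect_equal(nrow(mp$positions), 121)
  # (11 - 1) x 10 mm pitch per side
  expect_equal(max(mp$positions[, 1]) - min(mp$positions[, 1]), 100)
  expect_equal(max(mp$positions[, 2]) - min(mp$positions[, 2]), 100)
  # all detectors coplanar
  expect_equal(length(unique(mp$positions[, 3])), 1L)
  # centre detector sits at plane_origin + (50, 50, 0)
  centre_id <- which(mp$positions[, 1] == 50 & mp$positions[, 2] == 50)
  expect_length(centre_id, 1L)
  # corner diode at the origin
  expect_equal(unname(mp$positions[1, ]), c(0, 0, 0))
  mp2 <- build_magic_plate(pitch = 7.5, plane_origin = c(1, 2, 3))
  expect_equal(unname(mp2$positions[1, ]), c(1, 2, 3))
  expect_equal(max(mp2$positions[, 1]) - min(mp2$positions[, 1]), 75)
})

test_that("WEPL is exact in uniform media and on hand-checked rays", {
  ph <- make_water_phantom(c(10, 10, 10), spacing = 3, origin = c(0, 0, 0))
  a <- c(1, 2, 3); b <- c(28, 17, 24)
  expect_equal(wepl(ph, a, b), sqrt(sum((b - a)^2)), tolerance = 1e-9)
  # ray partially outside the grid still water-equivalent
  expect_equal(wepl(ph, c(-50, 5, 5), c(80, 5, 5)), 130, tolerance = 1e-9)
  # axis-aligned ray through densities (0.998, 1.996, 0.998): 3 + 6 + 3
  dens <- array(0.998, dim = c(3, 1, 1)); dens[2, 1, 1] <- 1.996
  slab <- voxel_phantom(dens, origin = c(0, 0, 0), spacing = 3)
  expect_equal(wepl(slab, c(0, 1.5, 1.5), c(9, 1.5, 1.5)), 12,
               tolerance = 1e-9)
  expect_error(wepl(ph, a, a), "zero-length")
})

test_that("WEPL agrees with a fine-step sampling oracle on oblique rays", {
  ph <- make_pelvic_phantom(seed = 8)
  set.seed(9)
  for (k in 1:6) {
    a <- c(runif(1, 25, 75), runif(1, 40, 60), runif(1, 30, 60))
    b <- c(runif(1, 0, 100), runif(1, 0, 100), 0)
    expect_equal(wepl(ph, a, b), wepl_sampling_oracle(ph, a, b),
                 tolerance = 1e-3)
  }
})

test_that("detector dose reduces to the TG-43 dose rate in water", {
  src <- source_model()
  mp <- build_magic_plate()
  s <- c(50, 50, 40)
  ang_free <- detector_dose(s, mp$positions, src)
  wat <- make_water_phantom()
  ang_wat <- detector_dose(s, mp$positions, src, phantom = wat)
  expect_equal(ang_free, ang_wat, tolerance = 1e-9)
  # against a direct (r, theta) evaluation for one detector
  p <- mp$positions[61, ]
  r <- sqrt(sum((s - p)^2))
  theta <- acos((p[2] - s[2]) / r) * 180 / pi
  expect_equal(unname(detector_dose(s, p, src)), dose_rate(r, theta, src),
               tolerance = 1e-12)
})

test_that("a dense slab on the ray attenuates by the closed-form factor", {
  src <- source_model()
  # 3 mm-thick density-1.996 slab perpendicular to a vertical ray
  dens <- array(0.998, dim = c(5, 5, 9))
  dens[, , 4] <- 1.996
  slab <- voxel_phantom(dens, origin = c(-7.5, -7.5, 0), spacing = 3)
  s <- c(0, 0, 40); p <- c(0, 0, 0)
  base <- detector_dose(s, p, src)
  att <- detector_dose(s, p, src, phantom = slab)
  # excess WEPL = t * (1.996 - 0.998)/0.998 with t = 3 mm
  t_mm <- 3 * (1.996 - 0.998) / 0.998
  expect_equal(unname(att / base), exp(-0.111 * t_mm / 10), tolerance = 1e-9)
  # density above water decreases dose; below water increases it
  dens2 <- dens; dens2[, , 4] <- 0.2
  light <- voxel_phantom(dens2, origin = c(-7.5, -7.5, 0), spacing = 3)
  expect_lt(unname(att), unname(base))
  expect_gt(unname(detector_dose(s, p, src, phantom = light)), unname(base))
})

test_that("dose is symmetric about the source transverse plane", {
  src <- source_model()
  s <- c(50, 50, 40)
  # detectors mirrored in y about the source's transverse plane
  p1 <- c(30, 50 + 17, 0); p2 <- c(30, 50 - 17, 0)
  expect_equal(unname(detector_dose(s, p1, src)),
               unname(detector_dose(s, p2, src)), tolerance = 1e-12)
})

test_that("heterogeneity off makes dose a function of (r, theta) only", {
  src <- source_model()
  het_off <- heterogeneity_model(enabled = FALSE)
  ph <- make_pelvic_phantom(seed = 1)
  s <- c(50, 50, 40)
  # same (r, theta), different positions/paths
  p1 <- c(50 + 30, 50, 40); p2 <- c(50 - 30, 50, 40); p3 <- c(50, 50, 10)
  d <- detector_dose(s, rbind(p1, p2, p3), src, phantom = ph, het = het_off)
  expect_equal(d[1], d[2], tolerance = 1e-12)
  expect_equal(d[1], d[3], tolerance = 1e-12)
})

test_that("total array dose decreases as the source recedes along +z", {
  src <- source_model()
  mp <- build_magic_plate()
  totals <- vapply(seq(20, 80, by = 1), function(z)
    sum(detector_dose(c(50, 50, z), mp$positions, src)), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("array scoring applies the calibrated noise model deterministically", {
  src <- source_model(strength_scale = 3)
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  clean <- score_array(plan, mp, src, noise_sigma = 0)
  # noiseless scoring equals the forward doses and D_10 the strength scale
  expect_equal(clean$doses[1, ],
               detector_dose(dwell_positions(plan)[1, ], mp$positions, src,
                             array = mp), tolerance = 1e-12)
  expect_equal(clean$d10, 3, tolerance = 1e-12)
  expect_equal(calibrate_D10(source_model(strength_scale = 6)), 6)
  # same seed -> identical readings; different seed -> different
  r1 <- score_array(plan, mp, src, noise_sigma = 0.01, seed = 10)
  r2 <- score_array(plan, mp, src, noise_sigma = 0.01, seed = 10)
  r3 <- score_array(plan, mp, src, noise_sigma = 0.01, seed = 11)
  expect_identical(r1$doses, r2$doses)
  expect_false(identical(r1$doses, r3$doses))
  # D_10 is noiseless and independent of the phantom contents
  het <- score_array(plan, mp, src, phantom = make_pelvic_phantom(seed = 1),
                     noise_sigma = 0.01, seed = 10)
  expect_equal(het$d10, 3, tolerance = 1e-12)
})

test_that("noise realizations have the requested relative spread", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- tiny_plan()
  clean <- score_array(plan, mp, src, noise_sigma = 0)$doses[1, ]
  set.seed(123)
  ratios <- unlist(lapply(1:85, function(k)
    score_array(plan, mp, src, noise_sigma = 0.01)$doses[1, ] / clean))
  # ~1e4 multiplicative factors: SD ~ 1% of the mean within 5% relative
  expect_equal(sd(ratios) / mean(ratios), 0.01, tolerance = 0.05)
})

test_that("readings round-trip through CSV plus JSON sidecar", {
  src <- source_model()
  mp <- build_magic_plate()
  rd <- score_array(make_dwell_plan(), mp, src, noise_sigma = 0.01, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_readings(rd, f)
  back <- read_readings(f)
  expect_equal(back$doses, rd$doses, tolerance = 1e-12)
  expect_equal(back$d10, rd$d10)
  expect_equal(back$noise_sigma, 0.01)
  expect_equal(back$seed, 4)
})
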