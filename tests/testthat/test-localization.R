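# Reconstruction: dose normalization, distance inversion within the loop,
# subset selection, multilateration, and the WEPL correction.

test_that("relative dose is an elementwise scale-invariant ratio", {
  a <- relative_dose(c(2, 1, 0), 2)
  expect_equal(as.numeric(a), c(1, 0.5, 0))
  expect_identical(attr(a, "usable"), c(TRUE, TRUE, FALSE))
  # scaling all doses and D_10 leaves alpha unchanged
  d <- runif(10, 0.1, 2)
  expect_equal(as.numeric(relative_dose(7 * d, 7 * 0.8)),
               as.numeric(relative_dose(d, 0.8)), tolerance = 1e-12)
  expect_error(relative_dose(d, 0), "positive")
})

test_that("top-n selection matches a brute-force sort oracle", {
  src <- source_model()
  mp <- build_magic_plate()
  # symmetric noiseless field: n = 9 is the 3x3 block under the source
  d <- detector_dose(c(50, 50, 30), mp$positions, src)
  sel <- sort(select_top_n(d, 9))
  cols <- (sel - 1) %% 11 + 1; rows <- (sel - 1) %/% 11 + 1
  expect_setequal(cols, 5:7)
  expect_setequal(rows, 5:7)
  # brute-force oracle on random doses
  set.seed(21)
  for (k in 1:10) {
    dd <- runif(121)
    expect_identical(select_top_n(dd, 25),
                     order(dd, decreasing = TRUE)[1:25])
  }
  # equal doses everywhere: ties broken by ascending index
  expect_identical(select_top_n(rep(1, 121), 9), 1:9)
  expect_identical(select_top_n(rep(1, 121), 121), 1:121)
  expect_error(select_top_n(c(rep(1, 8), rep(0, 113)), 9), "usable")
  expect_error(select_top_n(rep(1, 121), 10), "must be one of")
})

test_that("linearized multilateration recovers exact-geometry positions", {
  mp <- build_magic_plate()
  truth <- c(43.7, 58.2, 47.9)
  r <- sqrt(colSums((truth - t(mp$positions))^2))
  est <- initial_estimate(mp$positions, r)
  expect_lt(sqrt(sum((est - truth)^2)), 1e-6)
  # source on the central vertical axis: x, y at the array centre
  truth2 <- c(50, 50, 35)
  r2 <- sqrt(colSums((truth2 - t(mp$positions))^2))
  est2 <- initial_estimate(mp$positions, r2)
  expect_equal(est2[1:2], c(50, 50), tolerance = 1e-9)
  # coplanar sign ambiguity resolved to the +z (patient) side
  expect_gt(est2[3], mp$plane_origin[3])
  expect_error(initial_estimate(mp$positions[1:3, ], r[1:3]), ">= 4")
})

test_that("noiseless water localization is self-consistent to < 0.01 mm", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  rd <- score_array(plan, mp, src, noise_sigma = 0)
  res <- refine_position(rd, src)
  err <- localization_errors(res, plan)
  expect_lt(max(err$d3d), 0.01)
  expect_true(all(err$converged))
})

test_that("refinement matches an exhaustive grid search on 9-detector cases", {
  src <- source_model()
  mp <- build_magic_plate()
  inv <- distance_inverter(src)
  for (truth in list(c(41, 52, 36), c(55, 47, 50))) {
    D <- detector_dose(truth, mp$positions, src, array = mp)
    res <- refine_position(D, src, mp, n_detectors = 9, d10 = 1,
                           inverter = inv)
    sel <- res$detector_ids
    # corrected distances at the converged estimate, as the loop sees them
    P <- mp$positions[sel, , drop = FALSE]
    v <- sweep(P, 2, res$position)
    rr <- sqrt(rowSums(v^2))
    corr <- angular_dose_profile(pmin(pmax(rr, 1), 200),
                                 acos(pmin(pmax(v[, 2] / rr, -1), 1)) *
                                   180 / pi, src)
    a <- (D[sel] / corr)
    r <- as.numeric(inv(a))
    oracle <- grid_search_oracle(P, r, truth)
    expect_lt(sqrt(sum((res$position - oracle)^2)), 0.1)
    expect_lt(sqrt(sum((res$position - truth)^2)), 0.01)
  }
})

test_that("localization error is invariant under rigid scene translation", {
  src <- source_model()
  plan <- make_dwell_plan()
  shift <- c(-13, 27, 8)
  mp1 <- build_magic_plate()
  mp2 <- build_magic_plate(plane_origin = shift)
  plan2 <- plan
  plan2$x_mm <- plan$x_mm + shift[1]
  plan2$y_mm <- plan$y_mm + shift[2]
  plan2$z_mm <- plan$z_mm + shift[3]
  r1 <- score_array(plan, mp1, src, noise_sigma = 0)
  r2 <- score_array(plan2, mp2, src, noise_sigma = 0)
  e1 <- localization_errors(refine_position(r1, src), plan)
  e2 <- localization_errors(refine_position(r2, src), plan2)
  expect_equal(e1$d3d, e2$d3d, tolerance = 1e-6)
})

test_that("more detectors do not hurt water accuracy under 1% noise", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  inv <- distance_inverter(src)
  errs <- sapply(c(9, 25), function(nd) {
    set.seed(77)
    mean(unlist(lapply(1:5, function(rep_i) {
      rd <- score_array(plan, mp, src, noise_sigma = 0.01)
      localization_errors(refine_position(rd, src, n_detectors = nd,
                                          inverter = inv), plan)$d3d
    })))
  })
  expect_lte(errs[2], errs[1])
})

test_that("uncorrected heterogeneous localization overestimates z", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  ph <- make_pelvic_phantom(seed = 1)
  rd <- score_array(plan, mp, src, phantom = ph, noise_sigma = 0)
  err <- localization_errors(refine_position(rd, src), plan)
  expect_gt(mean(err$dz), 0)
  expect_true(all(err$dz > 0))
})

test_that("WEPL correction is the identity in water and exact when models match", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  wat <- make_water_phantom()
  rd <- score_array(plan, mp, src, phantom = wat, noise_sigma = 0)
  res <- refine_position(rd, src)
  cor <- wepl_correct(rd, wat, res, src)
  for (i in seq_along(res))
    expect_equal(cor[[i]]$position, res[[i]]$position, tolerance = 1e-6)
  # noiseless heterogeneous data: exact model inversion
  ph <- make_pelvic_phantom(seed = 1)
  rdh <- score_array(plan, mp, src, phantom = ph, noise_sigma = 0)
  resh <- refine_position(rdh, src)
  corh <- wepl_correct(rdh, ph, resh, src)
  errc <- localization_errors(corh, plan)
  expect_lt(mean(errc$d3d), 0.1)
  # and the correction reduces the heterogeneous error in every dwell
  errh <- localization_errors(resh, plan)
  expect_true(all(errc$d3d < errh$d3d))
})

test_that("noisy heterogeneous accuracy after correction matches water", {
  src <- source_model()
  mp <- build_magic_plate()
  plan <- make_dwell_plan()
  ph <- make_pelvic_phantom(seed = 1)
  inv <- distance_inverter(src)
  set.seed(31)
  d3d_cor <- unlist(lapply(1:3, function(k) {
    rdh <- score_array(plan, mp, src, phantom = ph, noise_sigma = 0.01)
    resh <- refine_position(rdh, src, inverter = inv)
    localization_errors(wepl_correct(rdh, ph, resh, src, inverter = inv),
                        plan)$d3d
  }))
  d3d_wat <- unlist(lapply(1:3, function(k) {
    rdw <- score_array(plan, mp, src, noise_sigma = 0.01)
    localization_errors(refine_position(rdw, src, inverter = inv), plan)$d3d
  }))
  ht <- t_test(d3d_cor, d3d_wat)
  expect_gt(ht$p, 0.05)
})
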