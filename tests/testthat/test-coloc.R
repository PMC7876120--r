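# Colocalization quantification: CSR baselines, calibration curves,
# inversion, and the absolute-density extrapolation arithmetic.

test_that("coloc_fraction handles degenerate geometries", {
  set.seed(70)
  pts <- data.frame(x = runif(50, 0, 500), y = runif(50, 0, 500))
  expect_equal(coloc_fraction(pts, pts), 1.0)
  far <- data.frame(x = pts$x + 1e6, y = pts$y)
  expect_equal(coloc_fraction(pts, far), 0.0)
  expect_error(coloc_fraction(pts[0, ], pts), "empty")
  expect_error(coloc_fraction(pts, pts[0, ]), "empty")
})

test_that("CSR colocalization matches the void-probability closed form", {
  roi <- rect_mask(1e4, 1e4)
  # reference density 183.3/um^2 at 25 nm threshold: 1-exp(-pi rho r^2) = 0.302
  expect_equal(csr_coloc_fraction(183.3, 25), 0.302, tolerance = 0.005)
  for (rho_b in c(100, 400)) {
    src <- gen_random_field(50, roi, seed = 71)
    ref <- gen_random_field(rho_b, roi, seed = 72 + rho_b)
    obs <- coloc_fraction(src, ref, 25)
    expected <- csr_coloc_fraction(rho_b, 25)
    mc_se <- sqrt(expected * (1 - expected) / nrow(src))
    expect_lt(abs(obs - expected), 4 * mc_se)
  }
})

test_that("calibration curves are anchored at CSR and monotone", {
  curve <- build_calibration_curve(grid = seq(0, 1, by = 0.25),
                                   replicates = 8,
                                   roi = rect_mask(5e3, 5e3), seed = 73)
  # c = 0 endpoint: CSR against the labeled reference density
  cfg <- attr(curve, "config")
  csr <- csr_coloc_fraction(cfg$density_a * cfg$le_a, cfg$threshold)
  expect_lt(abs(curve$mean[1] - csr), 4 * curve$sd[1] / sqrt(8) + 0.01)
  # construction: full complexing beats the density-driven baseline
  expect_gt(curve$mean[nrow(curve)], curve$mean[1] + 0.1)
  # monotone non-decreasing within Monte-Carlo tolerance
  steps <- diff(curve$mean)
  tol <- 2 * sqrt(curve$sd[-1]^2 + curve$sd[-nrow(curve)]^2) / sqrt(8)
  expect_true(all(steps > -tol))
})

test_that("inversion recovers the curve endpoints and flags range", {
  curve <- build_calibration_curve(grid = seq(0, 1, by = 0.25),
                                   replicates = 8,
                                   roi = rect_mask(5e3, 5e3), seed = 74)
  expect_equal(invert_calibration(curve$mean[1], curve)$c_hat, 0)
  expect_equal(invert_calibration(curve$mean[nrow(curve)], curve)$c_hat, 1)
  mid <- invert_calibration((curve$mean[1] + curve$mean[nrow(curve)]) / 2,
                            curve)
  expect_true(mid$c_hat > 0.2 && mid$c_hat < 0.8)
  expect_true(mid$interval[1] <= mid$c_hat && mid$c_hat <= mid$interval[2])
  expect_warning(res <- invert_calibration(0.999, curve), "outside")
  expect_true(res$out_of_range)
  expect_equal(res$c_hat, 1)
})

test_that("sensitivity sweep shows the documented trends", {
  sw <- sensitivity_sweep(densities = c(150, 600),
                          le_a_values = c(0.3, 1.0),
                          le_b_values = c(0.2, 0.66),
                          replicates = 6, roi = rect_mask(4e3, 4e3),
                          seed = 75)
  # CSR baseline increases with density at fixed LE
  base <- sw[sw$le_a == 0.3 & sw$le_b == 0.2, ]
  expect_gt(base$coloc_c0[base$density == 600],
            base$coloc_c0[base$density == 150])
  # dynamic range shrinks as labeling efficiencies decrease
  hi <- sw$dynamic_range[sw$density == 150 & sw$le_a == 1.0 & sw$le_b == 0.66]
  lo <- sw$dynamic_range[sw$density == 150 & sw$le_a == 0.3 & sw$le_b == 0.2]
  expect_gt(hi, lo)
})

test_that("density extrapolation reproduces the three-scenario arithmetic", {
  # worst / intermediate / best labeling-and-detection scenarios
  worst <- extrapolate_density(82.4, 0.25, 1 / 3)
  mid <- extrapolate_density(99.25, 0.33, 0.50)
  best <- extrapolate_density(117.6, 0.60, 0.80)
  expect_equal(trunc(worst), 988)
  expect_equal(trunc(best), 245)
  expect_equal(mid, 99.25 / (0.33 * 0.50), tolerance = 1e-12)
  expect_equal(extrapolate_density(42, 1, 1), 42)
  # exactly multiplicative: halving LE doubles the estimate
  expect_equal(extrapolate_density(50, 0.15, 0.5),
               2 * extrapolate_density(50, 0.30, 0.5))
  expect_error(extrapolate_density(10, 0, 0.5), "LE and DE")
  s <- scenario_summary(c(worst, mid, best))
  # integer-truncated display convention: 611 +/- 303
  expect_equal(trunc(s$mean), 611)
  expect_equal(trunc(s$sd), 303)
  expect_equal(scenario_summary(5)$sd, 0)
  expect_equal(scenario_summary(c(7, 7, 7))$sd, 0)
  expect_error(scenario_summary(numeric(0)), "at least one")
})
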