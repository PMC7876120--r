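# Synthetic-data generator: spatial layouts, labeling, binding kinetics,
# localization rendering. Statistical checks run at fixed seeds against
# counting-statistics oracles.

test_that("random fields have Poisson counts and uniform placement", {
  roi <- rect_mask(2000, 2000)  # 4 um^2
  expect_equal(nrow(gen_random_field(0, roi, seed = 1)), 0)
  expect_error(gen_random_field(-5, roi), ">= 0")
  counts <- vapply(1:200, function(s)
    nrow(gen_random_field(150, roi, seed = s)), numeric(1))
  lambda <- 150 * 4
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # same seed, same field
  expect_identical(gen_random_field(150, roi, seed = 7),
                   gen_random_field(150, roi, seed = 7))
})

test_that("mean NND of a homogeneous field matches 0.5/sqrt(rho)", {
  rho <- 600
  roi <- rect_mask(5000, 5000)  # 25 um^2 -> ~15k molecules
  f <- gen_random_field(rho, roi, seed = 11)
  r <- nnd(f, torus_period = c(5000, 5000))
  expect_equal(mean(r$distances), 0.5 / sqrt(rho / 1e6), tolerance = 0.02)
})

test_that("complexed populations respect the pair-distance contract", {
  roi <- rect_mask(3000, 3000)
  expect_error(gen_complex_population(100, 100, 1.5, roi = roi), "\\[0, 1\\]")
  p0 <- gen_complex_population(100, 100, 0, roi = roi, seed = 2)
  expect_true(all(is.na(p0$b$partner)))
  p1 <- gen_complex_population(250, 150, 1, roi = roi, seed = 3)
  expect_true(all(!is.na(p1$b$partner)))
  d <- sqrt((p1$a$x[p1$b$partner] - p1$b$x)^2 +
              (p1$a$y[p1$b$partner] - p1$b$y)^2)
  expect_true(all(d >= 12 & d <= 16))
  expect_false(any(duplicated(p1$b$partner)))  # 1:1 complexes
  expect_true(all(p1$b$x >= 0 & p1$b$x <= 3000 &
                    p1$b$y >= 0 & p1$b$y <= 3000))
})

test_that("labeling is independent binomial thinning", {
  roi <- rect_mask(3000, 3000)
  f <- gen_random_field(1200, roi, seed = 4)  # ~10800 molecules
  expect_true(all(apply_labeling(f, 1, seed = 1)$labeled))
  expect_false(any(apply_labeling(f, 0, seed = 1)$labeled))
  fracs <- vapply(1:20, function(s)
    mean(apply_labeling(f, 0.3, seed = s)$labeled), numeric(1))
  se <- sqrt(0.3 * 0.7 / (nrow(f) * 20))
  expect_lt(abs(mean(fracs) - 0.3), 3 * se)
})

test_that("origami grids have the configured geometry", {
  g <- gen_origami_grid(3, 4, spacing = 20)
  expect_equal(nrow(g), 12)
  expect_equal(min(dist(cbind(g$x, g$y))), 20)
  g1 <- gen_origami_grid(1, 1)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$x, g1$y), c(0, 0))
  expect_error(gen_origami_grid(2, 2, spacing = 0), "spacing")
})

test_that("striped fields are piecewise-homogeneous", {
  roi <- rect_mask(9000, 3000)  # three 1um stripes + two 2um gaps + 1um
  f <- gen_striped_field(1000, 2000, density_stripe = 400, density_gap = 0,
                         roi = roi, seed = 5)
  expect_true(all(f$region == "stripe"))
  expect_true(all((f$x %% 3000) < 1000))
  f2 <- gen_striped_field(1000, 2000, 300, 30, roi = roi, seed = 6)
  # NND within the dense stripes is shorter than within the sparse gaps
  r_stripe <- nnd(as.data.frame(f2)[f2$region == "stripe", c("x", "y")])
  r_gap <- nnd(as.data.frame(f2)[f2$region == "gap", c("x", "y")])
  expect_lt(mean(r_stripe$distances), mean(r_gap$distances))
})

test_that("binding kinetics follow the renewal-process oracle", {
  cfg <- lossless_kinetics(n_frames = 40000)  # 4000 s
  lay <- gen_origami_grid(5, 10, spacing = 100)  # 50 sites
  traces <- simulate_kinetics(lay, cfg, seed = 8)
  counts <- vapply(traces, function(t) nrow(t$events), numeric(1))
  # expected events per site: T / (mean_dark + mean_bright)
  lambda <- 4000 / (1 / cfg$influx_rate + cfg$mean_bright_time)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(counts)))
  # zero influx -> empty traces
  t0 <- simulate_kinetics(lay, kinetics_config(influx_rate = 0), seed = 1)
  expect_true(all(vapply(t0, function(t) nrow(t$events) == 0, logical(1))))
})

test_that("three concatenated sequences shorten dark times three-fold", {
  cfg <- lossless_kinetics(n_frames = 80000)
  lay1 <- gen_origami_grid(4, 10, spacing = 100, sites_per_position = 1)
  lay3 <- gen_origami_grid(4, 10, spacing = 100, sites_per_position = 3)
  d1 <- unlist(lapply(simulate_kinetics(lay1, cfg, seed = 9),
                      extract_dark_times))
  d3 <- unlist(lapply(simulate_kinetics(lay3, cfg, seed = 10),
                      extract_dark_times))
  expect_equal(mean(d3) / mean(d1), 1 / 3, tolerance = 0.12)
})

test_that("rendering conserves occupied frames and applies Gaussian noise", {
  cfg <- kinetics_config(n_frames = 20000, sigma = 0)
  lay <- site_layout(500, 700)
  tr <- simulate_kinetics(lay, cfg, seed = 12)
  tab <- render_localizations(tr, lay, cfg, seed = 13)
  expect_equal(nrow(tab), length(occupied_frames(tr[[1]])))
  expect_true(all(tab$x == 500 & tab$y == 700))  # sigma = 0: exact

  cfg7 <- kinetics_config(n_frames = 160000, sigma = 7)
  tr7 <- simulate_kinetics(lay, cfg7, seed = 14)
  tab7 <- render_localizations(tr7, lay, cfg7, seed = 15)
  expect_gt(nrow(tab7), 1000)
  expect_equal(sd(tab7$x), 7, tolerance = 0.05)
  expect_equal(sd(tab7$y), 7, tolerance = 0.05)
  expect_true(all(tab7$photons >= 1))
})

test_that("generators are bit-identical under identical seeds", {
  cfg <- kinetics_config(n_frames = 5000)
  lay <- gen_origami_grid(2, 2, spacing = 50)
  a <- render_localizations(simulate_kinetics(lay, cfg, seed = 3), lay, cfg,
                            seed = 4)
  b <- render_localizations(simulate_kinetics(lay, cfg, seed = 3), lay, cfg,
                            seed = 4)
  expect_identical(a, b)
})
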