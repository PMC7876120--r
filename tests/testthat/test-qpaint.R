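# qPAINT counting: dark-time arithmetic, influx calibration, binding-site
# estimation linearity.

trace_from_events <- function(starts, durs, n_frames = 80000) {
  qsmcl:::new_kinetic_trace(1L, starts, durs, n_frames)
}

test_that("dark times are the gaps between events in seconds", {
  # events at frames 100-104, 300-301, 900-902 with 100 ms exposure
  tr <- trace_from_events(c(100, 300, 900), c(5, 2, 3))
  expect_equal(extract_dark_times(tr, exposure_s = 0.1), c(19.5, 59.8))
  expect_equal(extract_dark_times(trace_from_events(10, 5)), numeric(0))
  g <- extract_dark_times(tr, exposure_s = 0.1, censored = TRUE)
  expect_equal(g$censored_s, c(10, 7909.7))
})

test_that("simulated dark times match their exponential oracle", {
  cfg <- lossless_kinetics(n_frames = 160000)  # mean dark 50 s
  lay <- gen_origami_grid(4, 10, spacing = 100)
  darks <- unlist(lapply(simulate_kinetics(lay, cfg, seed = 41),
                         extract_dark_times))
  expect_gt(length(darks), 5000)
  expect_lt(abs(mean(darks) - 50), 3 * 50 / sqrt(length(darks)) + 0.2)
})

test_that("influx calibration recovers the simulated rate", {
  cfg <- lossless_kinetics(n_frames = 160000)
  lay <- gen_origami_grid(10, 20, spacing = 100)  # 200 reference sites
  traces <- simulate_kinetics(lay, cfg, seed = 42)
  cal <- calibrate_influx(traces, exposure_s = 0.1)
  expect_equal(cal$influx_rate, cfg$influx_rate, tolerance = 0.10)
  expect_equal(cal$n_sites, 200)

  cfg2 <- lossless_kinetics(n_frames = 160000, influx_rate = 0.04)
  cal2 <- calibrate_influx(simulate_kinetics(lay, cfg2, seed = 43),
                           exposure_s = 0.1)
  expect_equal(cal2$influx_rate / cal$influx_rate, 2, tolerance = 0.1)

  # censoring-aware MLE agrees with the mean estimator on long traces
  cal_mle <- calibrate_influx(traces, exposure_s = 0.1, method = "mle")
  expect_equal(cal_mle$influx_rate, cal$influx_rate, tolerance = 0.02)

  empty <- list(trace_from_events(integer(0), integer(0)))
  expect_error(calibrate_influx(empty), "no usable dark times")
})

test_that("counting is linear in the number of superposed sites", {
  cfg <- kinetics_config(n_frames = 160000)
  study1 <- qpaint_counting_study(1, n_ref = 150, n_clouds = 40, cfg = cfg,
                                  seed = 44)
  expect_equal(study1$median_rounded, 1)
  for (k in c(2, 3, 5)) {
    st <- qpaint_counting_study(k, n_ref = 150, n_clouds = 40, cfg = cfg,
                                seed = 44 + k)
    expect_equal(st$median_rounded, k)
    expect_equal(mean(st$counts$sites_raw), k, tolerance = 0.12)
  }
})

test_that("single-site estimate spread is paper-scale (~0.3-0.4)", {
  st <- qpaint_counting_study(1, n_ref = 150, n_clouds = 60,
                              cfg = kinetics_config(n_frames = 160000),
                              seed = 50)
  # order-of-magnitude property, not an exact target
  expect_gt(sd(st$counts$sites_raw), 0.02)
  expect_lt(sd(st$counts$sites_raw), 0.8)
})

test_that("cluster frames convert back into the generating trace", {
  cfg <- kinetics_config(n_frames = 40000, sigma = 5)
  lay <- site_layout(600, 600)
  tr <- simulate_kinetics(lay, cfg, seed = 45)
  tab <- render_localizations(tr, lay, cfg, seed = 46)
  back <- frames_to_trace(tab$frame, cfg$n_frames)
  expect_equal(back$events, tr[[1]]$events)

  # explicit merging: frames 3,4,5,9,10 -> events (3,len 3) and (9,len 2)
  t2 <- frames_to_trace(c(9, 3, 4, 10, 5), 100)
  expect_equal(t2$events$start_frame, c(3L, 9L))
  expect_equal(t2$events$duration, c(3L, 2L))
})

test_that("counting works end-to-end from detected clusters", {
  cfg <- kinetics_config(n_frames = 160000)
  # reference traces for calibration
  ref <- simulate_kinetics(gen_origami_grid(10, 15, spacing = 100), cfg,
                           seed = 47)
  cal <- calibrate_influx(ref, exposure_s = 0.1)
  # render five well-separated single sites, cluster, count via frames
  lay <- site_layout(seq(500, 2500, by = 500), rep(500, 5))
  tr <- simulate_kinetics(lay, cfg, seed = 48)
  tab <- render_localizations(tr, lay, cfg, seed = 49)
  cs <- std_frame_filter(dbscan_clusters(
    tab, cluster_params(7, default_min_pts(cfg), cfg$n_frames)))
  expect_equal(n_clusters(cs), 5)
  counts <- count_binding_sites_all(cluster_traces(cs, tab, cfg$n_frames),
                                    cal)
  expect_equal(median(counts$sites_rounded), 1)
  expect_equal(mean(counts$sites_raw), 1, tolerance = 0.1)
})
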