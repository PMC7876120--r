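# Closed-loop simulation benchmarks: the docking-site pair resolution study
# (how close two sites can be and still be split into two clouds by the
# automated pipeline) and trace-level qPAINT counting studies.

#' Two-site resolution benchmark for the detection pipeline
#'
#' Simulates pairs of docking sites at each separation with full binding
#' kinetics and localization noise, runs DBSCAN (eps = the pair's NeNA
#' precision estimate, min_pts from the binding frequency) plus both
#' temporal filters, and records how often the pair is resolved into
#' exactly two localization clouds.
#'
#' @param separations site separations to probe (nm).
#' @param n_pairs simulated pairs per separation.
#' @param cfg a `kinetics_config` (80,000 frames, sigma 7 nm by default).
#' @param seed master seed; every pair derives its own stream.
#' @param eps optional fixed DBSCAN radius (nm); default: per-pair NeNA.
#' @param min_pts optional fixed DBSCAN minimum; default from `cfg`.
#' @return data.frame with `separation`, `frac_two` (fraction of pairs
#'   giving exactly two clusters), `n_pairs`.
#' @export
resolution_benchmark <- function(separations = c(20, 25, 30, 35),
                                 n_pairs = 50, cfg = kinetics_config(),
                                 seed = 1, eps = NULL, min_pts = NULL) {
  if (is.null(min_pts)) min_pts <- default_min_pts(cfg)
  out <- lapply(separations, function(sep) {
    two <- vapply(seq_len(n_pairs), function(p) {
      s <- derive_seed(seed, sprintf("resolution_%g_%d", sep, p))
      layout <- site_layout(c(1000, 1000 + sep), c(1000, 1000))
      traces <- simulate_kinetics(layout, cfg, seed = s)
      tab <- render_localizations(traces, layout, cfg)
      e <- if (is.null(eps)) tryCatch(nena_precision(tab),
                                      error = function(err) cfg$sigma)
           else eps
      params <- cluster_params(e, min_pts, cfg$n_frames)
      cs <- detect_clusters(tab, params)
      n_clusters(cs) == 2L
    }, logical(1))
    data.frame(separation = sep, frac_two = mean(two), n_pairs = n_pairs)
  })
  do.call(rbind, out)
}

#' Smallest reliably resolved separation
#'
#' @param bench output of [resolution_benchmark()].
#' @param reliability required fraction of resolved pairs (default 0.9).
#' @return the smallest separation meeting the reliability, or `NA` if none.
#' @export
min_resolvable <- function(bench, reliability = 0.9) {
  ok <- bench$separation[bench$frac_two >= reliability]
  if (!length(ok)) NA_real_ else min(ok)
}

#' Trace-level qPAINT counting study
#'
#' Simulates single-binding-site reference clouds plus clouds holding
#' `sites` binding sites each (superposed independent kinetics), calibrates
#' the influx rate on the references, and counts binding sites in the
#' multi-site clouds.
#'
#' @param sites binding sites per test cloud (e.g. 3 for the concatenated
#'   triple-sequence construct, 2 for a dual-labeled tandem-tag cloud).
#' @param n_ref reference single-site clouds.
#' @param n_clouds test clouds.
#' @param cfg a `kinetics_config` (use 160,000 frames for counting).
#' @param seed seed.
#' @return list: `calibration`, `counts` (data.frame from
#'   [count_binding_sites_all()]), `median_rounded`.
#' @export
qpaint_counting_study <- function(sites, n_ref = 200, n_clouds = 60,
                                  cfg = kinetics_config(n_frames = 160000),
                                  seed = 1) {
  ref_layout <- site_layout(seq_len(n_ref) * 100, rep(0, n_ref))
  ref_traces <- simulate_kinetics(ref_layout, cfg,
                                  seed = derive_seed(seed, "qpaint_ref"))
  calib <- calibrate_influx(ref_traces, exposure_s = cfg$exposure_ms / 1000)
  cloud_traces <- lapply(seq_len(n_clouds), function(i) {
    lay <- site_layout(rep(0, sites), rep(0, sites))
    tr <- simulate_kinetics(lay, cfg,
                            seed = derive_seed(seed,
                                               sprintf("qpaint_cloud%d", i)))
    merge_traces(tr, cfg$n_frames)
  })
  counts <- count_binding_sites_all(cloud_traces, calib)
  list(calibration = calib, counts = counts,
       median_rounded = median(counts$sites_rounded, na.rm = TRUE))
}

#' Merge several kinetic traces into one cloud trace
#'
#' Superposes the occupied frames of all traces (one localization cloud
#' containing several binding sites) and re-merges consecutive frames into
#' events.
#'
#' @param traces list of `kinetic_trace`s.
#' @param n_frames acquisition length.
#' @return a single `kinetic_trace`.
#' @export
merge_traces <- function(traces, n_frames) {
  frames_to_trace(unlist(lapply(traces, occupied_frames)), n_frames)
}
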