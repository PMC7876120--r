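# qPAINT molecular counting: dark-time extraction from blinking traces,
# influx-rate calibration on single-site references, and binding-site
# number estimation per localization cloud.
#
# The estimator rests on the renewal structure of imager binding: a cloud
# holding n independent binding sites shows dark times that are n-fold
# shorter than a single site's, so n_hat = tau_dark(calibration) /
# tau_dark(cloud) = 1 / (influx_rate * tau_dark(cloud)).

#' Extract dark times from a kinetic trace
#'
#' Dark durations are the gaps between successive (merged) binding events,
#' converted to seconds with the exposure time. The censored leading and
#' trailing gaps (before the first and after the last event) are excluded
#' by default; `censored = TRUE` additionally returns them for
#' censoring-aware estimation.
#'
#' @param trace a `kinetic_trace`.
#' @param exposure_s exposure per frame in seconds.
#' @param censored also return the censored lead/tail gaps.
#' @return numeric vector of dark times (s); with `censored = TRUE` a list
#'   with `dark_s` and `censored_s`.
#' @export
extract_dark_times <- function(trace, exposure_s = 0.1, censored = FALSE) {
  ev <- trace$events
  dark <- if (nrow(ev) < 2) numeric(0) else {
    ends <- ev$start_frame + ev$duration
    (ev$start_frame[-1] - ends[-nrow(ev)]) * exposure_s
  }
  if (!censored) return(dark)
  cens <- if (nrow(ev) == 0) trace$n_frames * exposure_s else
    c(ev$start_frame[1],
      trace$n_frames - (ev$start_frame[nrow(ev)] + ev$duration[nrow(ev)])) *
      exposure_s
  list(dark_s = dark, censored_s = pmax(cens, 0))
}

mean_dark_time <- function(trace, exposure_s, method) {
  g <- extract_dark_times(trace, exposure_s, censored = TRUE)
  if (length(g$dark_s) == 0) return(NA_real_)
  switch(method,
         mean = mean(g$dark_s),
         # exponential MLE with the censored end gaps in the exposure
         mle = (sum(g$dark_s) + sum(g$censored_s)) / length(g$dark_s),
         stop("unknown dark-time method: ", method))
}

#' Calibrate the imager influx rate on single-site reference traces
#'
#' Reference localization clouds known to hold exactly one binding site
#' (for example manually validated origami sites) are calibrated to one
#' unit per binding site: the calibration dark time is the pooled mean dark
#' time and the influx rate its reciprocal.
#'
#' @param reference_traces list of single-site `kinetic_trace`s.
#' @param exposure_s exposure per frame (s).
#' @param method `"mean"` (pooled arithmetic mean of uncensored gaps,
#'   default) or `"mle"` (exponential fit including censored end gaps).
#' @return a `qpaint_calibration`: `influx_rate` (events/s per site),
#'   `tau_dark_cal` (s), `n_sites`, and `site_dispersion` (SD of per-site
#'   mean dark times).
#' @export
calibrate_influx <- function(reference_traces, exposure_s = 0.1,
                             method = c("mean", "mle")) {
  method <- match.arg(method)
  per_site <- vapply(reference_traces, mean_dark_time, numeric(1),
                     exposure_s = exposure_s, method = method)
  per_site <- per_site[!is.na(per_site)]
  if (!length(per_site))
    stop("no usable dark times in the reference traces")
  darks <- unlist(lapply(reference_traces, extract_dark_times,
                         exposure_s = exposure_s))
  tau <- if (method == "mean") mean(darks) else {
    tot <- vapply(reference_traces, function(tr) {
      g <- extract_dark_times(tr, exposure_s, censored = TRUE)
      if (!length(g$dark_s)) return(c(0, 0))
      c(sum(g$dark_s) + sum(g$censored_s), length(g$dark_s))
    }, numeric(2))
    sum(tot[1, ]) / sum(tot[2, ])
  }
  structure(list(influx_rate = 1 / tau, tau_dark_cal = tau,
                 n_sites = length(per_site),
                 site_dispersion = if (length(per_site) > 1) sd(per_site)
                 else NA_real_,
                 exposure_s = exposure_s, method = method),
            class = "qpaint_calibration")
}

#' @export
print.qpaint_calibration <- function(x, ...) {
  cat(sprintf(paste0("<qpaint_calibration: influx %.4g /s ",
                     "(tau_dark %.3g s) from %d sites>\n"),
              x$influx_rate, x$tau_dark_cal, x$n_sites))
  invisible(x)
}

#' Estimate the number of binding sites in a localization cloud
#'
#' @param trace the cloud's `kinetic_trace` (simulated, or built from
#'   cluster member frames with [frames_to_trace()]).
#' @param calibration a `qpaint_calibration`.
#' @return a one-row data.frame: `n_events`, `mean_dark_s`, `sites_raw`,
#'   `sites_rounded`. Clouds without measurable dark times come back with
#'   `NA` estimates.
#' @export
count_binding_sites <- function(trace, calibration) {
  stopifnot(inherits(calibration, "qpaint_calibration"))
  tau <- mean_dark_time(trace, calibration$exposure_s, calibration$method)
  raw <- calibration$tau_dark_cal / tau
  data.frame(n_events = nrow(trace$events),
             mean_dark_s = tau,
             sites_raw = raw,
             sites_rounded = ifelse(is.na(raw), NA_integer_,
                                    as.integer(round(raw))))
}

#' qPAINT counting over a list of clouds
#'
#' @param traces list of `kinetic_trace`s.
#' @param calibration a `qpaint_calibration`.
#' @return a data.frame with one row per cloud.
#' @export
count_binding_sites_all <- function(traces, calibration) {
  out <- do.call(rbind, lapply(traces, count_binding_sites, calibration))
  out$cloud <- seq_along(traces)
  out[, c("cloud", "n_events", "mean_dark_s", "sites_raw", "sites_rounded")]
}

#' Convert cluster member frames into a kinetic trace
#'
#' Marks the frames occupied by a cluster's member localizations and merges
#' consecutive occupied frames into binding events, recovering the blinking
#' record that qPAINT consumes.
#'
#' @param frames integer vector of occupied (0-based) frame indices.
#' @param n_frames acquisition length.
#' @param site optional site/cluster id.
#' @return a `kinetic_trace`.
#' @export
frames_to_trace <- function(frames, n_frames, site = NA_integer_) {
  f <- sort(unique(as.integer(frames)))
  if (!length(f))
    return(new_kinetic_trace(site, integer(0), integer(0), n_frames))
  brk <- c(0L, which(diff(f) > 1L), length(f))
  starts <- f[brk[-length(brk)] + 1L]
  durs <- diff(brk)
  new_kinetic_trace(site, starts, durs, n_frames)
}

#' Traces for every cluster in a cluster set
#'
#' Gathers, pick-style, all localizations within `pick_radius` of each
#' cluster centroid (not only the DBSCAN members: localizations in the
#' Gaussian tail of a cloud are often classed as noise, and dropping them
#' would split binding events and inflate the apparent event count), and
#' converts their frames into a blinking trace per cluster. Each
#' localization contributes to its nearest centroid only.
#'
#' @param cs a `cluster_set`.
#' @param table the `loc_table` the clusters were detected in.
#' @param n_frames acquisition length.
#' @param pick_radius pick region radius in nm (default 3 x the DBSCAN
#'   eps); `NULL` falls back to the raw member localizations.
#' @return list of `kinetic_trace`s, one per cluster.
#' @export
cluster_traces <- function(cs, table, n_frames,
                           pick_radius = 3 * cs$params$eps) {
  if (is.null(pick_radius))
    return(lapply(seq_along(cs$members), function(i)
      frames_to_trace(table$frame[cs$members[[i]]], n_frames,
                      site = cs$clusters$id[i])))
  cents <- cs$clusters
  nn <- cpp_knn(table$x, table$y, cents$x, cents$y, 1L, FALSE)
  grp <- nn$index[, 1]
  grp[nn$dist[, 1] > pick_radius] <- NA_integer_
  lapply(seq_len(nrow(cents)), function(i)
    frames_to_trace(table$frame[!is.na(grp) & grp == i], n_frames,
                    site = cents$id[i]))
}
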