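# Imager binding kinetics: docking-site layouts, two-state (dark/bright)
# renewal simulation, frame quantization, and rendering of localization
# tables with Gaussian localization noise.

#' Kinetics configuration for DNA-PAINT simulation
#'
#' Defaults describe a plausible imaging regime at calibration imager
#' concentration: mean dark time 50 s (influx rate 0.02 events/s per binding
#' sequence), mean bright time 0.5 s, 100 ms exposure, ~7 nm localization
#' precision. 80,000 frames is the NND-imaging convention; use 160,000 for
#' qPAINT counting.
#'
#' @param influx_rate imager influx rate per binding sequence (events/s).
#' @param mean_bright_time mean bright (bound) duration in s.
#' @param n_frames number of acquisition frames.
#' @param exposure_ms exposure per frame (ms).
#' @param sigma isotropic localization precision (nm).
#' @param mean_photons mean photon count per localization.
#' @param frame_overlap minimum fraction of the exposure a binding event
#'   must cover for a frame to yield a localization.
#' @return a `kinetics_config` list.
#' @export
kinetics_config <- function(influx_rate = 0.02, mean_bright_time = 0.5,
                            n_frames = 80000, exposure_ms = 100, sigma = 7,
                            mean_photons = 2000, frame_overlap = 0.5) {
  if (influx_rate < 0) stop("influx_rate must be >= 0")
  if (mean_bright_time <= 0) stop("mean_bright_time must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (mean_photons <= 0) stop("mean_photons must be > 0")
  structure(list(influx_rate = influx_rate,
                 mean_bright_time = mean_bright_time,
                 n_frames = as.integer(n_frames), exposure_ms = exposure_ms,
                 sigma = sigma, mean_photons = mean_photons,
                 frame_overlap = frame_overlap),
            class = "kinetics_config")
}

#' Generate a DNA-origami-style grid of docking sites
#'
#' @param rows,cols grid dimensions.
#' @param spacing lattice spacing in nm (20 nm for the standard grid).
#' @param sites_per_position number of concatenated binding sequences per
#'   docking position (1 or 3 for the usual constructs); scales the binding
#'   event rate in [simulate_kinetics()].
#' @param origin grid origin (nm), lower-left site.
#' @return a `site_layout` data.frame with columns `site`, `x`, `y`.
#' @export
gen_origami_grid <- function(rows, cols, spacing = 20, sites_per_position = 1,
                             origin = c(0, 0)) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (spacing <= 0) stop("spacing must be > 0")
  if (sites_per_position < 1) stop("sites_per_position must be >= 1")
  g <- expand.grid(cx = seq_len(cols) - 1, cy = seq_len(rows) - 1)
  site_layout(origin[1] + g$cx * spacing, origin[2] + g$cy * spacing,
              sites_per_position = sites_per_position, spacing = spacing)
}

#' Construct a docking-site layout
#'
#' @param x,y site coordinates in nm.
#' @param sites_per_position concatenated binding sequences per site.
#' @param spacing nominal lattice spacing (nm), if applicable.
#' @return a `site_layout` data.frame.
#' @export
site_layout <- function(x, y, sites_per_position = 1, spacing = NA_real_) {
  df <- data.frame(site = seq_along(x), x = as.numeric(x), y = as.numeric(y))
  attr(df, "sites_per_position") <- as.integer(sites_per_position)
  attr(df, "spacing") <- spacing
  class(df) <- c("site_layout", "data.frame")
  df
}

new_kinetic_trace <- function(site, start_frame, duration, n_frames) {
  ord <- order(start_frame)
  structure(list(site = site,
                 events = data.frame(start_frame = as.integer(start_frame[ord]),
                                     duration = as.integer(duration[ord])),
                 n_frames = as.integer(n_frames)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace site %s: %d events over %d frames>\n",
              x$site, nrow(x$events), x$n_frames))
  invisible(x)
}

# quantize continuous [t0, t1) bright intervals (seconds) to frames:
# a frame yields a localization if the event covers >= frame_overlap of it.
quantize_events <- function(t0, t1, exposure_s, n_frames, frame_overlap) {
  starts <- integer(0); durs <- integer(0)
  for (i in seq_along(t0)) {
    f0 <- floor(t0[i] / exposure_s); f1 <- floor((t1[i] - 1e-12) / exposure_s)
    f0 <- max(f0, 0); f1 <- min(f1, n_frames - 1)
    if (f1 < f0) next
    fr <- f0:f1
    ov <- pmin(t1[i], (fr + 1) * exposure_s) - pmax(t0[i], fr * exposure_s)
    fr <- fr[ov >= frame_overlap * exposure_s]
    if (!length(fr)) next
    starts <- c(starts, fr[1]); durs <- c(durs, fr[length(fr)] - fr[1] + 1)
  }
  if (!length(starts)) return(data.frame(start_frame = integer(0),
                                         duration = integer(0)))
  # merge events separated by zero-frame gaps after quantization
  ord <- order(starts)
  starts <- starts[ord]; durs <- durs[ord]
  ms <- starts[1]; md <- durs[1]
  out_s <- integer(0); out_d <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ms + md) {
      md <- max(ms + md, starts[i] + durs[i]) - ms
    } else {
      out_s <- c(out_s, ms); out_d <- c(out_d, md)
      ms <- starts[i]; md <- durs[i]
    }
  }
  data.frame(start_frame = c(out_s, ms), duration = c(out_d, md))
}

#' Simulate imager binding kinetics for a site layout
#'
#' Each docking site runs an alternating dark/bright renewal process: dark
#' durations are exponential with rate `influx_rate * sites_per_position`,
#' bright durations exponential with mean `mean_bright_time`. Continuous
#' events are quantized to frames and merged where quantization closes the
#' gap between them.
#'
#' @param layout a `site_layout`.
#' @param cfg a `kinetics_config`.
#' @param seed optional seed.
#' @return a list of `kinetic_trace`, one per site.
#' @export
simulate_kinetics <- function(layout, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "kinetics_config"))
  local_seed(seed)
  spp <- attr(layout, "sites_per_position")
  if (is.null(spp)) spp <- 1L
  rate <- cfg$influx_rate * spp
  exposure_s <- cfg$exposure_ms / 1000
  total_s <- cfg$n_frames * exposure_s
  lapply(seq_len(nrow(layout)), function(i) {
    t0 <- numeric(0); t1 <- numeric(0)
    if (rate > 0) {
      t <- 0
      repeat {
        t <- t + rexp(1, rate)
        if (t >= total_s) break
        dur <- rexp(1, 1 / cfg$mean_bright_time)
        t0 <- c(t0, t); t1 <- c(t1, min(t + dur, total_s))
        t <- t + dur
        if (t >= total_s) break
      }
    }
    ev <- quantize_events(t0, t1, exposure_s, cfg$n_frames, cfg$frame_overlap)
    new_kinetic_trace(layout$site[i], ev$start_frame, ev$duration,
                      cfg$n_frames)
  })
}

#' Occupied frames of a kinetic trace
#'
#' @param trace a `kinetic_trace`.
#' @return integer vector of 0-based occupied frame indices.
#' @export
occupied_frames <- function(trace) {
  ev <- trace$events
  if (!nrow(ev)) return(integer(0))
  unlist(lapply(seq_len(nrow(ev)),
                function(i) ev$start_frame[i] + seq_len(ev$duration[i]) - 1L))
}

#' Render kinetic traces into a localization table
#'
#' One localization per occupied frame per site, positioned at the site
#' coordinate plus isotropic Gaussian noise of SD `sigma`; photon counts are
#' geometric positive integers around `mean_photons`.
#'
#' @param traces list of `kinetic_trace` (one per layout row).
#' @param layout the `site_layout` the traces were simulated from.
#' @param cfg the `kinetics_config` used.
#' @param seed optional seed.
#' @param keep_site keep a `site` column linking localizations to their
#'   ground-truth site (default TRUE; dropped on file export if unwanted).
#' @return a `loc_table`.
#' @export
render_localizations <- function(traces, layout, cfg, seed = NULL,
                                 keep_site = TRUE) {
  stopifnot(length(traces) == nrow(layout))
  local_seed(seed)
  frames <- lapply(traces, occupied_frames)
  n_per <- vapply(frames, length, integer(1))
  n <- sum(n_per)
  site_idx <- rep(seq_len(nrow(layout)), n_per)
  fr <- unlist(frames)
  if (n == 0) fr <- integer(0)
  x <- layout$x[site_idx] + rnorm(n, 0, cfg$sigma)
  y <- layout$y[site_idx] + rnorm(n, 0, cfg$sigma)
  photons <- rgeom(n, 1 / cfg$mean_photons) + 1
  tab <- loc_table(x, y, fr, photons = photons,
                   precision = rep(max(cfg$sigma, 1e-6), n),
                   n_frames = cfg$n_frames)
  if (keep_site) tab$site <- layout$site[site_idx]
  tab
}
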