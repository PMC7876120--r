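# Automated localization-cloud detection: DBSCAN with a constant parameter
# set, temporal plausibility filters (mean-frame and std-frame), NeNA
# localization-precision estimation, and detection-efficiency scoring
# against simulation ground truth.

#' Clustering parameter set
#'
#' `eps` defaults to the dataset's NeNA localization precision (set it
#' explicitly or via [nena_precision()]); `min_pts` defaults, when a
#' kinetics configuration is given, to `max(10, 0.3 * expected localizations
#' per binding site)` so the threshold tracks the imager binding frequency.
#'
#' @param eps DBSCAN neighbourhood radius in nm.
#' @param min_pts minimum localizations within `eps` (the point itself
#'   counts).
#' @param n_frames acquisition length in frames.
#' @param mean_frame_sd_multiplier cut-off width of the mean-frame filter in
#'   units of the population spread.
#' @param std_frame_min_fraction minimum cluster `std_frame` as a fraction
#'   of `n_frames` (uniform temporal coverage gives 1/sqrt(12) = 0.289).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(eps, min_pts, n_frames,
                           mean_frame_sd_multiplier = 1.0,
                           std_frame_min_fraction = 0.2) {
  if (eps <= 0) stop("eps must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  if (mean_frame_sd_multiplier <= 0 || std_frame_min_fraction < 0)
    stop("filter multipliers must be positive")
  structure(list(eps = eps, min_pts = as.integer(ceiling(min_pts)),
                 n_frames = as.integer(n_frames),
                 mean_frame_sd_multiplier = mean_frame_sd_multiplier,
                 std_frame_min_fraction = std_frame_min_fraction),
            class = "cluster_params")
}

#' Expected localizations per binding site under a kinetics configuration
#'
#' influx rate x acquisition time x mean bright frames per event; the basis
#' of the default `min_pts`.
#'
#' @param cfg a `kinetics_config`.
#' @return expected localization count for a single binding sequence.
#' @export
expected_locs_per_site <- function(cfg) {
  exposure_s <- cfg$exposure_ms / 1000
  cfg$influx_rate * (cfg$n_frames * exposure_s) *
    (cfg$mean_bright_time / exposure_s)
}

#' @rdname expected_locs_per_site
#' @export
default_min_pts <- function(cfg) {
  max(10L, as.integer(round(0.3 * expected_locs_per_site(cfg))))
}

#' NeNA localization-precision estimate
#'
#' Estimates the localization precision from nearest-neighbour displacements
#' between localizations in consecutive frames: repeated visits to the same
#' site make those displacements Rayleigh-distributed with scale
#' `sigma * sqrt(2)`. The scale is fitted by maximum likelihood on the
#' distances below `max_radius` (truncation handled in the likelihood).
#'
#' @param table a `loc_table` with repeated visits across frames.
#' @param max_radius pairing cap in nm; displacements beyond it are treated
#'   as cross-site pairs and dropped.
#' @return the precision estimate sigma in nm.
#' @export
nena_precision <- function(table, max_radius = 100) {
  if (nrow(table) < 4) stop("too few localizations for NeNA estimation")
  ord <- order(table$frame, table$x, table$y)
  d <- cpp_consecutive_nn(table$x[ord], table$y[ord],
                          as.integer(table$frame[ord]), max_radius)
  if (length(d) < 5)
    stop("too few consecutive-frame localization pairs for NeNA estimation")
  nll <- function(sigma) {
    s2 <- 2 * sigma^2
    trunc <- 1 - exp(-max_radius^2 / (2 * s2))
    -(sum(log(d) - d^2 / (2 * s2)) - length(d) * (log(s2) + log(trunc)))
  }
  optimize(nll, c(1e-3, max_radius))$minimum
}

new_cluster_set <- function(clusters, members, params) {
  structure(list(clusters = clusters, members = members, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters (eps = %.3g nm, min_pts = %d)>\n",
              nrow(x$clusters), x$params$eps, x$params$min_pts))
  invisible(x)
}

#' Number of clusters
#' @param x a `cluster_set`.
#' @return integer count.
#' @export
n_clusters <- function(x) nrow(x$clusters)

convex_hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  shoelace_area_nm2(cbind(x[h], y[h]))
}

#' Detect localization clouds with DBSCAN
#'
#' Standard DBSCAN core/border/noise semantics on the (x, y) coordinates;
#' noise localizations belong to no cluster. The input is sorted by
#' (frame, x, y) before clustering so border-point assignment (first core
#' cluster reaching them) does not depend on row order.
#'
#' @param table a `loc_table` in nm.
#' @param params a `cluster_params`.
#' @param species species tag copied onto the cluster records (taken from
#'   the table if it is single-species).
#' @return a `cluster_set`: per-cluster records (`id`, centroid `x`/`y`,
#'   `n_locs`, `mean_frame`, `std_frame`, `area_nm2`, `species`) plus the
#'   member localization indices (into the original table).
#' @export
dbscan_clusters <- function(table, params, species = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      n_locs = integer(0), mean_frame = numeric(0),
                      std_frame = numeric(0), area_nm2 = numeric(0),
                      species = character(0))
  if (nrow(table) == 0) return(new_cluster_set(empty, list(), params))
  if (is.null(species)) {
    sp <- unique(table$species)
    species <- if (length(sp) == 1 && !is.null(sp)) sp else NA_character_
  }
  ord <- order(table$frame, table$x, table$y)
  labels <- cpp_dbscan(table$x[ord], table$y[ord], params$eps, params$min_pts)
  keep <- labels > 0
  if (!any(keep)) return(new_cluster_set(empty, list(), params))
  idx_by_cluster <- split(ord[keep], labels[keep])
  recs <- lapply(seq_along(idx_by_cluster), function(i) {
    m <- idx_by_cluster[[i]]
    data.frame(id = i, x = mean(table$x[m]), y = mean(table$y[m]),
               n_locs = length(m), mean_frame = mean(table$frame[m]),
               std_frame = sd_pop(table$frame[m]),
               area_nm2 = convex_hull_area(table$x[m], table$y[m]),
               species = species)
  })
  new_cluster_set(do.call(rbind, recs), unname(idx_by_cluster), params)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

subset_cluster_set <- function(cs, keep) {
  cl <- cs$clusters[keep, , drop = FALSE]
  if (nrow(cl)) cl$id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  new_cluster_set(cl, cs$members[keep], cs$params)
}

#' Mean-frame filter
#'
#' Clusters produced by genuine repetitive imager binding have a mean frame
#' near half the acquisition; transient contaminations sit early or late.
#' The population of cluster `mean_frame`s is summarized by a robust centre
#' and spread (median and 1.4826 x MAD by default) and clusters outside
#' centre +/- multiplier x spread are removed.
#'
#' @param cs a `cluster_set`.
#' @param multiplier cut-off width (defaults to the value in the cluster
#'   params).
#' @param robust use median/MAD (default) instead of mean/SD.
#' @return the filtered `cluster_set`.
#' @export
mean_frame_filter <- function(cs, multiplier = NULL, robust = TRUE) {
  if (is.null(multiplier)) multiplier <- cs$params$mean_frame_sd_multiplier
  mf <- cs$clusters$mean_frame
  if (length(mf) < 2) {
    warning("fewer than 2 clusters; mean-frame filter passed through")
    return(cs)
  }
  # the cut-off belongs to the population fit of the detected clusters; a
  # set that was already filtered keeps its original fit, which makes the
  # filter idempotent
  fit <- cs$mean_frame_fit
  if (is.null(fit)) {
    fit <- if (robust) c(centre = median(mf), spread = mad(mf))
           else c(centre = mean(mf), spread = sd(mf))
  }
  out <- subset_cluster_set(cs, abs(mf - fit[["centre"]]) <=
                              multiplier * fit[["spread"]] + 1e-9)
  out$mean_frame_fit <- fit
  out
}

#' Standard-deviation-frame filter
#'
#' Removes clusters whose localizations bunch into a short stretch of the
#' acquisition (imager sticking): a single contiguous event of length L has
#' `std_frame = L / sqrt(12)`, far below the `n_frames / sqrt(12)` of
#' uniformly repetitive binding. Clusters with
#' `std_frame < min_fraction * n_frames` are removed.
#'
#' @param cs a `cluster_set`.
#' @param n_frames acquisition length (defaults to the cluster params).
#' @param min_fraction threshold fraction (default from params, 0.2).
#' @return the filtered `cluster_set`.
#' @export
std_frame_filter <- function(cs, n_frames = NULL, min_fraction = NULL) {
  if (is.null(n_frames)) n_frames <- cs$params$n_frames
  if (is.null(min_fraction)) min_fraction <- cs$params$std_frame_min_fraction
  if (!nrow(cs$clusters)) return(cs)
  subset_cluster_set(cs, cs$clusters$std_frame >= min_fraction * n_frames)
}

#' Full detection pipeline: DBSCAN plus both temporal filters
#'
#' @inheritParams dbscan_clusters
#' @return a filtered `cluster_set`.
#' @export
detect_clusters <- function(table, params, species = NULL) {
  cs <- dbscan_clusters(table, params, species = species)
  if (nrow(cs$clusters) >= 2) cs <- mean_frame_filter(cs)
  std_frame_filter(cs)
}

#' Detection efficiency against simulation ground truth
#'
#' Greedy one-to-one matching of cluster centroids to labeled ground-truth
#' molecules: candidate pairs within `match_radius` are processed by
#' increasing distance (ties by lower cluster index), each centroid and each
#' molecule used at most once. DE = matched / total labeled molecules.
#'
#' @param cs a `cluster_set` (or a data.frame with `x`, `y` centroids).
#' @param ground_truth a `molecule_set`; only `labeled` molecules count.
#' @param match_radius maximum centroid-to-truth distance in nm.
#' @return a list: `de`, `n_matched`, `n_truth`, `matches` (two-column
#'   matrix of cluster/truth indices).
#' @export
detection_efficiency <- function(cs, ground_truth, match_radius = 25) {
  cents <- if (inherits(cs, "cluster_set")) cs$clusters else as.data.frame(cs)
  truth <- labeled_points(ground_truth)
  if (nrow(truth) == 0) stop("ground truth contains no labeled molecules")
  nc <- nrow(cents)
  if (nc == 0)
    return(list(de = 0, n_matched = 0L, n_truth = nrow(truth),
                matches = cbind(cluster = integer(0), truth = integer(0))))
  k <- min(nrow(truth), 16L)
  nn <- cpp_knn(cents$x, cents$y, truth$x, truth$y, k, FALSE)
  pairs <- data.frame(cluster = rep(seq_len(nc), k),
                      truth = as.vector(nn$index),
                      d = as.vector(nn$dist))
  pairs <- pairs[!is.na(pairs$d) & pairs$d <= match_radius, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$cluster, pairs$truth), , drop = FALSE]
  used_c <- logical(nc); used_t <- logical(nrow(truth))
  mc <- integer(0); mt <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    ci <- pairs$cluster[i]; ti <- pairs$truth[i]
    if (!used_c[ci] && !used_t[ti]) {
      used_c[ci] <- TRUE; used_t[ti] <- TRUE
      mc <- c(mc, ci); mt <- c(mt, ti)
    }
  }
  list(de = length(mc) / nrow(truth), n_matched = length(mc),
       n_truth = nrow(truth), matches = cbind(cluster = mc, truth = mt))
}
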