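# Ternary complex analysis: anchored nearest-neighbour tuples (for each
# anchor molecule the distances to its nearest neighbour in two other
# species), 2D two-sample Kolmogorov-Smirnov comparison, and the bootstrap
# procedure contrasting observed tuple clouds with CSR simulations.

#' Anchored nearest-neighbour tuples
#'
#' For each anchor molecule (e.g. an active integrin receptor) the exact
#' distance to its nearest molecule in each of two reference species (e.g.
#' kindlin and talin), giving one (d_k, d_t) tuple per anchor.
#'
#' @param anchors anchor point set.
#' @param set_k,set_t the two reference sets.
#' @return a `tuple_set` data.frame with columns `d1`, `d2` (nm).
#' @export
i2kt_tuples <- function(anchors, set_k, set_t) {
  anc <- as_xy(anchors); pk <- as_xy(set_k); pt <- as_xy(set_t)
  if (nrow(anc) == 0) stop("anchor set is empty")
  if (nrow(pk) == 0 || nrow(pt) == 0) stop("reference sets must be non-empty")
  d1 <- cpp_knn(anc$x, anc$y, pk$x, pk$y, 1L, FALSE)$dist[, 1]
  d2 <- cpp_knn(anc$x, anc$y, pt$x, pt$y, 1L, FALSE)$dist[, 1]
  out <- data.frame(d1 = d1, d2 = d2)
  class(out) <- c("tuple_set", "data.frame")
  out
}

#' 2D relative-frequency grid of a tuple set
#'
#' @param tuples a `tuple_set`.
#' @param bin_width bin width in nm.
#' @param max_dist grid extent (defaults to the largest tuple coordinate).
#' @return a matrix (rows = `d1` bins, cols = `d2` bins) summing to 1, with
#'   bin `breaks` as an attribute.
#' @export
tuple_heatmap <- function(tuples, bin_width = 5, max_dist = NULL) {
  if (!nrow(tuples)) stop("empty tuple set")
  if (is.null(max_dist)) max_dist <- max(tuples$d1, tuples$d2)
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  b1 <- cut(tuples$d1, breaks, include.lowest = TRUE, labels = FALSE)
  b2 <- cut(tuples$d2, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1
  grid <- matrix(0, nb, nb)
  for (i in seq_len(nrow(tuples))) grid[b1[i], b2[i]] <- grid[b1[i], b2[i]] + 1
  grid <- grid / sum(grid)
  attr(grid, "breaks") <- breaks
  grid
}

#' Two-sample 2D Kolmogorov-Smirnov statistic
#'
#' Fasano-Franceschini-style statistic: the maximum, over all data points of
#' both samples and the four quadrant orientations around each, of the
#' absolute difference in empirical quadrant fractions. Points on a
#' quadrant boundary count toward the quadrant closed on both axes.
#'
#' @param sample_a,sample_b `tuple_set`s (or any two-column tables),
#'   each with >= 10 rows.
#' @return the statistic D in `[0, 1]`.
#' @export
ks2d <- function(sample_a, sample_b) {
  a <- tuple_xy(sample_a); b <- tuple_xy(sample_b)
  if (nrow(a) < 10 || nrow(b) < 10) stop("both samples need >= 10 tuples")
  if (max(var(a[, 1]), var(a[, 2])) == 0 || max(var(b[, 1]), var(b[, 2])) == 0)
    warning("degenerate (all-identical) sample in ks2d")
  cpp_ks2d(a[, 1], a[, 2], b[, 1], b[, 2])
}

tuple_xy <- function(s) {
  df <- as.data.frame(s)
  if (!is.null(df$d1)) as.matrix(df[, c("d1", "d2")])
  else as.matrix(df[, 1:2])
}

#' Bootstrap 2D Kolmogorov-Smirnov comparison of two tuple clouds
#'
#' Per run, `subsample` tuples are drawn without replacement from each set
#' and D computed; the cross-set distribution of D is summarized by mean and
#' SD. The null distribution is built by within-set self-comparison (each
#' run splits one set into two disjoint subsamples), and the p-value is the
#' fraction of null D draws at least as large as the mean cross-set D.
#'
#' @param sample_a,sample_b `tuple_set`s.
#' @param subsample tuples drawn per set per run (reduced with a warning if
#'   a set is too small).
#' @param runs bootstrap runs.
#' @param seed seed.
#' @return a `ks_result`: `D_mean`, `D_sd`, `p_value`, `D_values`,
#'   `null_values`, `subsample`, `runs`.
#' @export
bootstrap_compare <- function(sample_a, sample_b, subsample = 1000,
                              runs = 1000, seed = NULL) {
  a <- tuple_xy(sample_a); b <- tuple_xy(sample_b)
  na <- nrow(a); nb <- nrow(b)
  if (min(na, nb) < 20) stop("samples too small for bootstrap comparison")
  sub <- min(subsample, na, nb)
  if (sub < subsample)
    warning("subsample reduced to ", sub, " (smallest sample size)")
  sub_null <- min(sub, floor(na / 2), floor(nb / 2))
  local_seed(seed)
  D <- vapply(seq_len(runs), function(r) {
    ia <- sample.int(na, sub); ib <- sample.int(nb, sub)
    cpp_ks2d(a[ia, 1], a[ia, 2], b[ib, 1], b[ib, 2])
  }, numeric(1))
  null_one <- function(m, n) {
    idx <- sample.int(n, 2 * sub_null)
    i1 <- idx[seq_len(sub_null)]; i2 <- idx[sub_null + seq_len(sub_null)]
    cpp_ks2d(m[i1, 1], m[i1, 2], m[i2, 1], m[i2, 2])
  }
  null_D <- c(vapply(seq_len(ceiling(runs / 2)), function(r) null_one(a, na),
                     numeric(1)),
              vapply(seq_len(ceiling(runs / 2)), function(r) null_one(b, nb),
                     numeric(1)))
  structure(list(D_mean = mean(D),
                 D_sd = if (runs > 1) sd(D) else NA_real_,
                 p_value = mean(null_D >= mean(D)),
                 D_values = D, null_values = null_D,
                 subsample = sub, runs = runs),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result: D = %.4f +/- %.4f, p = %.4g (%d runs x %d tuples)>\n",
              x$D_mean, x$D_sd, x$p_value, x$runs, x$subsample))
  invisible(x)
}
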