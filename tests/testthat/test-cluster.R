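# Cluster pipeline: DBSCAN against a brute-force oracle, temporal filters,
# NeNA precision recovery, detection-efficiency matching.

sim_site_table <- function(sites_x, sites_y, cfg, seed) {
  lay <- site_layout(sites_x, sites_y)
  tr <- simulate_kinetics(lay, cfg, seed = seed)
  render_localizations(tr, lay, cfg, seed = seed + 1)
}

test_that("NeNA recovers the simulated localization precision", {
  cfg <- kinetics_config(n_frames = 80000, sigma = 7)
  tab <- sim_site_table(c(500, 1500), c(500, 500), cfg, seed = 21)
  expect_equal(nena_precision(tab), 7, tolerance = 0.10)

  cfg2 <- kinetics_config(n_frames = 80000, sigma = 2)
  tab2 <- sim_site_table(500, 500, cfg2, seed = 22)
  s2 <- nena_precision(tab2)
  expect_equal(s2, 2, tolerance = 0.10)

  cfg4 <- kinetics_config(n_frames = 80000, sigma = 4)
  tab4 <- sim_site_table(500, 500, cfg4, seed = 22)
  expect_equal(nena_precision(tab4) / s2, 2, tolerance = 0.15)

  expect_error(nena_precision(loc_table(1:3, 1:3, c(0, 5, 9))), "too few")
})

test_that("DBSCAN matches a brute-force neighbourhood-graph oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    # mixture of tight blobs and sparse noise, <= 500 points
    centres <- cbind(runif(6, 100, 900), runif(6, 100, 900))
    blob <- do.call(rbind, lapply(1:6, function(i)
      cbind(rnorm(50, centres[i, 1], 5), rnorm(50, centres[i, 2], 5))))
    noise <- cbind(runif(80, 0, 1000), runif(80, 0, 1000))
    pts <- rbind(blob, noise)
    tab <- loc_table(pts[, 1], pts[, 2], seq_len(nrow(pts)) - 1L)
    eps <- 8; min_pts <- 10
    cs <- dbscan_clusters(tab, cluster_params(eps, min_pts, nrow(pts)))
    oracle <- dbscan_oracle(tab$x, tab$y, eps, min_pts)

    member <- rep(0L, nrow(tab))
    for (i in seq_along(cs$members)) member[cs$members[[i]]] <- i
    # noise sets agree exactly
    expect_identical(unname(member == 0L), unname(oracle$noise))
    # core-point partitions agree up to label permutation
    core <- oracle$core
    expect_true(all(member[core] > 0))
    tab_lab <- table(member[core], oracle$core_label[core])
    expect_true(all(rowSums(tab_lab > 0) == 1) &&
                  all(colSums(tab_lab > 0) == 1))
  }
})

test_that("sparse uniform noise yields no clusters and empty input no error", {
  set.seed(30)
  tab <- loc_table(runif(400, 0, 5000), runif(400, 0, 5000), 0:399)
  cs <- dbscan_clusters(tab, cluster_params(7, 20, 400))
  expect_equal(n_clusters(cs), 0)
  empty <- dbscan_clusters(loc_table(numeric(0), numeric(0), integer(0)),
                           cluster_params(7, 20, 400))
  expect_equal(n_clusters(empty), 0)
})

test_that("cluster records equal direct recomputation from members", {
  cfg <- kinetics_config(n_frames = 40000)
  tab <- sim_site_table(c(300, 800, 1300), c(300, 300, 300), cfg, seed = 31)
  cs <- dbscan_clusters(tab, cluster_params(7, 50, cfg$n_frames))
  expect_gt(n_clusters(cs), 0)
  for (i in seq_len(n_clusters(cs))) {
    m <- cs$members[[i]]
    expect_equal(cs$clusters$x[i], mean(tab$x[m]))
    expect_equal(cs$clusters$mean_frame[i], mean(tab$frame[m]))
    expect_equal(cs$clusters$std_frame[i],
                 sqrt(mean((tab$frame[m] - mean(tab$frame[m]))^2)))
    expect_gte(cs$clusters$n_locs[i], 50)
  }
})

make_cluster_set <- function(mean_frames, std_frames, n_frames = 80000) {
  n <- length(mean_frames)
  cl <- data.frame(id = seq_len(n), x = seq_len(n) * 100,
                   y = rep(0, n), n_locs = rep(100L, n),
                   mean_frame = mean_frames, std_frame = std_frames,
                   area_nm2 = rep(400, n),
                   species = rep(NA_character_, n))
  qsmcl:::new_cluster_set(cl, as.list(seq_len(n)),
                          cluster_params(7, 10, n_frames))
}

test_that("mean-frame filter removes temporally clumped clusters", {
  # population centred at half the acquisition; one early-burst outlier
  mf <- c(rnorm(30, 40000, 1500), 2000)
  cs <- make_cluster_set(mf, rep(23000, 31))
  kept <- mean_frame_filter(cs)
  expect_false(2000 %in% kept$clusters$mean_frame)
  # all-identical temporal structure: everything retained
  cs_same <- make_cluster_set(rep(40000, 10), rep(23000, 10))
  expect_equal(n_clusters(mean_frame_filter(cs_same)), 10)
  # idempotence
  expect_equal(mean_frame_filter(kept)$clusters$mean_frame,
               kept$clusters$mean_frame)
  # degenerate population passes through with a warning
  cs1 <- make_cluster_set(500, 100)
  expect_warning(mean_frame_filter(cs1), "fewer than 2")
})

test_that("std-frame filter removes sticking events", {
  n_frames <- 80000
  # contiguous 200-frame sticking block: SD = 200/sqrt(12) ~ 58 frames
  stick_sd <- 200 / sqrt(12)
  uniform_sd <- n_frames / sqrt(12)
  cs <- make_cluster_set(c(40000, 40100), c(uniform_sd, stick_sd), n_frames)
  kept <- std_frame_filter(cs)
  expect_equal(n_clusters(kept), 1)
  expect_equal(kept$clusters$std_frame, uniform_sd)
  # uniform temporal coverage (0.289 n_frames) clears the 0.2 cut-off
  expect_gt(uniform_sd, 0.2 * n_frames)
  # idempotent, and empty input passes through
  expect_equal(n_clusters(std_frame_filter(kept)), 1)
  empty <- make_cluster_set(numeric(0), numeric(0))
  expect_equal(n_clusters(std_frame_filter(empty)), 0)
})

test_that("detection efficiency scores greedy centroid matching", {
  truth <- qsmcl:::new_molecule_set(c(100, 300, 500, 700), rep(100, 4))
  cents <- data.frame(x = c(101, 299, 501, 699), y = rep(100.5, 4))
  expect_equal(detection_efficiency(cents, truth, 25)$de, 1.0)
  expect_equal(detection_efficiency(cents[1:2, ], truth, 25)$de, 0.5)
  expect_error(detection_efficiency(cents,
                                    qsmcl:::new_molecule_set(1, 1, FALSE)),
               "no labeled")
})

test_that("greedy matching equals optimal assignment on sparse instances", {
  skip_if_not_installed("igraph")
  for (seed in 1:8) {
    set.seed(seed)
    nt <- sample(8:20, 1)
    truth <- qsmcl:::new_molecule_set(runif(nt, 0, 2000), runif(nt, 0, 2000))
    nc <- sample(5:nt, 1)
    keep <- sample(nt, nc)
    cents <- data.frame(x = truth$x[keep] + rnorm(nc, 0, 4),
                        y = truth$y[keep] + rnorm(nc, 0, 4))
    res <- detection_efficiency(cents, truth, match_radius = 20)
    # maximum-cardinality bipartite matching oracle
    d <- outer(seq_len(nc), seq_len(nt), function(i, j)
      sqrt((cents$x[i] - truth$x[j])^2 + (cents$y[i] - truth$y[j])^2))
    pairs <- which(d <= 20, arr.ind = TRUE)
    g <- igraph::make_bipartite_graph(
      c(rep(TRUE, nc), rep(FALSE, nt)),
      edges = as.vector(t(cbind(pairs[, 1], nc + pairs[, 2]))))
    opt <- igraph::max_bipartite_match(g)$matching_size
    expect_equal(res$n_matched, opt)
  }
})
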