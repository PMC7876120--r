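# Independent brute-force oracles used to validate the spatial core, plus
# small fixture builders. Oracles deliberately use naive all-pairs
# computations so they share no code path with the implementations they
# check.

# all-pairs k-th nearest-neighbour distances
nnd_oracle <- function(src, ref = NULL, k = 1) {
  self <- is.null(ref)
  if (self) ref <- src
  apply(as.matrix(src), 1, function(p) {
    d <- sqrt((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2)
    if (self) d <- d[-which.min(abs(d))]  # drop the zero self-distance
    sort(d)[k]
  })
}

# naive DBSCAN: core points from neighbour counts, clusters as connected
# components of the core-core adjacency, noise = not within eps of any core
dbscan_oracle <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  lab <- rep(0L, n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v] != 0L) next
      lab[v] <- cl
      queue <- c(queue, which(nb[v, ] & core & lab == 0L))
    }
  }
  reached <- if (any(core)) apply(nb[, core, drop = FALSE], 1, any)
             else rep(FALSE, n)
  list(core = core, core_label = lab, noise = !reached)
}

# quadrant-scan 2D KS oracle (plain R, no shared code with cpp_ks2d)
ks2d_oracle <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  qf <- function(m, px, py) {
    lx <- m[, 1] <= px; ly <- m[, 2] <= py
    c(mean(lx & ly), mean(lx & !ly), mean(!lx & ly), mean(!lx & !ly))
  }
  pts <- rbind(a, b)
  D <- 0
  for (i in seq_len(nrow(pts))) {
    dd <- max(abs(qf(a, pts[i, 1], pts[i, 2]) - qf(b, pts[i, 1], pts[i, 2])))
    if (dd > D) D <- dd
  }
  D
}

# kinetics with (near-)lossless frame quantization, for renewal-process
# oracle checks where detection losses must not enter
lossless_kinetics <- function(...) {
  kinetics_config(..., frame_overlap = 1e-9)
}

# random localization table fixture
random_loc_table <- function(n, seed = 1, n_frames = 1000) {
  set.seed(seed)
  loc_table(runif(n, 0, 5000), runif(n, 0, 5000),
            sample(0:(n_frames - 1), n, replace = TRUE),
            photons = rpois(n, 800), precision = runif(n, 5, 9),
            n_frames = n_frames)
}
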