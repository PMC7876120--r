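# Synthetic molecule fields: homogeneous Poisson layouts, two-species
# complexed populations, stochastic labeling, and striped micropatterns.
# Densities are molecules per square micrometre; coordinates are nm.

new_molecule_set <- function(x, y, labeled = TRUE, partner = NA_integer_,
                             region = NULL, species = "A") {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   labeled = rep_len(as.logical(labeled), length(x)),
                   partner = rep_len(as.integer(partner), length(x)))
  if (!is.null(region)) df$region <- region
  attr(df, "species") <- species
  class(df) <- c("molecule_set", "data.frame")
  df
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set '%s': %d molecules, %d labeled>\n",
              attr(x, "species"), nrow(x), sum(x$labeled)))
  invisible(x)
}

#' Labeled subset of a molecule set
#'
#' @param set a `molecule_set`.
#' @return the rows with `labeled == TRUE`.
#' @export
labeled_points <- function(set) {
  if (is.null(set$labeled)) return(set)
  out <- set[set$labeled, , drop = FALSE]
  attr(out, "species") <- attr(set, "species")
  class(out) <- class(set)
  out
}

sample_uniform_in_mask <- function(n, roi) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  v <- roi$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  out <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    m <- max(2 * (n - got), 100)
    px <- runif(m, xr[1], xr[2]); py <- runif(m, yr[1], yr[2])
    keep <- in_mask(px, py, roi)
    take <- min(sum(keep), n - got)
    if (take > 0) {
      idx <- which(keep)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Generate a homogeneous 2D Poisson molecule field
#'
#' The number of molecules is Poisson with mean `density * area`, positions
#' i.i.d. uniform over the mask (complete spatial randomness).
#'
#' @param density molecules per um^2 (>= 0).
#' @param roi a `region_mask`.
#' @param seed optional seed.
#' @param species species tag.
#' @return a `molecule_set`.
#' @export
gen_random_field <- function(density, roi, seed = NULL, species = "A") {
  if (!is.numeric(density) || density < 0) stop("density must be >= 0")
  local_seed(seed)
  n <- rpois(1, density * roi$area_um2)
  p <- sample_uniform_in_mask(n, roi)
  new_molecule_set(p[, "x"], p[, "y"], species = species)
}

#' Generate a two-species population with a tunable complexed fraction
#'
#' Species A is a plain random field. A fraction `complex_fraction` of
#' species-B molecules is placed at a distance drawn uniformly from
#' `dist_range` (default 12-16 nm, the measured tag-to-tag distance of a
#' tandem-tag control construct), at uniform angle, around a distinct
#' species-A partner; the rest of B is uniform over the mask.
#'
#' @param density_a,density_b molecular densities (molecules/um^2).
#' @param complex_fraction fraction of B molecules in complexes, in `[0, 1]`.
#' @param dist_range complex pair-distance range in nm, `c(low, high)`.
#' @param roi a `region_mask`.
#' @param seed optional seed.
#' @param species names for the two species.
#' @return a list with `molecule_set`s `a` and `b`; complexed B rows carry
#'   `partner` = row index of their A partner.
#' @export
gen_complex_population <- function(density_a, density_b, complex_fraction,
                                   dist_range = c(12, 16), roi, seed = NULL,
                                   species = c("A", "B")) {
  if (complex_fraction < 0 || complex_fraction > 1)
    stop("complex_fraction must be in [0, 1]")
  if (length(dist_range) != 2 || any(dist_range <= 0) ||
      dist_range[1] > dist_range[2])
    stop("dist_range must be positive with low <= high")
  local_seed(seed)
  a <- gen_random_field(density_a, roi, species = species[1])
  nb <- rpois(1, density_b * roi$area_um2)
  n_cx <- round(complex_fraction * nb)
  if (nrow(a) == 0 && n_cx > 0)
    stop("no species-A molecules to host complexes")
  # partners drawn without replacement (1:1 complexes); if Poisson count
  # fluctuations leave more complexed B than A molecules, the overflow
  # reuses partners
  partners <- if (n_cx > 0) {
    base <- sample.int(nrow(a), min(n_cx, nrow(a)))
    if (n_cx > nrow(a))
      c(base, sample.int(nrow(a), n_cx - nrow(a), replace = TRUE))
    else base
  } else integer(0)
  bx <- numeric(nb); by <- numeric(nb)
  bpartner <- rep(NA_integer_, nb)
  if (n_cx > 0) {
    # batch placement with vectorized in-mask checks; redraw the (rare)
    # draws that land outside the mask near its boundary
    px <- py <- rep(NA_real_, n_cx)
    todo <- seq_len(n_cx)
    for (round in seq_len(200)) {
      if (!length(todo)) break
      r <- runif(length(todo), dist_range[1], dist_range[2])
      th <- runif(length(todo), 0, 2 * pi)
      cx <- a$x[partners[todo]] + r * cos(th)
      cy <- a$y[partners[todo]] + r * sin(th)
      ok <- in_mask(cx, cy, roi)
      px[todo[ok]] <- cx[ok]; py[todo[ok]] <- cy[ok]
      todo <- todo[!ok]
    }
    if (length(todo))
      stop("could not place ", length(todo), " complexes inside the mask")
    bx[seq_len(n_cx)] <- px; by[seq_len(n_cx)] <- py
    bpartner[seq_len(n_cx)] <- partners
  }
  if (nb > n_cx) {
    free <- sample_uniform_in_mask(nb - n_cx, roi)
    bx[(n_cx + 1):nb] <- free[, "x"]
    by[(n_cx + 1):nb] <- free[, "y"]
  }
  b <- new_molecule_set(bx, by, partner = bpartner, species = species[2])
  list(a = a, b = b)
}

#' Thin a molecule set by stochastic labeling
#'
#' Every molecule independently keeps its label with probability `le`
#' (labeling efficiency); unlabeled molecules stay in the set with
#' `labeled = FALSE` so ground-truth scoring can still see them.
#'
#' @param set a `molecule_set`.
#' @param le labeling efficiency in `[0, 1]`.
#' @param seed optional seed.
#' @return the set with its `labeled` flags thinned.
#' @export
apply_labeling <- function(set, le, seed = NULL) {
  if (le < 0 || le > 1) stop("labeling efficiency must be in [0, 1]")
  local_seed(seed)
  set$labeled <- set$labeled & (runif(nrow(set)) < le)
  set
}

#' Generate a striped (micropatterned) molecule field
#'
#' Piecewise-homogeneous Poisson field emulating molecules on adhesive
#' stripes separated by passivated gaps: vertical stripes of width
#' `stripe_width` at density `density_stripe`, gaps of width `gap_width` at
#' `density_gap`, repeating along x from the mask origin.
#'
#' @param stripe_width,gap_width stripe and gap widths in nm (defaults
#'   1 um and 2 um).
#' @param density_stripe,density_gap densities (molecules/um^2).
#' @param roi a `region_mask`.
#' @param seed optional seed.
#' @param species species tag.
#' @return a `molecule_set` with a `region` column (`"stripe"`/`"gap"`).
#' @export
gen_striped_field <- function(stripe_width = 1000, gap_width = 2000,
                              density_stripe, density_gap, roi, seed = NULL,
                              species = "A") {
  if (stripe_width <= 0 || gap_width <= 0) stop("widths must be > 0")
  if (density_stripe < 0 || density_gap < 0) stop("densities must be >= 0")
  local_seed(seed)
  rho_max <- max(density_stripe, density_gap)
  if (rho_max == 0) return(new_molecule_set(numeric(0), numeric(0),
                                            region = character(0),
                                            species = species))
  # exact thinning of a dominating homogeneous field
  n <- rpois(1, rho_max * roi$area_um2)
  p <- sample_uniform_in_mask(n, roi)
  x0 <- min(roi$vertices[, 1])
  period <- stripe_width + gap_width
  in_stripe <- ((p[, "x"] - x0) %% period) < stripe_width
  rho <- ifelse(in_stripe, density_stripe, density_gap)
  keep <- runif(n) < rho / rho_max
  new_molecule_set(p[keep, "x"], p[keep, "y"],
                   region = ifelse(in_stripe[keep], "stripe", "gap"),
                   species = species)
}
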