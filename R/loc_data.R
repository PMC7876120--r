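# Localization tables, region masks and run configuration.
#
# Internal length unit is nanometres everywhere; pixels exist only at the I/O
# boundary (camera tables store pixel coordinates, everything downstream is
# nm). Frames are 0-based, half-open [0, n_frames).

LOC_COLUMNS <- c("x", "y", "frame", "photons", "precision", "species")
LOC_MANDATORY <- c("x", "y", "frame")

#' Construct a localization table
#'
#' A localization table is a plain `data.frame` (class `loc_table`) with one
#' row per localization and columns `x`, `y` (nm), `frame` (0-based integer),
#' and optionally `photons`, `precision` (nm) and a free-string `species` tag.
#'
#' @param x,y coordinates in nm.
#' @param frame 0-based acquisition frame index.
#' @param photons photon count per localization (optional).
#' @param precision localization precision in nm (optional).
#' @param species optional species tag (free string).
#' @param n_frames optional total number of frames, stored as an attribute
#'   and used to validate `frame`.
#' @return a `loc_table` data.frame.
#' @export
loc_table <- function(x, y, frame, photons = NULL, precision = NULL,
                      species = NULL, n_frames = NULL) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   frame = as.integer(frame))
  if (!is.null(photons)) df$photons <- as.numeric(photons)
  if (!is.null(precision)) df$precision <- as.numeric(precision)
  if (!is.null(species)) df$species <- as.character(species)
  attr(df, "n_frames") <- if (is.null(n_frames)) NULL else as.integer(n_frames)
  class(df) <- c("loc_table", "data.frame")
  validate_loc_table(df)
}

#' Validate a localization table
#'
#' Checks the structural invariants: finite coordinates, non-negative frames
#' (below `n_frames` when known), non-negative photon counts and strictly
#' positive precision where present.
#'
#' @param table a `loc_table`.
#' @return the table, invisibly passed through.
#' @export
validate_loc_table <- function(table) {
  for (col in LOC_MANDATORY)
    if (is.null(table[[col]]))
      stop("localization table is missing mandatory column '", col, "'")
  if (nrow(table) > 0) {
    if (!all(is.finite(table$x)) || !all(is.finite(table$y)))
      stop("localization coordinates must be finite")
    if (any(table$frame < 0)) stop("frame indices must be >= 0")
    nf <- attr(table, "n_frames")
    if (!is.null(nf) && any(table$frame >= nf))
      stop("frame indices must be < n_frames (", nf, ")")
    if (!is.null(table$photons) && any(table$photons < 0, na.rm = TRUE))
      stop("photon counts must be >= 0")
    if (!is.null(table$precision) && any(table$precision <= 0, na.rm = TRUE))
      stop("localization precision must be > 0")
  }
  table
}

#' Read a localization table from disk
#'
#' The CSV dialect is a plain header + columns file
#' (`x,y,frame,photons,precision[,species]`) with lengths in nm unless
#' `pixel_size_nm` is given, in which case `x`, `y` and `precision` are
#' converted from pixels to nm on ingest.
#'
#' @param path file path.
#' @param dialect file dialect; only `"csv"` is supported.
#' @param pixel_size_nm if the file stores pixel units, the camera pixel size
#'   in nm (typically 130); `NULL` (default) means the file is already in nm.
#' @return a `loc_table`.
#' @export
read_localizations <- function(path, dialect = c("csv", "hdf5"),
                               pixel_size_nm = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the 'hdf5' dialect is not supported by this build; use 'csv'")
  if (!file.exists(path)) stop("cannot read localization file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in LOC_MANDATORY)
    if (is.null(df[[col]]))
      stop("file '", path, "' is missing mandatory column '", col, "'")
  if (!is.null(pixel_size_nm)) {
    df$x <- px_to_nm(df$x, pixel_size_nm)
    df$y <- px_to_nm(df$y, pixel_size_nm)
    if (!is.null(df$precision))
      df$precision <- px_to_nm(df$precision, pixel_size_nm)
  }
  loc_table(df$x, df$y, df$frame, photons = df$photons,
            precision = df$precision, species = df$species)
}

#' Write a localization table to disk
#'
#' @param table a `loc_table`.
#' @param path output file path.
#' @param dialect file dialect; only `"csv"` is supported.
#' @return the path, invisibly.
#' @export
write_localizations <- function(table, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the 'hdf5' dialect is not supported by this build; use 'csv'")
  validate_loc_table(table)
  df <- as.data.frame(table)
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write localization file: ", path)
  invisible(path)
}

#' Pixel/nanometre unit conversion
#'
#' Linear conversion between camera pixels and nm using the effective pixel
#' size (130 nm for the default sCMOS configuration).
#'
#' @param value lengths in pixels (`px_to_nm`) or nm (`nm_to_px`).
#' @param pixel_size_nm pixel size in nm; must be > 0.
#' @return converted lengths.
#' @export
px_to_nm <- function(value, pixel_size_nm = 130) {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  value * pixel_size_nm
}

#' @rdname px_to_nm
#' @export
nm_to_px <- function(value, pixel_size_nm = 130) {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  value / pixel_size_nm
}

# ---------------------------------------------------------------------------
# Region masks
# ---------------------------------------------------------------------------

shoelace_area_nm2 <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Construct a region-of-interest polygon mask
#'
#' @param vertices two-column matrix (or data.frame) of polygon vertices in
#'   nm, in order, without repeating the first vertex.
#' @param label region label, e.g. `"FA"` or `"MEM"`.
#' @return a `region_mask` with vertices (nm) and `area_um2`.
#' @export
region_mask <- function(vertices, label = "ROI") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) stop("mask needs >= 3 two-column vertices")
  storage.mode(v) <- "double"
  n <- nrow(v)
  # simple-polygon check: no two non-adjacent edges properly intersect
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || abs(i - j) == n - 1 || j <= i) next
      if (segments_intersect(v[i, ], v[i %% n + 1, ], v[j, ], v[j %% n + 1, ]))
        stop("mask polygon is self-intersecting")
    }
  }
  area <- shoelace_area_nm2(v) / 1e6
  if (area <= 0) stop("mask polygon must enclose a positive area")
  structure(list(vertices = v, area_um2 = area, label = label),
            class = "region_mask")
}

#' Rectangular mask helper
#'
#' @param width,height rectangle extent in nm, lower-left corner at origin.
#' @param label region label.
#' @return a `region_mask`.
#' @export
rect_mask <- function(width, height = width, label = "ROI") {
  region_mask(rbind(c(0, 0), c(width, 0), c(width, height), c(0, height)),
              label = label)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s': %d vertices, %.4g um^2>\n",
              x$label, nrow(x$vertices), x$area_um2))
  invisible(x)
}

in_mask <- function(x, y, mask) {
  bnd <- rbind(mask$vertices, mask$vertices[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(x, y))
}

#' Read a region mask from a CSV vertex list or GeoJSON-style polygon
#'
#' CSV files need `x,y` columns (nm); `.json`/`.geojson` files need a
#' `coordinates` array of one polygon ring.
#'
#' @param path file path.
#' @param label region label.
#' @return a `region_mask`.
#' @export
read_region_mask <- function(path, label = "ROI") {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    coords <- if (!is.null(g$coordinates)) g$coordinates else g$geometry$coordinates
    v <- matrix(unlist(coords), ncol = 2, byrow = is.null(dim(coords)))
    if (is.list(coords) || (is.array(coords) && length(dim(coords)) == 3))
      v <- matrix(aperm(array(unlist(coords), dim = c(1, dim(coords)[-1]))), ncol = 2)
    v <- unique(round(v, 9))
  } else {
    df <- read.csv(path)
    if (is.null(df$x) || is.null(df$y)) stop("mask CSV needs x,y columns")
    v <- cbind(df$x, df$y)
  }
  region_mask(v, label = label)
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Assemble and validate a run configuration
#'
#' @param pixel_size_nm camera pixel size (nm).
#' @param n_frames number of acquisition frames (80,000 for NND imaging,
#'   160,000 for qPAINT by convention).
#' @param exposure_ms camera exposure per frame (ms).
#' @param eps DBSCAN radius in nm (defaults to the NeNA precision when NULL).
#' @param min_pts DBSCAN minimum neighbourhood size.
#' @param coloc_threshold colocalization distance threshold (nm).
#' @param le named numeric vector of labeling efficiencies per species,
#'   each in (0, 1].
#' @param de detection efficiency in (0, 1].
#' @param seed master seed.
#' @return a validated `run_config` list.
#' @export
run_config <- function(pixel_size_nm = 130, n_frames = 80000,
                       exposure_ms = 100, eps = NULL, min_pts = NULL,
                       coloc_threshold = 25, le = c(halo = 0.30, snap = 0.20),
                       de = NULL, seed = 1L) {
  cfg <- list(pixel_size_nm = pixel_size_nm, n_frames = as.integer(n_frames),
              exposure_ms = exposure_ms, eps = eps, min_pts = min_pts,
              coloc_threshold = coloc_threshold, le = le, de = de,
              seed = as.integer(seed))
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  if (!is.null(eps) && eps <= 0) stop("eps must be > 0")
  if (!is.null(min_pts) && min_pts < 1) stop("min_pts must be >= 1")
  if (coloc_threshold <= 0) stop("coloc_threshold must be > 0")
  if (any(le <= 0 | le > 1)) stop("labeling efficiencies must be in (0, 1]")
  if (!is.null(de) && (de <= 0 || de > 1))
    stop("detection efficiency must be in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$le)) raw$le <- unlist(raw$le)
  do.call(run_config, raw)
}
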