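#' Spatial units (LSOA stand-ins)
#'
#' A `site_set` is a data frame with columns `unit_id`, `x`, `y` holding
#' planar coordinates in meters for the small-area spatial units (stand-ins
#' for LSOAs) over which exposures and outcomes are simulated. Coordinates are
#' projected meters, not lon/lat: the spatial covariance range below is
#' metric.
#'
#' @name site_set
NULL

new_site_set <- function(df) {
  validate_site_set(df)
  structure(df, class = c("site_set", "data.frame"))
}

validate_site_set <- function(df) {
  need <- c("unit_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_airmes("site set is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (nrow(df) < 2) stop_airmes("a site set needs at least 2 units, got %d", nrow(df))
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$x))) |
                   is.na(suppressWarnings(as.numeric(df$y))))
    stop_airmes("non-numeric coordinate(s), first offending row: %d",
                if (length(bad)) bad[1] else 1L)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))
    stop_airmes("non-finite coordinate at row %d", bad[1])
  }
  dup_id <- which(duplicated(df$unit_id))
  if (length(dup_id) > 0) {
    stop_airmes("duplicated unit_id '%s' at row %d", df$unit_id[dup_id[1]], dup_id[1])
  }
  dup_xy <- which(duplicated(df[, c("x", "y")]))
  if (length(dup_xy) > 0) {
    stop_airmes(
      "two units share coordinates (%g, %g), second occurrence at row %d; distinct locations are required",
      df$x[dup_xy[1]], df$y[dup_xy[1]], dup_xy[1])
  }
  invisible(df)
}

#' Sample spatial units uniformly over a rectangle
#'
#' Draws `n` unit locations uniformly over a `width` x `height` rectangle
#' (meters, lower-left corner at the origin). The default extent is a
#' 50 km x 50 km square, a city-scale study region. Sampling is uniform;
#' no spatial stratification is applied.
#'
#' @param n number of units (>= 2). The reference study design uses 1000.
#' @param extent numeric length-2, rectangle width and height in meters.
#' @param seed integer seed; the draw is deterministic given `(n, extent, seed)`.
#' @return a `site_set` data frame with columns `unit_id`, `x`, `y`.
#' @examples
#' s <- sample_sites(100, seed = 1)
#' @export
sample_sites <- function(n, extent = c(50000, 50000), seed = 1L) {
  if (length(n) != 1 || !is.finite(n) || n < 2) {
    stop_airmes("n must be a single number >= 2, got %s", paste(n, collapse = ","))
  }
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0)) {
    stop_airmes("extent must be two positive dimensions (width, height) in meters")
  }
  n <- as.integer(n)
  set.seed(seed)
  df <- data.frame(
    unit_id = sprintf("U%05d", seq_len(n)),
    x = runif(n, 0, extent[1]),
    y = runif(n, 0, extent[2]),
    stringsAsFactors = FALSE
  )
  new_site_set(df)
}

#' Load spatial units from a coordinates CSV
#'
#' Reads a UTF-8 CSV with header `unit_id,x,y` (coordinates in projected
#' meters) and validates it: unique ids, numeric finite coordinates, and no
#' two units at identical locations (coincident units are rejected, not
#' jittered, because the spatial covariance requires distinct locations).
#'
#' @param path path to the CSV file.
#' @return a `site_set`.
#' @export
load_sites <- function(path) {
  if (!file.exists(path)) stop_airmes("coordinates file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_airmes("coordinates file %s is missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop_airmes("non-numeric '%s' value '%s' at data row %d of %s",
                  col, v[bad[1]], bad[1], path)
    }
  }
  df$unit_id <- as.character(df$unit_id)
  new_site_set(df[, need])
}

#' Pairwise Euclidean distance matrix of a site set
#'
#' @param sites a `site_set`.
#' @return symmetric `n x n` matrix of Euclidean distances in meters, zero
#'   diagonal, strictly positive off-diagonal, dimnames set to `unit_id`.
#' @export
site_distances <- function(sites) {
  validate_site_set(sites)
  d <- as.matrix(dist(cbind(sites$x, sites$y)))
  dimnames(d) <- list(sites$unit_id, sites$unit_id)
  off <- d[upper.tri(d)]
  if (any(off <= 0)) {
    stop_airmes("zero distance between distinct units; coincident coordinates are invalid")
  }
  d
}
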