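# Occurrence sets: ordered coordinate records with a coordinate-system tag.
# Geographic coordinates are decimal degrees (lon, lat); metric coordinates
# are metres in an arbitrary planar frame (e.g. UTM or the package's own
# equal-area projection).

# Authalic Earth radius (m): the sphere radius preserving the ellipsoid's
# surface area, the natural choice when areas are the target quantity.
.R_EARTH <- 6371007.2

#' Create an occurrence set
#'
#' An occurrence set is an ordered table of record coordinates with a tag
#' saying whether they are geographic (longitude/latitude, decimal degrees)
#' or already planar-metric (metres). Most functions in the package accept
#' either and project geographic input to an equal-area plane internally.
#'
#' @param x,y Numeric coordinate vectors (x = longitude or eastness,
#'   y = latitude or northness).
#' @param crs Either `"geographic"`, `"metric"`, or `NULL` to autodetect:
#'   coordinates all within \[-180, 180\] x \[-90, 90\] are treated as
#'   geographic.
#' @param species Optional character vector of species labels (recycled).
#' @return An object of class `occurrences`: a data frame with columns
#'   `x`, `y` (and `species` if given) and a `crs` attribute.
#' @examples
#' occ <- occurrences(c(-16.9, -17.1), c(32.7, 32.8))
#' attr(occ, "crs")
#' @export
occurrences <- function(x, y, crs = NULL, species = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 1L) stop("no records")
  if (anyNA(x) || anyNA(y)) stop("coordinates contain missing values")
  if (is.null(crs)) {
    crs <- if (all(x >= -180 & x <= 180) && all(y >= -90 & y <= 90))
      "geographic" else "metric"
  }
  crs <- match.arg(crs, c("geographic", "metric"))
  if (crs == "geographic" &&
      (any(x < -180 | x > 180) || any(y < -90 | y > 90)))
    stop("coordinates outside valid geographic range")
  out <- data.frame(x = x, y = y)
  if (!is.null(species)) out$species <- rep_len(as.character(species), nrow(out))
  class(out) <- c("occurrences", "data.frame")
  attr(out, "crs") <- crs
  out
}

#' @export
print.occurrences <- function(x, ...) {
  cat(sprintf("Occurrence set: %d record(s), %s coordinates\n",
              nrow(x), attr(x, "crs")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

is_geographic <- function(records) identical(attr(records, "crs"), "geographic")

# Forward spherical Lambert azimuthal equal-area projection.
# lon0/lat0 in degrees; returns metres.
laea_forward <- function(lon, lat, lon0, lat0, R = .R_EARTH) {
  d <- pi / 180
  lam <- lon * d; phi <- lat * d
  lam0 <- lon0 * d; phi0 <- lat0 * d
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  # antipode of the centre maps to infinity; records never span that far
  k <- sqrt(2 / pmax(denom, 1e-12))
  list(x = R * k * cos(phi) * sin(lam - lam0),
       y = R * k * (cos(phi0) * sin(phi) -
                    sin(phi0) * cos(phi) * cos(lam - lam0)))
}

# Inverse of laea_forward; returns degrees.
laea_inverse <- function(x, y, lon0, lat0, R = .R_EARTH) {
  d <- pi / 180
  lam0 <- lon0 * d; phi0 <- lat0 * d
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  lat <- ifelse(rho == 0, phi0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho))
  lon <- lam0 + atan2(x * sin(cc),
                      rho * cos(phi0) * cos(cc) - y * sin(phi0) * sin(cc))
  lon <- ifelse(rho == 0, lam0, lon)
  list(lon = lon / d, lat = lat / d)
}

#' Project records to a metric equal-area plane
#'
#' Geographic records are projected with a spherical Lambert azimuthal
#' equal-area projection centred on the records' centroid, so that the
#' areas entering EOO and AOO are locally undistorted. Metric input is
#' returned unchanged.
#'
#' @param records An [occurrences] object.
#' @return An [occurrences] object with `crs = "metric"` (units metres).
#'   Projected output carries a `proj` attribute (`lon0`, `lat0`, `R`)
#'   enabling the inverse transform (used by KML export).
#' @export
project_to_metric <- function(records) {
  if (!inherits(records, "occurrences")) stop("records must be an occurrences object")
  if (nrow(records) < 1L) stop("no records")
  if (!is_geographic(records)) return(records)
  lon0 <- mean(records$x)
  lat0 <- mean(records$y)
  p <- laea_forward(records$x, records$y, lon0, lat0)
  out <- records
  out$x <- p$x
  out$y <- p$y
  attr(out, "crs") <- "metric"
  attr(out, "proj") <- list(lon0 = lon0, lat0 = lat0, R = .R_EARTH)
  out
}

#' Read occurrence records from CSV
#'
#' Accepts two numeric columns (x/longitude, y/latitude) for a single
#' species or three columns (species, x, y) for several. A header row is
#' detected and skipped automatically; blank lines are ignored. Duplicate
#' coordinates are retained (EOO and AOO are duplicate-safe).
#'
#' @param path Path to a CSV file.
#' @param crs Coordinate-system tag passed to [occurrences()] (default:
#'   autodetect).
#' @return An [occurrences] object (with a `species` column for 3-column
#'   input).
#' @export
read_occurrences <- function(path, crs = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in ", path)
  parts <- strsplit(lines, ",")
  ncols <- length(parts[[1L]])
  if (!ncols %in% c(2L, 3L))
    stop("expected 2 (x,y) or 3 (species,x,y) columns, found ", ncols)
  xi <- ncols - 1L; yi <- ncols
  first_numeric <- !is.na(suppressWarnings(as.numeric(parts[[1L]][xi]))) &&
    !is.na(suppressWarnings(as.numeric(parts[[1L]][yi])))
  if (!first_numeric) {
    parts <- parts[-1L]
    if (length(parts) == 0L) stop("no records in ", path)
  }
  get <- function(i) vapply(parts, function(p) trimws(p[i]), character(1))
  xs <- suppressWarnings(as.numeric(get(xi)))
  ys <- suppressWarnings(as.numeric(get(yi)))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop("non-numeric coordinate at line ",
         paste(bad + as.integer(!first_numeric), collapse = ", "))
  sp <- if (ncols == 3L) get(1L) else NULL
  occurrences(xs, ys, crs = crs, species = sp)
}

#' Write occurrence records to CSV
#'
#' @param records An [occurrences] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  df <- as.data.frame(records)
  cols <- intersect(c("species", "x", "y"), names(df))
  utils::write.csv(format(df[cols], digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
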