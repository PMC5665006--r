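# IUCN criterion B range metrics: Extent of Occurrence (minimum convex
# polygon) and Area of Occupancy (2 km x 2 km grid cell counting).

# Resolve any accepted range input (occurrence set or binary presence
# raster) to metric point sites. Raster input contributes the centres of
# its presence (value == 1) cells.
range_sites <- function(x) {
  if (inherits(x, "occurrences")) {
    if (nrow(x) < 1L) stop("no records")
    p <- project_to_metric(x)
    return(cbind(x = p$x, y = p$y))
  }
  if (inherits(x, "red_raster")) {
    idx <- which(!is.na(x$values) & x$values == 1)
    if (!length(idx)) stop("no presences")
    rc <- cbind(((idx - 1L) %% n_rows(x)) + 1L, ((idx - 1L) %/% n_rows(x)) + 1L)
    ctr <- cell_center(x, rc)
    if (identical(x$crs, "geographic")) {
      lon0 <- mean(range(ctr[, 1L])); lat0 <- mean(range(ctr[, 2L]))
      pr <- laea_forward(ctr[, 1L], ctr[, 2L], lon0, lat0)
      ctr <- cbind(x = pr$x, y = pr$y)
    }
    return(ctr)
  }
  stop("input must be an occurrences object or a binary red_raster")
}

# Shoelace area of a polygon given vertex coordinates (not closed).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# AOO (km^2) of metric point sites on the fixed 2-km grid anchored at (0,0).
aoo_points_km2 <- function(xy) {
  cells <- unique(paste(floor(xy[, 1L] / 2000), floor(xy[, 2L] / 2000)))
  4 * length(cells)
}

#' Extent of Occurrence (EOO)
#'
#' EOO is the planar area of the minimum convex polygon covering all known
#' or predicted sites for the species, the IUCN criterion B1 metric.
#' Geographic input is projected to an equal-area plane first; a binary
#' presence raster contributes its presence-cell centres as sites. When
#' the hull is degenerate (one or two sites, or all sites collinear) or
#' its area falls below the AOO of the same sites, the AOO is returned
#' instead, so that EOO >= AOO always holds.
#'
#' @param x An [occurrences] object or a binary `red_raster`
#'   (1 = presence).
#' @return EOO in km^2.
#' @examples
#' sq <- occurrences(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000),
#'                   crs = "metric")
#' eoo(sq)  # 100
#' @export
eoo <- function(x) {
  xy <- range_sites(x)
  hull <- grDevices::chull(xy[, 1L], xy[, 2L])
  area_km2 <- polygon_area(xy[hull, 1L], xy[hull, 2L]) / 1e6
  max(area_km2, aoo_points_km2(xy))
}

#' Area of Occupancy (AOO)
#'
#' AOO is the summed area of occupied cells on a fixed 2 km x 2 km grid
#' (the resolution required by IUCN), i.e. 4 km^2 per occupied cell. The
#' grid is anchored at the metric origin (0,0) so results are reproducible
#' bit-for-bit. Point records occupy the cell they fall in; presence
#' rasters at other resolutions are mapped to the 2-km grid by the
#' any-overlap rule (every 2-km cell overlapping a presence cell counts).
#'
#' @param x An [occurrences] object or a binary `red_raster`.
#' @return AOO in km^2 (a multiple of 4).
#' @export
aoo <- function(x) {
  if (inherits(x, "red_raster") && identical(x$crs, "metric")) {
    idx <- which(!is.na(x$values) & x$values == 1)
    if (!length(idx)) stop("no presences")
    rc <- cbind(((idx - 1L) %% n_rows(x)) + 1L, ((idx - 1L) %/% n_rows(x)) + 1L)
    cs <- x$cellsize
    x0 <- x$xmin + (rc[, 2L] - 1) * cs
    y1 <- x$ymax - (rc[, 1L] - 1) * cs
    eps <- cs * 1e-9
    keys <- character(0)
    for (k in seq_along(idx)) {
      ci <- floor(x0[k] / 2000):floor((x0[k] + cs - eps) / 2000)
      ri <- floor((y1[k] - cs) / 2000):floor((y1[k] - eps) / 2000)
      keys <- c(keys, as.vector(outer(ci, ri, paste)))
    }
    return(4 * length(unique(keys)))
  }
  aoo_points_km2(range_sites(x))
}

#' Elevation range of records
#'
#' Samples a digital elevation model at each record's cell and returns the
#' minimum and maximum. Records on NoData cells are an error (clean them
#' first with [move_to_valid()]).
#'
#' @param records An [occurrences] object in the DEM's coordinate system.
#' @param dem A `red_raster` of elevations.
#' @return Named numeric `c(min = , max = )` in the DEM's value units.
#' @export
elevation_range <- function(records, dem) {
  v <- extract_values(dem, records$x, records$y)[, 1L]
  bad <- which(is.na(v))
  if (length(bad))
    stop("record(s) ", paste(bad, collapse = ", "),
         " fall on NoData cells; run move_to_valid first")
  c(min = min(v), max = max(v))
}

## ---- country boundaries ---------------------------------------------------

#' Read polygon boundaries from GeoJSON
#'
#' Reads Polygon and MultiPolygon features with a `name` property, e.g.
#' country boundaries, for use with [countries_of()].
#'
#' @param path Path to a GeoJSON file.
#' @return An object of class `boundaries`: a named list, one element per
#'   feature, each a list of rings (first ring outer, others holes), each
#'   ring a two-column coordinate matrix.
#' @export
read_boundaries <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- if (!is.null(g$features)) g$features else list(g)
  out <- list()
  for (f in feats) {
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("feature", length(out) + 1L)
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    rings <- list()
    for (poly in polys) for (ring in poly) {
      rings[[length(rings) + 1L]] <-
        do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    }
    out[[nm]] <- rings
  }
  structure(out, class = "boundaries")
}

# Even-odd ray-casting point-in-polygon over a set of rings.
points_in_rings <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  for (ring in rings) {
    rx <- ring[, 1L]; ry <- ring[, 2L]
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((ry[i] > y) != (ry[j] > y)) &
        (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i])
      inside <- xor(inside, crosses & !is.na(crosses))
      j <- i
    }
  }
  inside
}

#' Countries (named polygons) occupied by a range
#'
#' Returns the sorted unique names of the supplied polygons that contain
#' at least one record (or presence-cell centre). Boundaries must be in
#' the same coordinate system as the input.
#'
#' @param x An [occurrences] object or binary `red_raster`.
#' @param boundaries A [read_boundaries()] object, or a named list of ring
#'   lists in the same format.
#' @return Sorted character vector of names (empty if no polygon contains
#'   a site).
#' @export
countries_of <- function(x, boundaries) {
  sites <- if (inherits(x, "occurrences")) {
    cbind(x$x, x$y)
  } else if (inherits(x, "red_raster")) {
    idx <- which(!is.na(x$values) & x$values == 1)
    if (!length(idx)) return(character(0))
    rc <- cbind(((idx - 1L) %% n_rows(x)) + 1L, ((idx - 1L) %/% n_rows(x)) + 1L)
    cell_center(x, rc)
  } else stop("input must be an occurrences object or a binary red_raster")
  hit <- vapply(boundaries, function(rings)
    any(points_in_rings(sites[, 1L], sites[, 2L], rings)), logical(1))
  sort(names(boundaries)[hit])
}
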