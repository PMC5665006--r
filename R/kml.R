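# KML export: presence cells are dissolved into boundary polygons and
# written as a KML 2.2 document for visualization in Google Earth.

# Dissolve the presence cells of a binary raster into polygon rings.
# Boundary edges are emitted directed so the interior is on the left
# (outer rings counter-clockwise, holes clockwise) and chained into
# closed rings; collinear vertices are removed. Returns a list of
# two-column matrices in map coordinates.
dissolve_cells <- function(r) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  pres <- !is.na(v) & v == 1
  at <- function(rr, cc)
    rr >= 1 & rr <= nr & cc >= 1 & cc <= nc & pres[cbind(pmax(pmin(rr, nr), 1),
                                                         pmax(pmin(cc, nc), 1))]
  idx <- which(pres)
  if (!length(idx)) return(list())
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # corner coordinates in grid units: x = col offsets, y counted upward
  x0 <- cc - 1L; x1 <- cc
  y1 <- nr - rr + 1L; y0 <- nr - rr    # y1 top of cell, y0 bottom
  edges <- rbind(
    cbind(x0, y0, x1, y0)[!at(rr + 1L, cc), , drop = FALSE],  # bottom, east
    cbind(x1, y0, x1, y1)[!at(rr, cc + 1L), , drop = FALSE],  # right, north
    cbind(x1, y1, x0, y1)[!at(rr - 1L, cc), , drop = FALSE],  # top, west
    cbind(x0, y1, x0, y0)[!at(rr, cc - 1L), , drop = FALSE])  # left, south
  key <- function(x, y) paste(x, y)
  from <- key(edges[, 1L], edges[, 2L])
  used <- rep(FALSE, nrow(edges))
  starts <- split(seq_len(nrow(edges)), from)
  rings <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    ring <- matrix(edges[e0, 1:2], ncol = 2)
    cur <- e0
    repeat {
      used[cur] <- TRUE
      nxt_key <- key(edges[cur, 3L], edges[cur, 4L])
      ring <- rbind(ring, edges[cur, 3:4])
      cand <- starts[[nxt_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1L]
    }
    if (nrow(ring) >= 4L &&
        all(ring[1L, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
      # drop collinear vertices
      n <- nrow(ring)
      keep <- vapply(seq_len(n), function(i) {
        p <- ring[((i - 2L) %% n) + 1L, ]; q <- ring[i, ]
        s <- ring[(i %% n) + 1L, ]
        (q[1L] - p[1L]) * (s[2L] - q[2L]) != (q[2L] - p[2L]) * (s[1L] - q[1L])
      }, logical(1))
      ring <- ring[keep, , drop = FALSE]
      rings[[length(rings) + 1L]] <- ring
    }
  }
  cs <- r$cellsize
  ymin <- r$ymax - nr * cs
  lapply(rings, function(g)
    cbind(x = r$xmin + g[, 1L] * cs, y = ymin + g[, 2L] * cs))
}

ring_signed_area <- function(g) {
  n <- nrow(g)
  j <- c(n, seq_len(n - 1L))
  sum(g[j, 1L] * g[, 2L] - g[, 1L] * g[j, 2L]) / 2
}

#' Write a binary raster as KML
#'
#' Presence cells are dissolved into polygons (with holes) and written as
#' a KML 2.2 document. KML requires geographic coordinates: metric input
#' is inverse-projected using the raster's projection anchor; a metric
#' raster without one is anchored at longitude/latitude (0, 0), which
#' preserves shape for visualization of purely synthetic data.
#'
#' @param r A binary `red_raster` (1 = presence).
#' @param path Output .kml path.
#' @param name Document name (default the raster's name).
#' @return `path`, invisibly. An empty raster produces a valid KML with
#'   zero placemarks and a warning.
#' @export
write_kml <- function(r, path, name = r$name) {
  rings <- dissolve_cells(r)
  if (!length(rings)) warning("no presence cells: writing empty KML")
  if (!identical(r$crs, "geographic")) {
    anchor <- if (!is.null(r$proj)) r$proj else list(lon0 = 0, lat0 = 0)
    rings <- lapply(rings, function(g) {
      ll <- laea_inverse(g[, 1L], g[, 2L], anchor$lon0, anchor$lat0)
      cbind(x = ll$lon, y = ll$lat)
    })
  }
  outer_idx <- which(vapply(rings, ring_signed_area, numeric(1)) > 0)
  hole_idx <- setdiff(seq_along(rings), outer_idx)
  # assign each hole to the outer ring containing its first vertex
  hole_of <- lapply(outer_idx, function(i) integer(0))
  names(hole_of) <- as.character(outer_idx)
  for (h in hole_idx) {
    p <- rings[[h]][1L, ]
    for (i in outer_idx) {
      if (points_in_rings(p[1L], p[2L] + 1e-9, rings[i])) {
        hole_of[[as.character(i)]] <- c(hole_of[[as.character(i)]], h)
        break
      }
    }
  }
  coords <- function(g) {
    g <- rbind(g, g[1L, , drop = FALSE])
    paste(sprintf("%.10g,%.10g,0", g[, 1L], g[, 2L]), collapse = " ")
  }
  pm <- character(0)
  for (i in outer_idx) {
    inner <- paste(vapply(hole_of[[as.character(i)]], function(h) paste0(
      "<innerBoundaryIs><LinearRing><coordinates>", coords(rings[[h]]),
      "</coordinates></LinearRing></innerBoundaryIs>"), character(1)),
      collapse = "")
    pm <- c(pm, paste0(
      "<Placemark><name>", name, "</name><styleUrl>#range</styleUrl>",
      "<Polygon><outerBoundaryIs><LinearRing><coordinates>",
      coords(rings[[i]]),
      "</coordinates></LinearRing></outerBoundaryIs>", inner,
      "</Polygon></Placemark>"))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<kml xmlns="http://www.opengis.net/kml/2.2"><Document><name>', name,
    '</name><Style id="range"><PolyStyle><color>7f0000ff</color>',
    '<outline>1</outline></PolyStyle></Style>',
    paste(pm, collapse = ""), "</Document></kml>\n")
  writeLines(doc, path)
  invisible(path)
}

#' Draw a range map to an image file
#'
#' Renders the raster with records overplotted as filled circles and
#' writes PNG or PDF depending on the file extension.
#'
#' @param records An [occurrences] object (or NULL to omit points).
#' @param raster A `red_raster` in the same coordinate system.
#' @param path Output .png or .pdf path.
#' @param dpi Resolution for PNG output (default 96).
#' @param width Plot width in inches (default 6; height follows the
#'   raster aspect ratio).
#' @return `path`, invisibly.
#' @export
draw_map <- function(records, raster, path, dpi = 96, width = 6) {
  nr <- n_rows(raster); nc <- n_cols(raster)
  height <- width * nr / nc
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  } else if (ext == "pdf") {
    grDevices::pdf(path, width = width, height = height)
  } else stop("unsupported extension: ", ext)
  on.exit(grDevices::dev.off())
  cs <- raster$cellsize
  xs <- raster$xmin + (seq_len(nc) - 0.5) * cs
  ys <- raster$ymax - (rev(seq_len(nr)) - 0.5) * cs
  z <- t(raster$values[nr:1, , drop = FALSE])
  graphics::par(mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.4, 0))
  graphics::image(xs, ys, z, col = grDevices::hcl.colors(64, "Terrain"),
                  xlab = "x", ylab = "y", main = raster$name, asp = 1,
                  useRaster = TRUE)
  if (!is.null(records))
    graphics::points(records$x, records$y, pch = 19, cex = 0.8)
  invisible(path)
}
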