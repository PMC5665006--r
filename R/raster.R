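# Lightweight in-memory raster containers. Grids are regular and north-up:
# row 1 is the top row, cell (r, c) has its centre at
#   x = xmin + (c - 0.5) * cellsize,  y = ymax - (r - 0.5) * cellsize.
# NoData cells hold NA. This convention is stated here once and used
# everywhere in the package.

#' Create a raster layer
#'
#' @param values Numeric matrix (rows x cols), row 1 = top (north). `NA`
#'   marks NoData cells.
#' @param xmin X coordinate of the left edge (map units).
#' @param ymax Y coordinate of the top edge (map units).
#' @param cellsize Cell edge length (map units), > 0; cells are square.
#' @param crs `"metric"` (units metres) or `"geographic"` (degrees).
#' @param categorical Logical: values are class codes, not quantities.
#' @param name Layer name.
#' @param proj Optional projection anchor (list `lon0`, `lat0`, `R`) for
#'   metric grids derived from geographic data; enables inverse projection.
#' @return An object of class `red_raster`.
#' @export
red_raster <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                       cellsize = 1, crs = "metric", categorical = FALSE,
                       name = "layer", proj = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty grid")
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 cellsize = cellsize, crs = crs,
                 categorical = isTRUE(categorical), name = name,
                 proj = proj),
            class = "red_raster")
}

#' @export
print.red_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("Raster '%s': %d x %d cells, cellsize %g (%s)%s\n",
              x$name, nrow(v), ncol(v), x$cellsize, x$crs,
              if (x$categorical) ", categorical" else ""))
  cat(sprintf("  extent x [%g, %g], y [%g, %g]; %d NoData cell(s)\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymax - nrow(v) * x$cellsize, x$ymax, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Create a raster stack
#'
#' @param ... `red_raster` layers (or a single list of them). All layers
#'   must share grid geometry.
#' @return An object of class `red_stack` (a named list of layers).
#' @export
red_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "red_raster"))
    layers <- layers[[1L]]
  if (!length(layers)) stop("no layers")
  for (l in layers) {
    if (!inherits(l, "red_raster")) stop("all elements must be red_raster")
    if (!grids_congruent(l, layers[[1L]])) stop("layers are not congruent")
  }
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  names(layers) <- nm
  structure(layers, class = "red_stack")
}

#' @export
print.red_stack <- function(x, ...) {
  cat(sprintf("Raster stack: %d layer(s) [%s]\n", length(x),
              paste(names(x), collapse = ", ")))
  print(x[[1L]])
  invisible(x)
}

#' @export
`[.red_stack` <- function(x, i) {
  red_stack(unclass(x)[i])
}

grids_congruent <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

n_rows <- function(r) nrow(r$values)
n_cols <- function(r) ncol(r$values)

# Row/col (1-based) of the cells containing points; NA outside the extent.
# Points exactly on the right/bottom edge belong to the last cell.
cell_of <- function(r, x, y) {
  cs <- r$cellsize
  col <- floor((x - r$xmin) / cs) + 1
  row <- floor((r$ymax - y) / cs) + 1
  nr <- n_rows(r); nc <- n_cols(r)
  col[x == r$xmin + nc * cs] <- nc
  row[y == r$ymax - nr * cs] <- nr
  off <- col < 1 | col > nc | row < 1 | row > nr
  col[off] <- NA_integer_; row[off] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Centre coordinates of cells given (row, col) matrix.
cell_center <- function(r, rc) {
  cbind(x = r$xmin + (rc[, 2L] - 0.5) * r$cellsize,
        y = r$ymax - (rc[, 1L] - 0.5) * r$cellsize)
}

# (row, col) of all data (non-NA) cells.
data_cells <- function(r) {
  idx <- which(!is.na(r$values))
  cbind(row = ((idx - 1L) %% n_rows(r)) + 1L,
        col = ((idx - 1L) %/% n_rows(r)) + 1L)
}

# Extract layer values at points; returns a matrix (points x layers).
# Off-extent points yield NA.
extract_values <- function(stack, x, y) {
  if (inherits(stack, "red_raster")) stack <- red_stack(stack)
  rc <- cell_of(stack[[1L]], x, y)
  sapply(stack, function(l) {
    v <- rep(NA_real_, nrow(rc))
    ok <- !is.na(rc[, 1L])
    v[ok] <- l$values[cbind(rc[ok, 1L], rc[ok, 2L])]
    v
  }, simplify = TRUE, USE.NAMES = TRUE) |> matrix(nrow = nrow(rc),
                                                  dimnames = list(NULL, names(stack)))
}

quantitative_layers <- function(stack) {
  stack[!vapply(stack, function(l) l$categorical, logical(1))]
}

## ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read an ESRI ASCII grid (.asc)
#'
#' Honors `NODATA_value` and both `xllcorner`/`yllcorner` and
#' `xllcenter`/`yllcenter` header conventions.
#'
#' @param path Path to an .asc file.
#' @param crs,categorical,name Passed to [red_raster()].
#' @return A `red_raster`.
#' @export
read_asc <- function(path, crs = "metric", categorical = FALSE,
                     name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      i <- i + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop("expected ", nrows * ncols, " values, found ", length(vals))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  red_raster(m, xmin = xmin, ymax = ymin + nrows * cs, cellsize = cs,
             crs = crs, categorical = categorical, name = name)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param r A `red_raster`.
#' @param path Output path.
#' @param nodata NoData sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  ymin <- r$ymax - nrow(v) * r$cellsize
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xmin, digits = 17, scientific = FALSE)),
    paste("yllcorner", format(ymin, digits = 17, scientific = FALSE)),
    paste("cellsize", format(r$cellsize, digits = 17, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1L, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

## ---- GeoTIFF I/O ----------------------------------------------------------
# Minimal GeoTIFF codec: uncompressed little-endian TIFF, float64 samples
# (band-interleaved-by-pixel for stacks), georeferencing via
# ModelPixelScaleTag (33550) and ModelTiepointTag (33922), NoData via the
# GDAL_NODATA ASCII tag (42113). Values round-trip bit-exactly.

.TIFF_NODATA <- -1.7976931348623157e308

#' Write a GeoTIFF
#'
#' Writes a single layer or a stack as an uncompressed float64 GeoTIFF
#' with georeferencing (pixel scale + tiepoint) and a NoData tag. Values
#' round-trip exactly through [read_geotiff()].
#'
#' @param r A `red_raster` or `red_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(r, path) {
  stack <- if (inherits(r, "red_raster")) red_stack(r) else r
  ref <- stack[[1L]]
  nr <- n_rows(ref); nc <- n_cols(ref); nb <- length(stack)
  # pixel-interleaved sample buffer, row-major from the top row
  arr <- array(NA_real_, dim = c(nb, nc, nr))
  for (b in seq_len(nb)) arr[b, , ] <- t(stack[[b]]$values)
  arr[is.na(arr)] <- .TIFF_NODATA
  strip <- as.vector(arr)

  nodata_str <- format(.TIFF_NODATA, digits = 17)
  nodata_len <- nchar(nodata_str, type = "bytes") + 1L  # + terminating nul
  n_entries <- 14L
  hdr_len <- 8L
  ifd_len <- 2L + n_entries * 12L + 4L
  # out-of-line data: BitsPerSample/SampleFormat arrays (if >2 bands),
  # pixel scale, tiepoint, nodata
  off <- hdr_len + ifd_len
  bps_off <- off
  if (nb > 2L) off <- off + 2L * nb        # SHORT array for >2 bands
  sf_off <- off
  if (nb > 2L) off <- off + 2L * nb
  scale_off <- off;    off <- off + 3L * 8L
  tie_off <- off;      off <- off + 6L * 8L
  nodata_off <- off;   off <- off + nodata_len
  if (off %% 2L) off <- off + 1L
  strip_off <- off

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  # IFD
  w2(n_entries)
  entry <- function(tag, type, count, value, inline_short = FALSE) {
    w2(tag); w2(type); w4(count)
    if (inline_short) { w2(value); w2(0L) } else w4(value)
  }
  entry(256L, 3L, 1L, nc, inline_short = TRUE)          # ImageWidth
  entry(257L, 3L, 1L, nr, inline_short = TRUE)          # ImageLength
  if (nb == 1L) entry(258L, 3L, 1L, 64L, inline_short = TRUE)
  else if (nb == 2L) { w2(258L); w2(3L); w4(2L); w2(64L); w2(64L) }
  else entry(258L, 3L, nb, bps_off)                     # BitsPerSample
  entry(259L, 3L, 1L, 1L, inline_short = TRUE)          # no compression
  entry(262L, 3L, 1L, 1L, inline_short = TRUE)          # BlackIsZero
  entry(273L, 4L, 1L, strip_off)                        # StripOffsets
  entry(277L, 3L, 1L, nb, inline_short = TRUE)          # SamplesPerPixel
  entry(278L, 3L, 1L, nr, inline_short = TRUE)          # RowsPerStrip
  entry(279L, 4L, 1L, nr * nc * nb * 8L)                # StripByteCounts
  entry(284L, 3L, 1L, 1L, inline_short = TRUE)          # chunky planar
  if (nb == 1L) entry(339L, 3L, 1L, 3L, inline_short = TRUE)
  else if (nb == 2L) { w2(339L); w2(3L); w4(2L); w2(3L); w2(3L) }
  else { w2(339L); w2(3L); w4(nb); w4(sf_off) }         # SampleFormat: IEEE
  entry(33550L, 12L, 3L, scale_off)                     # ModelPixelScale
  entry(33922L, 12L, 6L, tie_off)                       # ModelTiepoint
  entry(42113L, 2L, nodata_len, nodata_off)
  w4(0L)                                                # no next IFD
  if (nb > 2L) {
    w2(rep(64L, nb))
    w2(rep(3L, nb))
  }
  wd <- function(x) writeBin(as.double(x), con, size = 8, endian = "little")
  wd(c(ref$cellsize, ref$cellsize, 0))
  wd(c(0, 0, 0, ref$xmin, ref$ymax, 0))
  writeBin(c(charToRaw(nodata_str), as.raw(0L)), con)
  pos <- nodata_off + nodata_len
  if (pos %% 2L) writeBin(as.raw(0L), con)
  wd(strip)
  invisible(path)
}

#' Read a GeoTIFF written by [write_geotiff()]
#'
#' Supports the subset of TIFF this package writes: uncompressed, little-
#' endian, float64, chunky planar configuration, one strip.
#'
#' @param path Path to a .tif file.
#' @param crs,categorical Passed to [red_raster()].
#' @return A `red_raster` (single band) or `red_stack` (multi-band).
#' @export
read_geotiff <- function(path, crs = "metric", categorical = FALSE) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u <- function(at, size) {
    # little-endian unsigned int from bytes raw[at .. at+size-1] (1-based)
    sum(as.numeric(raw[at:(at + size - 1L)]) * 256^(0:(size - 1L)))
  }
  if (rawToChar(raw[1:2]) != "II") stop("not a little-endian TIFF")
  ifd <- u(5L, 4L)
  n <- u(ifd + 1L, 2L)
  tags <- list()
  for (i in seq_len(n)) {
    base <- ifd + 3L + (i - 1L) * 12L
    tag <- u(base, 2L); type <- u(base + 2L, 2L); count <- u(base + 4L, 4L)
    tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
    vbase <- if (count * tsize <= 4) base + 8L else u(base + 8L, 4L) + 1L
    val <- if (type %in% c(3L, 4L)) {
      vapply(seq_len(count), function(k) u(vbase + (k - 1L) * tsize, tsize),
             numeric(1))
    } else if (type == 12L) {
      readBin(raw[vbase:(vbase + count * 8L - 1L)], "double", n = count,
              size = 8, endian = "little")
    } else if (type == 2L) {
      rawToChar(raw[vbase:(vbase + count - 1L)][raw[vbase:(vbase + count - 1L)] != as.raw(0)])
    } else NULL
    tags[[as.character(tag)]] <- val
  }
  nc <- tags[["256"]]; nr <- tags[["257"]]
  nb <- if (is.null(tags[["277"]])) 1 else tags[["277"]]
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
    stop("compressed TIFF not supported")
  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  strip_off <- tags[["273"]]
  vals <- readBin(raw[(strip_off + 1L):(strip_off + nr * nc * nb * 8L)],
                  "double", n = nr * nc * nb, size = 8, endian = "little")
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NA
  arr <- array(vals, dim = c(nb, nc, nr))
  layers <- lapply(seq_len(nb), function(b) {
    m <- t(arr[b, , ])
    if (!is.na(nodata)) m[m == nodata] <- NA_real_
    red_raster(m, xmin = tie[4L], ymax = tie[5L], cellsize = scale[1L],
               crs = crs, categorical = categorical,
               name = paste0(sub("\\.[^.]*$", "", basename(path)),
                             if (nb > 1L) paste0("_", b) else ""))
  })
  if (nb == 1L) layers[[1L]] else red_stack(layers)
}
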