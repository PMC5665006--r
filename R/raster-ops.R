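# Raster utilities: dimensionality reduction of predictor stacks and
# habitat-patch range mapping.

#' Reduce the number of layers in a stack
#'
#' Overfitting threatens distribution models when the number of records is
#' low relative to the number of predictors. Two reductions are offered:
#' `"pca"` standardizes the layers over their common data cells, fits a
#' PCA and returns the first `n` component-score rasters; `"cor"`
#' iteratively drops the layer with the highest mean absolute pairwise
#' correlation until all pairwise |r| fall below `threshold`, returning
#' the surviving original layers. Categorical layers (e.g. land cover)
#' must be excluded by the caller — they have no place in either method.
#'
#' @param stack A `red_stack` of quantitative layers.
#' @param method `"pca"` or `"cor"`.
#' @param n Number of components to keep (pca; default all).
#' @param threshold Correlation bound (cor; default 0.7).
#' @return A `red_stack`.
#' @export
reduce_layers <- function(stack, method = c("pca", "cor"), n = NULL,
                          threshold = 0.7) {
  method <- match.arg(method)
  if (inherits(stack, "red_raster")) stack <- red_stack(stack)
  for (nm in names(stack)) {
    l <- stack[[nm]]
    if (l$categorical)
      stop("layer '", nm, "' is categorical; exclude it before reducing")
    if (stats::var(as.vector(l$values), na.rm = TRUE) == 0)
      stop("layer '", nm, "' is constant; exclude it before reducing")
  }
  if (length(stack) < 2L) stop("need at least 2 layers")
  vals <- sapply(stack, function(l) as.vector(l$values))
  ok <- stats::complete.cases(vals)
  if (method == "cor") {
    keep <- seq_len(ncol(vals))
    repeat {
      r <- abs(stats::cor(vals[ok, keep, drop = FALSE]))
      diag(r) <- NA
      if (length(keep) == 1L || all(r < threshold, na.rm = TRUE)) break
      worst <- which.max(colMeans(r, na.rm = TRUE))  # ties: lowest index
      keep <- keep[-worst]
    }
    return(stack[keep])
  }
  if (is.null(n)) n <- length(stack)
  n <- min(n, length(stack))
  pc <- stats::prcomp(vals[ok, , drop = FALSE], center = TRUE, scale. = TRUE)
  tmpl <- stack[[1L]]
  out <- lapply(seq_len(n), function(j) {
    v <- rep(NA_real_, nrow(vals))
    v[ok] <- pc$x[, j]
    red_raster(matrix(v, nrow = n_rows(tmpl)), xmin = tmpl$xmin,
               ymax = tmpl$ymax, cellsize = tmpl$cellsize, crs = tmpl$crs,
               name = paste0("PC", j), proj = tmpl$proj)
  })
  st <- red_stack(out)
  attr(st, "sdev") <- pc$sdev
  st
}

#' Label connected habitat patches
#'
#' Connected components of cells with value 1, under queen (8-neighbour,
#' the default: diagonal-touching habitat counts as connected) or rook
#' (4-neighbour) connectivity. Labels are assigned in raster scan order
#' (top-left to bottom-right by column-major order of first contact).
#'
#' @param habitat A binary `red_raster` (1 = habitat; 0 or NA otherwise).
#' @param connectivity 8 (queen) or 4 (rook).
#' @return A `red_raster` whose values are integer patch ids (0 =
#'   non-habitat, NA preserved), with attribute `n_patches`.
#' @export
label_patches <- function(habitat, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- habitat$values
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0, nr, nc)
  lab[is.na(v)] <- NA
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  nn <- if (connectivity == 8) 8L else 4L
  todo <- which(!is.na(v) & v == 1)
  next_id <- 0L
  stack <- integer(0)
  for (start in todo) {
    if (lab[start] != 0) next
    next_id <- next_id + 1L
    lab[start] <- next_id
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nn)) {
        r1 <- r0 + dr[k]; c1 <- c0 + dc[k]
        if (r1 < 1L || r1 > nr || c1 < 1L || c1 > nc) next
        j <- (c1 - 1L) * nr + r1
        if (!is.na(v[j]) && v[j] == 1 && lab[j] == 0) {
          lab[j] <- next_id
          stack <- c(stack, j)
        }
      }
    }
  }
  out <- red_raster(lab, xmin = habitat$xmin, ymax = habitat$ymax,
                    cellsize = habitat$cellsize, crs = habitat$crs,
                    categorical = TRUE, name = "patches",
                    proj = habitat$proj)
  attr(out, "n_patches") <- next_id
  out
}

#' Map a species range from occupied habitat patches
#'
#' For habitat specialists whose habitat distribution is known, the
#' occupied habitat patches may be the best available range map. Habitat
#' cells (value 1) are grouped into connected patches; the returned
#' presence raster marks every cell of each patch containing at least one
#' record. With `move = TRUE`, records off habitat (e.g. georeferencing
#' errors) are first snapped to the nearest habitat cell.
#'
#' @param records An [occurrences] object in the raster's coordinates.
#' @param habitat A binary `red_raster` (1 = habitat).
#' @param move Snap off-habitat records to the nearest habitat cell?
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @return A list of class `habitat_map`: `raster` (binary presence map),
#'   `raw` and `modelled` — each a named vector `c(eoo = , aoo = )` in
#'   km^2 — plus the (possibly moved) `records`.
#' @export
map_habitat <- function(records, habitat, move = FALSE, connectivity = 8) {
  if (nrow(records) < 1L) stop("no records")
  if (move) records <- move_to_valid(records, habitat, target = 1)
  patches <- label_patches(habitat, connectivity)
  at <- extract_values(patches, records$x, records$y)[, 1L]
  occ <- unique(at[!is.na(at) & at > 0])
  if (!length(occ)) stop("species occupies no habitat patch")
  v <- patches$values
  pres <- matrix(0, nrow(v), ncol(v))
  pres[is.na(habitat$values)] <- NA
  pres[!is.na(v) & v %in% occ] <- 1
  out <- red_raster(pres, xmin = habitat$xmin, ymax = habitat$ymax,
                    cellsize = habitat$cellsize, crs = habitat$crs,
                    name = "occupied_habitat", proj = habitat$proj)
  structure(list(raster = out,
                 raw = c(eoo = eoo(records), aoo = aoo(records)),
                 modelled = c(eoo = eoo(out), aoo = aoo(out)),
                 records = records,
                 occupied_patches = sort(occ)),
            class = "habitat_map")
}
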