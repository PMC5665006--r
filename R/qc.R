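# Occurrence-record quality control: snapping records to cells with
# environmental data, flagging environmental-space outliers, and spatial
# thinning to mitigate sampling-bias clumping.

#' Move records to the nearest cell with data
#'
#' Records falling on NoData cells (e.g. in the sea on a terrestrial
#' layer) or outside the raster extent are replaced by the centre of the
#' nearest data cell (Euclidean distance between the record and candidate
#' cell centres). Records already on data cells are unchanged; record
#' order is preserved.
#'
#' @param records An [occurrences] object in the layer's coordinate
#'   system.
#' @param layer A `red_raster` (or `red_stack`: a cell counts as data
#'   when its first layer has data).
#' @param target Optional value: when given, records are snapped to the
#'   nearest cell holding this value (e.g. 1 on a habitat raster) rather
#'   than to any data cell.
#' @return An [occurrences] object of the same length.
#' @export
move_to_valid <- function(records, layer, target = NULL) {
  if (inherits(layer, "red_stack")) layer <- layer[[1L]]
  good <- if (is.null(target)) !is.na(layer$values)
          else !is.na(layer$values) & layer$values == target
  if (!any(good)) stop("layer has no ",
                       if (is.null(target)) "data" else "target", " cells")
  idx <- which(good)
  rc <- cbind(((idx - 1L) %% n_rows(layer)) + 1L,
              ((idx - 1L) %/% n_rows(layer)) + 1L)
  ctr <- cell_center(layer, rc)
  at <- extract_values(layer, records$x, records$y)[, 1L]
  off <- if (is.null(target)) is.na(at) else is.na(at) | at != target
  out <- records
  for (i in which(off)) {
    d2 <- (ctr[, 1L] - records$x[i])^2 + (ctr[, 2L] - records$y[i])^2
    k <- which.min(d2)
    out$x[i] <- ctr[k, 1L]
    out$y[i] <- ctr[k, 2L]
  }
  out
}

#' Detect environmental-space outliers
#'
#' Unusual records can stem from misidentification, erroneous sources or
#' transcription errors. This reports, for each record, its geographic
#' distance to the records' centroid and its environmental distance to
#' the centroid of a PCA of the (record-wise standardized) environmental
#' values, and flags records whose environmental distance exceeds
#' `mean + k * SD` of all distances. Flags are advisory: assessors should
#' inspect flagged records, not delete them automatically.
#'
#' @param records An [occurrences] object; all records must lie on data
#'   cells (see [move_to_valid()]).
#' @param layers A `red_stack`; categorical layers are ignored, and at
#'   least two quantitative layers are required.
#' @param k Flagging multiplier on the SD of distances (default 2).
#' @return A data frame of class `outlier_report` with columns
#'   `geo_dist` (map units), `env_dist` (standardized PC space) and
#'   `flagged`.
#' @export
detect_outliers <- function(records, layers, k = 2) {
  if (nrow(records) < 3L) stop("need at least 3 records")
  if (inherits(layers, "red_raster")) layers <- red_stack(layers)
  q <- quantitative_layers(layers)
  if (length(q) < 2L) stop("need at least 2 quantitative layers")
  env <- extract_values(q, records$x, records$y)
  if (anyNA(env))
    stop("record(s) ", paste(which(rowSums(is.na(env)) > 0), collapse = ", "),
         " fall on NoData cells; run move_to_valid first")
  sds <- apply(env, 2L, stats::sd)
  scores <- matrix(0, nrow(env), 2L)
  if (all(sds == 0)) {
    # environmentally identical records: everything sits at the centroid
    env_dist <- rep(0, nrow(env))
  } else {
    if (any(sds == 0)) {
      warning("dropping zero-variance layer(s): ",
              paste(colnames(env)[sds == 0], collapse = ", "))
      env <- env[, sds > 0, drop = FALSE]
    }
    z <- scale(env)
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    # scores are centred (z is), so the PC-space centroid is the origin
    env_dist <- sqrt(rowSums(pc$x^2))
    scores <- pc$x
  }
  m <- project_to_metric(records)
  geo_dist <- sqrt((m$x - mean(m$x))^2 + (m$y - mean(m$y))^2)
  cut <- mean(env_dist) + k * stats::sd(env_dist)
  out <- data.frame(geo_dist = geo_dist, env_dist = env_dist,
                    flagged = env_dist > cut)
  class(out) <- c("outlier_report", "data.frame")
  attr(out, "cutoff") <- cut
  attr(out, "scores") <- scores
  out
}

#' Spatially thin occurrence records
#'
#' Eliminates records closer than a given distance to any other record.
#' The distance threshold is a proportion of the maximum pairwise distance
#' among the input records (e.g. 0.1 leaves no two records closer than
#' 10\% of the maximum distance). Because the order of deletions matters,
#' a number of random runs are made — each repeatedly deletes one member,
#' chosen at random, of a randomly chosen violating pair — and the single
#' run that keeps as many of the original records as possible is chosen
#' (ties resolved in favour of the earliest run).
#'
#' @param records An [occurrences] object.
#' @param proportion Distance threshold as a fraction of the maximum
#'   pairwise distance, in \[0, 1).
#' @param runs Number of random deletion runs (default 100).
#' @param seed Integer RNG seed.
#' @return An object of class `thin_result`: list with `records` (the
#'   thinned [occurrences]), `retained` (indices into the input),
#'   `threshold` (map units) and `min_dist` (achieved minimum pairwise
#'   distance, `Inf` for a single record).
#' @export
thin_records <- function(records, proportion = 0.1, runs = 100, seed = 1) {
  if (proportion < 0 || proportion >= 1) stop("proportion must be in [0, 1)")
  m <- project_to_metric(records)
  n <- nrow(m)
  result <- function(keep) {
    rec <- records[sort(keep), , drop = FALSE]
    attr(rec, "crs") <- attr(records, "crs")
    class(rec) <- class(records)
    d <- if (length(keep) > 1L)
      min(stats::dist(cbind(m$x, m$y)[sort(keep), ])) else Inf
    structure(list(records = rec, retained = sort(keep),
                   threshold = thr, min_dist = d),
              class = "thin_result")
  }
  dmat <- as.matrix(stats::dist(cbind(m$x, m$y)))
  thr <- proportion * max(dmat)
  if (n == 1L || proportion == 0) return(result(seq_len(n)))
  set.seed(seed)
  best <- integer(0)
  for (run in seq_len(runs)) {
    keep <- seq_len(n)
    repeat {
      sub <- dmat[keep, keep, drop = FALSE]
      viol <- which(upper.tri(sub) & sub < thr, arr.ind = TRUE)
      if (!nrow(viol)) break
      pair <- viol[sample.int(nrow(viol), 1L), ]
      drop <- keep[pair[[sample.int(2L, 1L)]]]
      keep <- setdiff(keep, drop)
      if (length(keep) == 1L) break
    }
    if (length(keep) > length(best)) best <- keep
  }
  result(best)
}

#' @export
print.thin_result <- function(x, ...) {
  cat(sprintf("Thinning: kept %d record(s); threshold %g, min distance %g\n",
              length(x$retained), x$threshold, x$min_dist))
  invisible(x)
}

#' Plot an outlier report
#'
#' Two panels: records in geographic space and in PC1/PC2 environmental
#' space, flagged records highlighted, the PCA centroid marked with an X.
#'
#' @param x An `outlier_report` from [detect_outliers()].
#' @param records The [occurrences] the report was computed from.
#' @param path Optional .png path; when given the plot is written there.
#' @param ... Unused.
#' @return `path` (or `NULL` when plotting to the active device),
#'   invisibly.
#' @export
plot.outlier_report <- function(x, records, path = NULL, ...) {
  if (!is.null(path)) {
    grDevices::png(path, width = 960, height = 480)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  col <- ifelse(x$flagged, "red", "black")
  graphics::plot(records$x, records$y, pch = 19, col = col,
                 xlab = "x", ylab = "y", main = "Geographic space", asp = 1)
  sc <- attr(x, "scores")
  graphics::plot(sc[, 1L], sc[, 2L], pch = 19, col = col,
                 xlab = "PC1", ylab = "PC2", main = "Environmental space")
  graphics::points(0, 0, pch = 4, cex = 2, lwd = 2)
  invisible(path)
}
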