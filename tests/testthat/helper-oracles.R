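# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the hull oracle gift-wraps, the patch oracle
# flood-fills breadth-first, the thinning oracle enumerates subsets.

# Convex hull area by gift wrapping (Jarvis march) + shoelace, O(n h).
oracle_hull_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  x <- pts[, 1L]; y <- pts[, 2L]
  start <- which.min(x + 1e-12 * y)
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_along(x), cur)
    nxt <- cand[1L]
    for (j in cand[-1L]) {
      cr <- (x[nxt] - x[cur]) * (y[j] - y[cur]) -
            (y[nxt] - y[cur]) * (x[j] - x[cur])
      d_n <- (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2
      d_j <- (x[j] - x[cur])^2 + (y[j] - y[cur])^2
      if (cr < 0 || (cr == 0 && d_j > d_n)) nxt <- j
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > length(x)) stop("gift wrap failed")
  }
  hx <- x[hull]; hy <- y[hull]
  j <- c(length(hx), seq_len(length(hx) - 1L))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# Flood fill (BFS, queue) collecting the patch containing (r0, c0).
oracle_flood_fill <- function(mat, r0, c0, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)[seq_len(connectivity)]
  dc <- c(0, 0, -1, 1, -1, 1, -1, 1)[seq_len(connectivity)]
  seen <- matrix(FALSE, nr, nc)
  if (is.na(mat[r0, c0]) || mat[r0, c0] != 1) return(seen)
  queue <- list(c(r0, c0))
  seen[r0, c0] <- TRUE
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (k in seq_along(dr)) {
      r1 <- p[1L] + dr[k]; c1 <- p[2L] + dc[k]
      if (r1 >= 1 && r1 <= nr && c1 >= 1 && c1 <= nc && !seen[r1, c1] &&
          !is.na(mat[r1, c1]) && mat[r1, c1] == 1) {
        seen[r1, c1] <- TRUE
        queue[[length(queue) + 1L]] <- c(r1, c1)
      }
    }
  }
  seen
}

# Largest subset with all pairwise distances >= thr, by exhaustive
# enumeration over all 2^n subsets (n <= ~12).
oracle_max_retained <- function(dmat, thr) {
  n <- nrow(dmat)
  best <- 1L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    sub <- dmat[idx, idx]
    if (all(sub[upper.tri(sub)] >= thr)) best <- length(idx)
  }
  best
}

# A tiny 3-polygon tiling of the unit square for point-in-polygon tests.
three_polygon_tiling <- function() {
  structure(list(
    A = list(cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1))),
    B = list(cbind(c(0.5, 1, 1, 0.5), c(0, 0, 0.5, 0.5))),
    C = list(cbind(c(0.5, 1, 1, 0.5), c(0.5, 0.5, 1, 1)))
  ), class = "boundaries")
}

# Small binary archipelago raster: 6 disjoint square islands on a
# 30 x 40 sea grid (patch blocks separated by > 1 cell so connectivity
# choice cannot merge them).
archipelago_raster <- function() {
  m <- matrix(0, 30, 40)
  blocks <- list(c(2, 5, 2, 6), c(2, 6, 12, 15), c(3, 7, 25, 33),
                 c(12, 18, 4, 9), c(14, 20, 18, 27), c(24, 28, 31, 38))
  for (b in blocks) m[b[1]:b[2], b[3]:b[4]] <- 1
  red_raster(m, xmin = 0, ymax = 30 * 1000, cellsize = 1000,
             name = "archipelago")
}

jaccard_maps <- function(a, b) {
  A <- !is.na(a$values) & a$values == 1
  B <- !is.na(b$values) & b$values == 1
  sum(A & B) / sum(A | B)
}

# Assemble a minimal sdm_run-shaped object from a binary matrix + AUC,
# for exercising consensus arithmetic without fitting models.
fake_run <- function(bin, auc, cellsize = 1000) {
  r <- red_raster(bin, xmin = 0, ymax = nrow(as.matrix(bin)) * cellsize,
                  cellsize = cellsize, name = "presence")
  structure(list(model = NULL, prob = r, threshold = 0.5, auc = auc,
                 binary = r), class = "sdm_run")
}

# Evaluate an expression while swallowing its console output; return its
# value (used for CLI exit codes).
capture_it <- function(expr) {
  val <- NULL
  utils::capture.output(val <- expr)
  val
}
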