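# Synthetic data generators: smoothed random-field landscapes, virtual
# species with known suitability, occurrence samples with controllable
# bias and error, and Markov-evolved category tables. Everything every
# module needs can be generated offline and reproducibly from a seed.

# 1-D Gaussian kernel smoothing with edge replication padding.
smooth_1d <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Gaussian random field: white noise smoothed by a separable kernel with
# correlation length `scale` (cells), then standardized.
gaussian_field <- function(rows, cols, scale) {
  m <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (scale > 0) {
    m <- apply(m, 2L, smooth_1d, sigma = scale)
    m <- t(apply(m, 1L, smooth_1d, sigma = scale))
  }
  (m - mean(m)) / stats::sd(m)
}

#' Generate a synthetic landscape
#'
#' Builds a raster stack emulating typical assessment inputs: smoothed
#' Gaussian random-field quantitative layers (think climate surfaces), an
#' elevation layer, a categorical land-cover layer obtained by
#' quantile-slicing another smooth field, and (optionally) an island mask
#' turning off-island cells into NoData "sea" — the situation that makes
#' records fall on cells without environmental data.
#'
#' @param rows,cols Grid dimensions (>= 8).
#' @param cellsize Cell edge length in metres (default 1000: 1-km cells).
#' @param n_quant Number of quantitative climate-like layers (default 2;
#'   an elevation layer is always added).
#' @param n_classes Land-cover classes (default 4).
#' @param spatial_scale Field correlation length in cells (default 10).
#' @param island Add an island mask (default TRUE)?
#' @param seed Integer seed.
#' @return A `red_stack` with layers `clim1..climK`, `elevation`
#'   (metres), and categorical `landcover`.
#' @export
gen_landscape <- function(rows = 100, cols = 100, cellsize = 1000,
                          n_quant = 2, n_classes = 4, spatial_scale = 10,
                          island = TRUE, seed = 1) {
  if (rows < 8 || cols < 8) stop("grid must be at least 8 x 8")
  set.seed(seed)
  mask <- NULL
  if (island) {
    rr <- (row(matrix(0, rows, cols)) - (rows + 1) / 2) / (rows / 2)
    cc <- (col(matrix(0, rows, cols)) - (cols + 1) / 2) / (cols / 2)
    base <- 1 - sqrt(rr^2 + cc^2) + 0.35 * gaussian_field(rows, cols, spatial_scale)
    mask <- base > stats::quantile(base, 0.45)   # ~55% land
  }
  mk <- function(v, name, categorical = FALSE) {
    if (!is.null(mask)) v[!mask] <- NA
    red_raster(v, xmin = 0, ymax = rows * cellsize, cellsize = cellsize,
               crs = "metric", categorical = categorical, name = name)
  }
  layers <- list()
  for (i in seq_len(n_quant))
    layers[[paste0("clim", i)]] <-
      mk(15 + 8 * gaussian_field(rows, cols, spatial_scale), paste0("clim", i))
  elev_field <- gaussian_field(rows, cols, spatial_scale)
  if (island) {
    # elevation rises towards the island interior, like a volcanic island
    rr <- (row(matrix(0, rows, cols)) - (rows + 1) / 2) / (rows / 2)
    cc <- (col(matrix(0, rows, cols)) - (cols + 1) / 2) / (cols / 2)
    elev_field <- elev_field + 2 * (1 - sqrt(rr^2 + cc^2))
  }
  elev <- 900 * (elev_field - min(elev_field)) / diff(range(elev_field)) * 2
  layers[["elevation"]] <- mk(elev, "elevation")
  lc_field <- gaussian_field(rows, cols, spatial_scale)
  if (!is.null(mask)) lc_field[!mask] <- NA
  qs <- stats::quantile(lc_field, probs = seq_len(n_classes - 1) / n_classes,
                        na.rm = TRUE)
  lc <- matrix(findInterval(lc_field, qs) + 1, rows, cols)
  layers[["landcover"]] <- mk(lc, "landcover", categorical = TRUE)
  red_stack(layers)
}

#' Generate a virtual species
#'
#' A virtual species has a known true suitability surface — the logistic
#' of a linear combination of the standardized quantitative layers — and
#' a known true presence raster (suitability >= cutoff), so distribution-
#' model output can be validated against truth.
#'
#' @param landscape A `red_stack` (categorical layers ignored).
#' @param coefficients Numeric response coefficients, one per
#'   quantitative layer.
#' @param cutoff Occupancy cutoff on suitability (default 0.5).
#' @param intercept Intercept on the logit scale (default 0).
#' @return An object of class `virtual_species`: `suitability` and
#'   `presence` rasters, plus `coefficients` and `cutoff`.
#' @export
gen_virtual_species <- function(landscape, coefficients, cutoff = 0.5,
                                intercept = 0) {
  q <- quantitative_layers(landscape)
  if (length(coefficients) != length(q))
    stop("need one coefficient per quantitative layer (", length(q), ")")
  if (all(coefficients == 0))
    warning("all-zero coefficients: uniform suitability 0.5")
  vals <- sapply(q, function(l) as.vector(l$values))
  ok <- stats::complete.cases(vals)
  z <- scale(vals[ok, , drop = FALSE])
  eta <- intercept + as.vector(z %*% coefficients)
  suit <- rep(NA_real_, nrow(vals))
  suit[ok] <- stats::plogis(eta)
  tmpl <- q[[1L]]
  suit_r <- red_raster(matrix(suit, nrow = n_rows(tmpl)), xmin = tmpl$xmin,
                       ymax = tmpl$ymax, cellsize = tmpl$cellsize,
                       crs = tmpl$crs, name = "true_suitability")
  pres_r <- red_raster(matrix(as.numeric(suit >= cutoff), nrow = n_rows(tmpl)),
                       xmin = tmpl$xmin, ymax = tmpl$ymax,
                       cellsize = tmpl$cellsize, crs = tmpl$crs,
                       name = "true_presence")
  structure(list(suitability = suit_r, presence = pres_r,
                 coefficients = coefficients, cutoff = cutoff),
            class = "virtual_species")
}

#' Sample occurrence records of a virtual species
#'
#' Draws record locations from the species' true presence cells, either
#' uniformly or clustered around a random focal cell (emulating the
#' clumped, accessibility-biased sampling that spatial thinning exists to
#' fix). With probability `error_rate` a record is displaced by a random
#' offset, landing possibly in the sea or outside the range (to exercise
#' [move_to_valid()] and [detect_outliers()]).
#'
#' @param species A `virtual_species`.
#' @param n Number of records.
#' @param bias `"none"` (uniform over presence cells) or `"clustered"`.
#' @param error_rate Probability a record is displaced (default 0).
#' @param cluster_scale SD of the clustering kernel, in cells (default 8).
#' @param seed Integer seed.
#' @return An [occurrences] object (metric).
#' @export
gen_occurrences <- function(species, n = 30, bias = c("none", "clustered"),
                            error_rate = 0, cluster_scale = 8, seed = 1) {
  bias <- match.arg(bias)
  if (n < 1) stop("n must be >= 1")
  pres <- species$presence
  idx <- which(!is.na(pres$values) & pres$values == 1)
  if (!length(idx)) stop("species has no presence cells")
  set.seed(seed)
  nr <- n_rows(pres)
  rc_all <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
  replace <- length(idx) < n
  if (replace && bias == "none")
    warning("more records than presence cells; sampling with replacement")
  if (bias == "none") {
    pick <- sample(seq_along(idx), n, replace = replace)
  } else {
    focal <- rc_all[sample(seq_along(idx), 1L), ]
    d2 <- (rc_all[, 1L] - focal[1L])^2 + (rc_all[, 2L] - focal[2L])^2
    wts <- exp(-d2 / (2 * cluster_scale^2))
    pick <- sample(seq_along(idx), n, replace = TRUE, prob = wts)
  }
  ctr <- cell_center(pres, rc_all[pick, , drop = FALSE])
  cs <- pres$cellsize
  x <- ctr[, 1L] + stats::runif(n, -cs / 2, cs / 2)
  y <- ctr[, 2L] + stats::runif(n, -cs / 2, cs / 2)
  err <- stats::runif(n) < error_rate
  if (any(err)) {
    x[err] <- x[err] + stats::rnorm(sum(err), sd = 5 * cs)
    y[err] <- y[err] + stats::rnorm(sum(err), sd = 5 * cs)
    ext_x <- c(pres$xmin, pres$xmin + n_cols(pres) * cs)
    ext_y <- c(pres$ymax - nr * cs, pres$ymax)
    x <- pmin(pmax(x, ext_x[1L] + cs / 2), ext_x[2L] - cs / 2)
    y <- pmin(pmax(y, ext_y[1L] + cs / 2), ext_y[2L] - cs / 2)
  }
  occurrences(x, y, crs = "metric")
}

#' Generate a category table by Markov evolution
#'
#' Species start in categories drawn from `init` and evolve between
#' assessment dates by a Markov transition matrix over the category
#' ladder — the identity matrix gives a "null" table with no change,
#' useful for calibrating the significance test.
#'
#' @param n_species,n_dates Table dimensions.
#' @param transition Square row-stochastic matrix over `categories`
#'   (default identity: no change).
#' @param init Initial category probabilities (default uniform over
#'   LC..CR).
#' @param categories Category codes indexing `transition` (default
#'   LC, NT, VU, EN, CR, EX).
#' @param seed Integer seed.
#' @return Character matrix n_species x n_dates, date labels as column
#'   names.
#' @export
gen_category_table <- function(n_species = 20, n_dates = 2,
                               transition = NULL, init = NULL,
                               categories = c("LC", "NT", "VU", "EN", "CR", "EX"),
                               seed = 1) {
  k <- length(categories)
  if (is.null(transition)) transition <- diag(k)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == k) ||
      any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0))
    stop("transition must be a ", k, "x", k, " row-stochastic matrix")
  if (is.null(init)) {
    init <- rep(0, k)
    init[seq_len(min(5L, k))] <- 1 / min(5L, k)
  }
  set.seed(seed)
  state <- sample.int(k, n_species, replace = TRUE, prob = init)
  out <- matrix("", n_species, n_dates)
  out[, 1L] <- categories[state]
  if (n_dates > 1L) for (d in 2:n_dates) {
    state <- vapply(state, function(s)
      sample.int(k, 1L, prob = transition[s, ]), integer(1))
    out[, d] <- categories[state]
  }
  colnames(out) <- as.character(seq(2000, by = 10, length.out = n_dates))
  out
}

#' The island-spider worked example fixture
#'
#' A self-contained desk-scale analogue of a classic single-island
#' endemic assessment: a 100 x 100 island landscape (two climate layers,
#' elevation, 4-class land cover, sea as NoData), a virtual species with
#' a strong climate response, and 10 occurrence records of which one lies
#' in the sea (as happens with real georeferencing).
#'
#' @param seed Integer seed (default 42).
#' @return List with `layers` (`red_stack`), `species`
#'   (`virtual_species`) and `records` ([occurrences], 10 rows).
#' @export
island_spider_fixture <- function(seed = 42) {
  layers <- gen_landscape(seed = seed)
  # negative intercept makes the species a restricted endemic occupying
  # roughly a tenth of the island rather than a third of it
  species <- gen_virtual_species(layers, coefficients = c(4, -2, 1.5),
                                 intercept = -2)
  records <- gen_occurrences(species, n = 10, bias = "clustered", seed = seed + 1)
  # displace one record into the sea: walk from the last record towards
  # the nearest NoData cell and drop it there
  ref <- layers[[1L]]
  sea <- which(is.na(ref$values))
  if (length(sea)) {
    nr <- n_rows(ref)
    rc <- cbind(((sea - 1L) %% nr) + 1L, ((sea - 1L) %/% nr) + 1L)
    ctr <- cell_center(ref, rc)
    d2 <- (ctr[, 1L] - records$x[10L])^2 + (ctr[, 2L] - records$y[10L])^2
    k <- which.min(d2)
    records$x[10L] <- ctr[k, 1L]
    records$y[10L] <- ctr[k, 2L]
  }
  list(layers = layers, species = species, records = records)
}
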