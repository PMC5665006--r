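# EOO, AOO, projection, elevation and countries.

test_that("projection leaves metric input unchanged and centres geographic input", {
  met <- occurrences(c(1000, 2000), c(500, 700), crs = "metric")
  expect_identical(project_to_metric(met), met)

  one <- project_to_metric(occurrences(-17, 32.8))
  expect_equal(c(one$x, one$y), c(0, 0), tolerance = 1e-9)

  # one degree of longitude at the equator is ~111.32 km on the ground
  p <- project_to_metric(occurrences(c(0, 1), c(0, 0)))
  d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  expect_lt(abs(d - 111320) / 111320, 0.005)
})

test_that("projected distances agree with geodesic distances at regional scale", {
  skip_if_not_installed("geosphere")
  set.seed(11)
  lon <- runif(6, -17.3, -16.6)
  lat <- runif(6, 32.6, 32.9)
  p <- project_to_metric(occurrences(lon, lat))
  for (i in 1:5) {
    planar <- sqrt((p$x[i] - p$x[6])^2 + (p$y[i] - p$y[6])^2)
    geo <- geosphere::distGeo(c(lon[i], lat[i]), c(lon[6], lat[6]))
    expect_lt(abs(planar - geo) / geo, 0.005)
  }
})

test_that("projection rejects bad input", {
  expect_error(occurrences(c(1, NA), c(2, 3)), "missing")
  expect_error(occurrences(200, 10, crs = "geographic"), "valid geographic")
  expect_error(occurrences(numeric(0), numeric(0)), "no records")
})

test_that("EOO of simple shapes is exact and degenerate hulls floor at AOO", {
  sq <- occurrences(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000), crs = "metric")
  expect_identical(eoo(sq), 100)
  expect_identical(eoo(occurrences(500, 500, crs = "metric")), 4)
  # two points and collinear points: hull area 0, floored at their AOO
  two <- occurrences(c(0, 30000), c(0, 0), crs = "metric")
  expect_identical(eoo(two), aoo(two))
  lin <- occurrences(c(0, 5000, 10000, 20000), rep(100, 4), crs = "metric")
  expect_identical(eoo(lin), aoo(lin))
})

test_that("EOO equals a gift-wrapping hull oracle on random configurations", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    x <- runif(n, 0, 1e5); y <- runif(n, 0, 1e5)
    got <- eoo(occurrences(x, y, crs = "metric"))
    want <- max(oracle_hull_area(x, y) / 1e6,
                4 * nrow(unique(cbind(floor(x / 2000), floor(y / 2000)))))
    expect_equal(got, want, tolerance = 1e-6)
  }
  # exhaustive small-n battery
  for (n in 3:8) for (rep in 1:5) {
    x <- runif(n, 0, 5e4); y <- runif(n, 0, 5e4)
    got <- eoo(occurrences(x, y, crs = "metric"))
    want <- max(oracle_hull_area(x, y) / 1e6,
                4 * nrow(unique(cbind(floor(x / 2000), floor(y / 2000)))))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("AOO counts distinct 2-km cells at 4 km2 each", {
  expect_identical(aoo(occurrences(100, 100, crs = "metric")), 4)
  in_one <- occurrences(c(100, 900, 1900), c(100, 1500, 300), crs = "metric")
  expect_identical(aoo(in_one), 4)
  set.seed(7)
  x <- runif(10, 0, 1e5); y <- runif(10, 0, 1e5)
  want <- 4 * nrow(unique(cbind(floor(x / 2000), floor(y / 2000))))
  expect_identical(aoo(occurrences(x, y, crs = "metric")), want)
})

test_that("EOO and AOO respect duplication, permutation and monotonicity", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    x <- runif(n, 0, 2e5); y <- runif(n, 0, 2e5)
    occ <- occurrences(x, y, crs = "metric")
    expect_gte(eoo(occ), aoo(occ))
    dup <- occurrences(c(x, x[1]), c(y, y[1]), crs = "metric")
    expect_identical(aoo(dup), aoo(occ))
    perm <- sample(n)
    expect_equal(eoo(occurrences(x[perm], y[perm], crs = "metric")), eoo(occ))
    extra <- occurrences(c(x, runif(1, 0, 2e5)), c(y, runif(1, 0, 2e5)),
                         crs = "metric")
    expect_gte(eoo(extra), eoo(occ))
    expect_gte(aoo(extra), aoo(occ))
  }
})

test_that("raster input uses presence-cell centres (EOO) and any-overlap (AOO)", {
  # single 3-km presence cell at origin overlaps four 2-km cells
  r3 <- red_raster(matrix(c(1, 0, 0, 0), 2, 2), xmin = 0, ymax = 6000,
                   cellsize = 3000)
  expect_identical(aoo(r3), 16)
  # presence centres: (1500, 4500) -> single 2-km cell for EOO's floor
  expect_identical(eoo(r3), 4)
  m <- matrix(0, 10, 10); m[c(1, 55, 100)] <- 1
  r1 <- red_raster(m, xmin = 0, ymax = 10000, cellsize = 1000)
  idx <- which(m == 1)
  cx <- ((idx - 1) %/% 10 + 0.5) * 1000
  cy <- 10000 - ((idx - 1) %% 10 + 0.5) * 1000
  expect_equal(eoo(r1), eoo(occurrences(cx, cy, crs = "metric")))
  expect_error(aoo(red_raster(matrix(0, 3, 3))), "no presences")
})

test_that("elevation range samples the DEM at record cells", {
  dem <- red_raster(matrix(c(10, 250, 1800, NA), 2, 2), xmin = 0,
                    ymax = 2000, cellsize = 1000)
  rec <- occurrences(c(500, 500, 1500), c(1500, 500, 1500), crs = "metric")
  expect_identical(elevation_range(rec, dem), c(min = 10, max = 1800))
  one <- occurrences(c(500, 600), c(1500, 1400), crs = "metric")
  expect_identical(elevation_range(one, dem), c(min = 10, max = 10))
  bad <- occurrences(c(500, 1500), c(1500, 500), crs = "metric")
  expect_error(elevation_range(bad, dem), "2")
  # synthetic cone DEM: sampled values match direct cell lookup
  cone <- outer(1:20, 1:20, function(r, c) 2000 - 50 * pmax(abs(r - 10), abs(c - 10)))
  demc <- red_raster(cone, xmin = 0, ymax = 20000, cellsize = 1000)
  set.seed(3)
  x <- runif(15, 0, 20000); y <- runif(15, 0, 20000)
  want <- vapply(seq_len(15), function(i)
    cone[ceiling((20000 - y[i]) / 1000), ceiling(x[i] / 1000)], numeric(1))
  expect_identical(elevation_range(occurrences(x, y, crs = "metric"), demc),
                   c(min = min(want), max = max(want)))
})

test_that("countries_of matches an independent point-in-polygon oracle", {
  tiling <- three_polygon_tiling()
  expect_identical(countries_of(occurrences(0.25, 0.5, crs = "metric"), tiling),
                   "A")
  expect_identical(
    countries_of(occurrences(c(0.2, 0.8), c(0.5, 0.25), crs = "metric"), tiling),
    c("A", "B"))
  expect_identical(
    countries_of(occurrences(5, 5, crs = "metric"), tiling), character(0))
  skip_if_not_installed("mgcv")
  set.seed(21)
  x <- runif(50); y <- runif(50)
  got <- countries_of(occurrences(x, y, crs = "metric"), tiling)
  want <- sort(names(tiling)[vapply(tiling, function(rings) {
    bnd <- rings[[1L]]
    any(mgcv::in.out(rbind(bnd, bnd[1L, ]), cbind(x, y)))
  }, logical(1))])
  expect_identical(got, want)
})
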