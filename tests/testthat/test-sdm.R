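# Presence-background modelling, AUC, ensembles and consensus maps.

test_that("background sampling is exhaustive, deterministic and uniform", {
  v <- matrix(NA_real_, 5, 4)
  v[c(1, 3, 7, 9, 12, 15, 17, 18, 19, 20)] <- 1
  r <- red_stack(red_raster(v, ymax = 5, cellsize = 1, name = "a"))
  all10 <- suppressWarnings(sample_background(r, 15, seed = 1))
  expect_identical(nrow(all10), 10L)
  expect_warning(sample_background(r, 15, seed = 1), "using all")
  s1 <- sample_background(r, 4, seed = 7)
  s2 <- sample_background(r, 4, seed = 7)
  expect_identical(s1, s2)
  # chi-square uniformity over many draws of single cells
  set.seed(123)
  counts <- table(replicate(4000, {
    b <- sample_background(r, 1)
    paste(b$x, b$y)
  }))
  expect_length(counts, 10L)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("AUC follows the Mann-Whitney formulation", {
  expect_identical(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_identical(auc(c(0.7, 0.8, 0.9), c(0.1, 0.2)), 1)
  expect_identical(auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)
  skip_if_not_installed("pROC")
  set.seed(4)
  p <- rnorm(40, 1); b <- rnorm(60)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = rep(1:0, c(40, 60)), predictor = c(p, b), quiet = TRUE,
    direction = "<", levels = c(0, 1))))
  expect_equal(auc(p, b), want, tolerance = 1e-12)
})

test_that("maxent-style fits separate separable data and not null data", {
  set.seed(10)
  # separable 1-D fixture: presences at high covariate values
  pres <- cbind(v = rnorm(30, 10, 0.5), w = rnorm(30))
  back <- cbind(v = rnorm(500, 0, 0.5), w = rnorm(500))
  m <- fit_maxent_like(pres, back)
  a <- auc(predict(m, pres), predict(m, back))
  expect_gt(a, 0.95)
  # predictions invariant under affine rescaling of a covariate
  resc <- function(mat) cbind(v = 3 * mat[, 1] - 100, w = mat[, 2])
  set.seed(11)
  m2 <- fit_maxent_like(resc(pres), resc(back))
  expect_equal(predict(m2, resc(pres)), predict(m, pres), tolerance = 1e-6)
  # no signal: AUC near one half
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    p0 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("v", "w")))
    b0 <- matrix(rnorm(800), 400, 2, dimnames = list(NULL, c("v", "w")))
    f <- fit_maxent_like(p0, b0)
    auc(predict(f, p0), predict(f, b0))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(fit_maxent_like(pres[1:4, ], back), "at least 5")
})

test_that("ensembles are internally consistent and seed-reproducible", {
  fx <- island_spider_fixture()
  rec <- gen_occurrences(fx$species, n = 20, seed = 3)
  layers <- fx$layers[1:3]
  e1 <- run_ensemble(rec, layers, runs = 2, background_n = 300, seed = 5)
  expect_length(e1, 2L)
  r1 <- e1[[1]]
  expect_identical(r1$binary$values,
                   ifelse(is.na(r1$prob$values), NA_real_,
                          as.numeric(r1$prob$values >= r1$threshold)))
  expect_true(all(r1$prob$values >= 0 & r1$prob$values <= 1, na.rm = TRUE))
  expect_gte(r1$auc, 0); expect_lte(r1$auc, 1)
  e2 <- run_ensemble(rec, layers, runs = 2, background_n = 300, seed = 5)
  expect_identical(lapply(e1, function(r) r$binary$values),
                   lapply(e2, function(r) r$binary$values))
  expect_identical(vapply(e1, `[[`, numeric(1), "auc"),
                   vapply(e2, `[[`, numeric(1), "auc"))
})

test_that("consensus arithmetic follows the AUC-squared weighting rule", {
  # three runs, AUCs 1.0 / 0.9 / 0.6 -> weights 0.25 / 0.16 / 0.01
  b1 <- matrix(c(1, 1, 0, 0), 2, 2)
  b2 <- matrix(c(1, 0, 1, 0), 2, 2)
  b3 <- matrix(c(0, 1, 1, 0), 2, 2)
  cm <- consensus_map(list(fake_run(b1, 1.0), fake_run(b2, 0.9),
                           fake_run(b3, 0.6)))
  expect_equal(cm$weights, c(0.25, 0.16, 0.01))
  # cell (1,1): present in runs 1-2 -> score 0.41/0.42 = 0.976 > 0.5
  expect_identical(cm$consensus$values[1, 1], 1)
  # present in 2/3 of runs: in the upper CL (>= 2.5%), not the lower (< 97.5%)
  expect_identical(cm$upper$values[1, 1], 1)
  expect_identical(cm$lower$values[1, 1], 0)
  # cell (2,2): present nowhere
  expect_identical(cm$consensus$values[2, 2], 0)
  expect_identical(cm$upper$values[2, 2], 0)
  # unanimity: consensus = lower = upper = the map
  uni <- consensus_map(lapply(1:4, function(i) fake_run(b1, 1.0)))
  expect_identical(uni$consensus$values, b1)
  expect_identical(uni$lower$values, b1)
  expect_identical(uni$upper$values, b1)
  # all-uninformative ensembles are refused
  expect_error(consensus_map(list(fake_run(b1, 0.5), fake_run(b2, 0.4))),
               "uninformative")
})

test_that("confidence-limit maps use unweighted run frequencies at 97.5/2.5", {
  set.seed(6)
  base <- matrix(1, 1, 1)
  mk_runs <- function(n_present, n_total) {
    c(lapply(seq_len(n_present), function(i) fake_run(base, 0.9)),
      lapply(seq_len(n_total - n_present), function(i)
        fake_run(matrix(0, 1, 1), 0.9)))
  }
  cm98 <- consensus_map(mk_runs(98, 100))
  expect_identical(cm98$lower$values[1, 1], 1)   # 98% >= 97.5%
  cm2 <- consensus_map(mk_runs(2, 100))
  expect_identical(cm2$lower$values[1, 1], 0)
  expect_identical(cm2$upper$values[1, 1], 0)    # 2% < 2.5%
  cm3 <- consensus_map(mk_runs(3, 100))
  expect_identical(cm3$upper$values[1, 1], 1)    # 3% >= 2.5%
})

test_that("lower CL nests in upper CL and consensus is weight-scale invariant", {
  set.seed(14)
  for (i in 1:20) {
    runs <- lapply(1:8, function(j)
      fake_run(matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6, 6),
               runif(1, 0.55, 1)))
    cm <- consensus_map(runs)
    expect_true(all(cm$upper$values[cm$lower$values == 1] == 1))
    expect_lte(cm$ranges["lower", "aoo"], cm$ranges["upper", "aoo"])
    expect_lte(cm$ranges["lower", "eoo"], cm$ranges["upper", "eoo"])
    # equal weights: lower <= consensus <= upper cellwise
    eq <- consensus_map(lapply(runs, function(r) { r$auc <- 0.8; r }))
    expect_true(all(eq$consensus$values[eq$lower$values == 1] == 1))
    expect_true(all(eq$upper$values[eq$consensus$values == 1] == 1))
  }
})

test_that("map_points marks exactly the record cells", {
  fx <- island_spider_fixture()
  rec <- move_to_valid(fx$records, fx$layers)
  mp <- map_points(rec, fx$layers)
  # direct binning oracle
  want <- sort(unique(ceiling((1e5 - rec$y) / 1000) +
                      100 * (ceiling(rec$x / 1000) - 1)))
  expect_identical(which(mp$raster$values == 1), as.integer(want))
  expect_identical(mp$range[["eoo"]], eoo(rec))
  expect_identical(mp$range[["aoo"]], aoo(rec))
  # duplicates collapse to one cell
  dup <- occurrences(c(50500, 50500), c(50500, 50600), crs = "metric")
  expect_identical(sum(map_points(dup, fx$layers)$raster$values == 1,
                       na.rm = TRUE), 1L)
  off <- occurrences(-5, -5, crs = "metric")
  expect_error(map_points(off, fx$layers), "1")
})

test_that("map_easy writes per-species outputs and a consistent summary", {
  fx <- island_spider_fixture()
  rec <- move_to_valid(fx$records, fx$layers)
  two <- occurrences(c(rec$x, rec$x + 500), c(rec$y, rec$y),
                     species = rep(c("spA", "spB"), each = nrow(rec)))
  attr(two, "crs") <- "metric"
  out <- file.path(tempdir(), "easy_points")
  res <- map_easy(two, fx$layers, mode = "points", output_dir = out)
  expect_identical(nrow(res), 2L)
  for (sp in c("spA", "spB")) {
    expect_true(file.exists(file.path(out, paste0(sp, ".asc"))))
    expect_true(file.exists(file.path(out, paste0(sp, ".png"))))
    expect_true(file.exists(file.path(out, paste0(sp, ".kml"))))
  }
  expect_true(file.exists(file.path(out, "summary.csv")))
  # componentwise consistency with direct eoo/aoo calls
  ra <- occurrences(rec$x, rec$y, crs = "metric")
  expect_equal(res$eoo[res$species == "spA"], eoo(ra))
  expect_equal(res$aoo[res$species == "spA"], aoo(ra))
  # a 1-record species under sdm is skipped, not fatal
  tiny <- occurrences(c(rec$x, 50500), c(rec$y, 50500),
                      species = c(rep("ok", nrow(rec)), "rare"))
  attr(tiny, "crs") <- "metric"
  res2 <- suppressMessages(
    map_easy(tiny, fx$layers[1:3], mode = "sdm",
             output_dir = file.path(tempdir(), "easy_sdm"),
             runs = 2, seed = 2))
  expect_true(is.na(res2$eoo[res2$species == "rare"]))
  expect_false(res2$status[res2$species == "rare"] == "ok")
})
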