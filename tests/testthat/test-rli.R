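# Red List Index: weights, point estimates, bootstrap, groups, SRLI.

worked_table <- function() {
  matrix(c("LC", "LC", "EN", "EN", "EX", "EX", "LC", "CR", "CR", "EX"),
         ncol = 2, byrow = TRUE, dimnames = list(NULL, c("2000", "2010")))
}

test_that("category weights climb the ladder from LC = 0 to EX/EW = 5", {
  expect_identical(category_weight(c("LC", "NT", "VU", "EN", "CR", "EW", "EX")),
                   c(0, 1, 2, 3, 4, 5, 5))
  expect_error(category_weight("XX"), "XX")
  expect_error(category_weight("DD"), "DD")
})

test_that("the index equals 1 - sum(w)/(5N) with the worked example at 0.52/0.32", {
  tab <- worked_table()
  expect_identical(rli_point(tab[, "2000"]), 1 - 12 / 25)
  expect_identical(rli_point(tab[, "2010"]), 1 - 17 / 25)
  expect_identical(rli_point(rep("LC", 7)), 1)
  expect_identical(rli_point(rep("EX", 4)), 0)
  # permutation-invariant, and equal to 1 - mean(weight)/5
  set.seed(1)
  cats <- sample(c("LC", "NT", "VU", "EN", "CR", "EX"), 30, replace = TRUE)
  expect_identical(rli_point(cats), rli_point(sample(cats)))
  expect_equal(rli_point(cats), 1 - mean(category_weight(cats)) / 5)
})

test_that("one-step worsening of one species lowers the index by 1/(5N)", {
  ladder <- c("LC", "NT", "VU", "EN", "CR", "EX")
  set.seed(2)
  cats <- sample(ladder[1:5], 12, replace = TRUE)
  for (i in c(1, 7, 12)) {
    worse <- cats
    worse[i] <- ladder[match(cats[i], ladder) + 1L]
    expect_equal(rli_point(cats) - rli_point(worse), 1 / (5 * 12))
  }
})

test_that("DD species are excluded by default but can be given a fixed weight", {
  expect_identical(rli_point(c("LC", "DD", "EX")), 1 - 5 / 10)
  expect_equal(rli_point(c("LC", "DD", "EX"), dd = "category"),
               1 - 7 / 15)
  expect_error(rli_point(c("DD", "DD")), "no assessable")
})

test_that("bootstrap limits behave on degenerate tables", {
  const <- matrix("LC", 6, 2, dimnames = list(NULL, c("a", "b")))
  res <- rli_bootstrap(const, reps = 200, seed = 1)
  expect_identical(res$index$rli, c(1, 1))
  expect_identical(res$index$lower, c(1, 1))
  expect_identical(res$index$upper, c(1, 1))
  expect_false(any(res$significant))
  one <- matrix(c("EN", "CR"), 1, 2, dimnames = list(NULL, c("a", "b")))
  r1 <- rli_bootstrap(one, reps = 100, seed = 1)
  expect_identical(r1$index$lower, r1$index$rli)
  expect_identical(r1$index$upper, r1$index$rli)
  expect_error(rli_bootstrap(const, reps = 1), "reps")
})

test_that("bootstrap replicates are consistent with the point estimate", {
  res <- rli_bootstrap(worked_table(), reps = 10000, seed = 42)
  expect_lt(max(abs(colMeans(res$replicates) - res$index$rli)), 0.02)
  # limits bracket the point and the replicate median
  expect_true(all(res$index$lower <= res$index$rli + 1e-12))
  expect_true(all(res$index$upper >= res$index$rli - 1e-12))
  med <- apply(res$replicates, 2, median)
  expect_true(all(res$index$lower <= med & med <= res$index$upper))
})

test_that("bootstrap interval width shrinks with species count", {
  widths <- vapply(c(5, 50, 500), function(n) {
    set.seed(3)
    tab <- cbind(sample(c("LC", "VU", "EN", "CR"), n, replace = TRUE))
    colnames(tab) <- "t1"
    r <- rli_bootstrap(tab, reps = 1000, seed = 4)
    r$index$upper - r$index$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("multi-group RLI reduces to per-group bootstraps", {
  tab <- cbind(c("Arthropods", "Arthropods", "Birds", "Birds", "Birds"),
               worked_table())
  res <- rli_multi(tab, reps = 300, seed = 5)
  expect_named(res, c("Arthropods", "Birds"))
  expect_equal(res$Birds$index$rli,
               c(rli_point(worked_table()[3:5, 1]),
                 rli_point(worked_table()[3:5, 2])))
  solo <- rli_multi(cbind("only", worked_table()), reps = 300, seed = 6)
  direct <- rli_bootstrap(worked_table(), reps = 300, seed = 6)
  expect_equal(solo$only$index, direct$index)
  # a group with no assessable species warns and yields NA
  dd <- rbind(cbind("good", worked_table()),
              cbind("bad", matrix("DD", 2, 2,
                                  dimnames = list(NULL, c("2000", "2010")))))
  expect_warning(res2 <- rli_multi(dd, reps = 100, seed = 1), "bad")
  expect_identical(res2$bad, NA)
})

test_that("sampled RLI: zero-variance tables need only 2 species, n = N is exact", {
  same <- matrix("VU", 10, 2, dimnames = list(NULL, c("a", "b")))
  res <- rli_sampled(same, max_error = 0.05, reps = 100, seed = 1)
  expect_identical(res$n_min, 2L)
  expect_true(all(res$curve$error == 0))
  mixed <- gen_category_table(n_species = 12, seed = 9,
                              init = c(0.3, 0.2, 0.2, 0.15, 0.1, 0.05))
  r2 <- rli_sampled(mixed, max_error = 0.05, reps = 300, seed = 2)
  expect_identical(r2$curve$error[r2$curve$n == 12], 0)
  expect_warning(rli_sampled(mixed, max_error = 1.5, reps = 50, seed = 1),
                 "trivially")
})

test_that("sampled RLI curve decreases and the minimal n is oracle-stable", {
  tab <- gen_category_table(n_species = 20, seed = 31,
                            init = c(0.35, 0.2, 0.15, 0.15, 0.1, 0.05))
  res <- rli_sampled(tab, max_error = 0.05, reps = 600, seed = 7)
  # non-increasing within Monte Carlo noise: allow small upward jitter
  expect_true(all(diff(res$curve$error) < 0.02))
  # independent re-simulation with a different RNG stream
  wmat <- matrix(category_weight(tab), nrow = 20)
  full <- 1 - colSums(wmat) / (5 * 20)
  set.seed(12345)
  err <- vapply(2:20, function(k) {
    if (k == 20) return(0)
    dev <- replicate(600, {
      rows <- sample.int(20, k)
      max(abs((1 - colSums(wmat[rows, , drop = FALSE]) / (5 * k)) - full))
    })
    unname(quantile(dev, 0.95))
  }, numeric(1))
  n_min_oracle <- min(c(2:20)[err <= 0.05])
  expect_lte(abs(res$n_min - n_min_oracle), 1)
  f <- tempfile(fileext = ".png")
  plot(res, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("category tables read from CSV feed the index unchanged", {
  tab <- worked_table()
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), f, row.names = FALSE)
  back <- read_category_table(f)
  expect_identical(unname(as.matrix(back)), unname(tab))
  expect_identical(rli_bootstrap(back, reps = 100, seed = 1)$index$rli,
                   rli_bootstrap(tab, reps = 100, seed = 1)$index$rli)
})
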