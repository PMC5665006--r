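# Presence-background distribution modelling with multi-run ensembles.
# The model family is an L1-penalized logistic regression on standardized
# linear + quadratic features — the penalized-regression formulation of
# maximum-entropy (maxent) presence-background modelling — so no external
# modelling program is required. Ensembles of runs give AUC-weighted
# consensus maps and two-sided confidence-limit maps, which in turn give
# confidence limits for EOO and AOO.

# Environmental design matrix at given cells (rows of a (row,col) matrix).
env_at_cells <- function(stack, rc) {
  sapply(stack, function(l) l$values[rc]) |>
    matrix(nrow = nrow(rc), dimnames = list(NULL, names(stack)))
}

#' Sample background points
#'
#' Draws `n` distinct data-cell centres uniformly without replacement
#' from the cells where every quantitative layer has data. If fewer than
#' `n` data cells exist, all are returned with a warning.
#'
#' @param layers A `red_stack`.
#' @param n Number of background points (default 1000).
#' @param seed Optional integer seed.
#' @return An [occurrences] object of cell centres.
#' @export
sample_background <- function(layers, n = 1000, seed = NULL) {
  if (inherits(layers, "red_raster")) layers <- red_stack(layers)
  q <- quantitative_layers(layers)
  ok <- Reduce(`&`, lapply(q, function(l) !is.na(l$values)))
  idx <- which(ok)
  if (!length(idx)) stop("no data cells")
  if (!is.null(seed)) set.seed(seed)
  if (length(idx) < n) {
    warning("only ", length(idx), " data cells available; using all")
  } else {
    idx <- sort(sample(idx, n))
  }
  ref <- q[[1L]]
  rc <- cbind(((idx - 1L) %% n_rows(ref)) + 1L, ((idx - 1L) %/% n_rows(ref)) + 1L)
  ctr <- cell_center(ref, rc)
  occurrences(ctr[, 1L], ctr[, 2L], crs = ref$crs)
}

# linear + quadratic feature expansion of a standardized covariate matrix
expand_features <- function(z) {
  cbind(z, z^2, deparse.level = 0) |>
    `colnames<-`(c(colnames(z), paste0(colnames(z), "^2")))
}

#' Fit a maxent-style presence-background model
#'
#' Fits an L1-regularized logistic regression of presence (1) versus
#' background (0) on linear and quadratic features of the standardized
#' covariates. L1 (lasso) shrinkage plays the role of maxent's feature
#' regularization: it guards against overfitting and keeps complete
#' separation from blowing up the coefficients.
#'
#' @param presence_env Numeric matrix of covariate values at presence
#'   sites (rows = sites).
#' @param background_env Matrix of covariate values at background sites,
#'   same columns.
#' @param regularization Regularization multiplier (default 1): the lasso
#'   penalty is `regularization` times the cross-validated deviance-optimal
#'   penalty, so values above 1 give smoother, more conservative models.
#'   Penalty selection uses 5-fold cross-validation and therefore consumes
#'   random numbers; seed the RNG for reproducibility.
#' @return An object of class `maxent_like` with a [predict][stats::predict]
#'   method mapping covariates (matrix or `red_stack`) to suitability in
#'   \[0, 1\].
#' @export
fit_maxent_like <- function(presence_env, background_env, regularization = 1) {
  presence_env <- as.matrix(presence_env)
  background_env <- as.matrix(background_env)
  if (nrow(presence_env) < 5L) stop("need at least 5 presence records")
  if (is.null(colnames(presence_env)))
    colnames(presence_env) <- colnames(background_env) <-
      paste0("v", seq_len(ncol(presence_env)))
  all_env <- rbind(presence_env, background_env)
  ctr <- colMeans(all_env)
  scl <- apply(all_env, 2L, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(all_env, 2L, ctr), 2L, scl, "/")
  x <- expand_features(z)
  y <- rep(1:0, c(nrow(presence_env), nrow(background_env)))
  # stratified folds: tiny presence samples must reach every CV fold
  np <- nrow(presence_env); nb <- nrow(background_env)
  nfolds <- max(2L, min(5L, np))
  foldid <- c(sample(rep_len(seq_len(nfolds), np)),
              sample(rep_len(seq_len(nfolds), nb)))
  # few-presence fits trigger glmnet's small-class grumbling; expected here
  cv <- suppressWarnings(glmnet::cv.glmnet(x, y, family = "binomial",
                                           alpha = 1, foldid = foldid))
  structure(list(fit = cv$glmnet.fit, center = ctr, scale = scl,
                 lambda = regularization * cv$lambda.min,
                 vars = colnames(presence_env)),
            class = "maxent_like")
}

#' @describeIn fit_maxent_like Predict suitability for a covariate matrix
#'   or over a `red_stack` (returns a probability `red_raster`, NoData
#'   propagated).
#' @param object A `maxent_like` model.
#' @param newdata Covariate matrix (columns as in fitting) or `red_stack`.
#' @param ... Unused.
#' @export
predict.maxent_like <- function(object, newdata, ...) {
  if (inherits(newdata, "red_stack") || inherits(newdata, "red_raster")) {
    stack <- if (inherits(newdata, "red_raster")) red_stack(newdata) else newdata
    stack <- stack[object$vars]
    vals <- sapply(stack, function(l) as.vector(l$values))
    ok <- stats::complete.cases(vals)
    p <- rep(NA_real_, nrow(vals))
    p[ok] <- predict.maxent_like(object, vals[ok, , drop = FALSE])
    tmpl <- stack[[1L]]
    return(red_raster(matrix(p, nrow = n_rows(tmpl)), xmin = tmpl$xmin,
                      ymax = tmpl$ymax, cellsize = tmpl$cellsize,
                      crs = tmpl$crs, name = "suitability",
                      proj = tmpl$proj))
  }
  newdata <- as.matrix(newdata)[, object$vars, drop = FALSE]
  z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  x <- expand_features(z)
  as.vector(stats::predict(object$fit, newx = x, s = object$lambda,
                           type = "response"))
}

#' Area under the ROC curve (AUC)
#'
#' The probability that a randomly chosen presence site outscores a
#' randomly chosen background site, with ties counted one half — the
#' Mann–Whitney formulation.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.4), c(0.5, 0.1))  # 0.75
#' @export
auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (!np || !nb) stop("both score sets must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

# Threshold maximizing sensitivity + specificity; ties -> lowest threshold.
best_threshold <- function(pres_scores, back_scores) {
  cand <- sort(unique(c(pres_scores, back_scores)))
  vp <- sort(pres_scores); vb <- sort(back_scores)
  sens <- (length(vp) - findInterval(cand, vp, left.open = TRUE)) / length(vp)
  spec <- findInterval(cand, vb, left.open = TRUE) / length(vb)
  cand[which.max(sens + spec)]
}

binarize <- function(prob, threshold) {
  v <- ifelse(is.na(prob$values), NA_real_, as.numeric(prob$values >= threshold))
  red_raster(matrix(v, nrow = n_rows(prob)), xmin = prob$xmin,
             ymax = prob$ymax, cellsize = prob$cellsize, crs = prob$crs,
             name = "presence", proj = prob$proj)
}

#' Run a distribution-model ensemble
#'
#' Each run draws a fresh random split of the presence records into
#' training and test sets (70/30 by default) and a fresh background
#' sample, fits [fit_maxent_like()] on the training presences, predicts a
#' suitability raster, scores the run by its test AUC, and binarizes the
#' raster at the threshold maximizing sensitivity + specificity on the
#' training data. Run-to-run variation across splits and background
#' samples is what the ensemble's confidence limits summarize.
#'
#' @param records An [occurrences] object (thinned/cleaned upstream), in
#'   the stack's coordinates.
#' @param layers A `red_stack` of quantitative predictors.
#' @param runs Number of runs (default 100).
#' @param test_fraction Fraction of presences held out per run (default
#'   0.3; 0 scores the AUC on the training presences instead).
#' @param background_n Background sample size per run (default 1000).
#' @param regularization Passed to [fit_maxent_like()].
#' @param seed Master seed; per-run seeds are derived from it, so a fixed
#'   seed makes the whole ensemble reproducible.
#' @return List of `sdm_run` objects: `model`, `prob` (suitability
#'   raster), `threshold`, `auc`, `binary` (presence raster).
#' @export
run_ensemble <- function(records, layers, runs = 100, test_fraction = 0.3,
                         background_n = 1000, regularization = 1, seed = 1) {
  if (inherits(layers, "red_raster")) layers <- red_stack(layers)
  layers <- quantitative_layers(layers)
  env <- extract_values(layers, records$x, records$y)
  if (anyNA(env))
    stop("record(s) ", paste(which(rowSums(is.na(env)) > 0), collapse = ", "),
         " fall on NoData cells; run move_to_valid first")
  n <- nrow(env)
  n_test <- floor(test_fraction * n)
  if (n - n_test < 5L)
    stop("fewer than 5 training presences after the test split")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)
  lapply(seq_len(runs), function(r) {
    res <- tryCatch({
      set.seed(run_seeds[r])
      test <- if (n_test > 0) sample.int(n, n_test) else integer(0)
      train <- setdiff(seq_len(n), test)
      bg <- sample_background(layers, n = background_n)
      bg_env <- extract_values(layers, bg$x, bg$y)
      model <- fit_maxent_like(env[train, , drop = FALSE], bg_env,
                               regularization = regularization)
      train_scores <- predict(model, env[train, , drop = FALSE])
      bg_scores <- predict(model, bg_env)
      thr <- best_threshold(train_scores, bg_scores)
      test_scores <- if (n_test > 0) predict(model, env[test, , drop = FALSE])
                     else train_scores
      prob <- predict(model, layers)
      structure(list(model = model, prob = prob, threshold = thr,
                     auc = auc(test_scores, bg_scores),
                     binary = binarize(prob, thr), seed = run_seeds[r]),
                class = "sdm_run")
    }, error = function(e) stop("run ", r, ": ", conditionMessage(e),
                                call. = FALSE))
    res
  })
}

#' Consensus and confidence-limit maps from an ensemble
#'
#' Binarized per-run maps are combined three ways. The consensus map
#' weights each run by `max(0, AUC - 0.5)^2` and predicts presence where
#' the weighted vote exceeds 0.5 (strictly). The lower confidence-limit
#' map keeps cells suitable in at least 97.5\% of the runs; the upper
#' keeps cells suitable in at least 2.5\% — together a two-sided
#' confidence band for the range, from which EOO and AOO confidence
#' limits follow.
#'
#' @param runs List of `sdm_run` objects from [run_ensemble()].
#' @return An object of class `ensemble_result`: binary rasters
#'   `consensus`, `lower`, `upper`; `weights`; `freq` (per-cell run
#'   frequency raster); and `ranges`, a data frame with EOO and AOO (km^2)
#'   for the three maps.
#' @export
consensus_map <- function(runs) {
  if (!length(runs)) stop("no runs")
  w <- vapply(runs, function(r) max(0, r$auc - 0.5)^2, numeric(1))
  if (all(w == 0)) stop("ensemble uninformative: all AUC <= 0.5")
  tmpl <- runs[[1L]]$binary
  bs <- vapply(runs, function(r) as.vector(r$binary$values),
               numeric(length(tmpl$values)))
  bs <- matrix(bs, ncol = length(runs))
  wsum <- as.vector(bs %*% w) / sum(w)
  freq <- rowMeans(bs)
  mk <- function(v, name) {
    v[is.na(as.vector(tmpl$values))] <- NA
    red_raster(matrix(v, nrow = n_rows(tmpl)), xmin = tmpl$xmin,
               ymax = tmpl$ymax, cellsize = tmpl$cellsize, crs = tmpl$crs,
               name = name, proj = tmpl$proj)
  }
  consensus <- mk(as.numeric(wsum > 0.5), "consensus")
  lower <- mk(as.numeric(freq >= 0.975), "lower_cl")
  upper <- mk(as.numeric(freq >= 0.025), "upper_cl")
  rng <- function(r) {
    if (!any(r$values == 1, na.rm = TRUE)) return(c(eoo = 0, aoo = 0))
    c(eoo = eoo(r), aoo = aoo(r))
  }
  ranges <- rbind(lower = rng(lower), consensus = rng(consensus),
                  upper = rng(upper))
  structure(list(consensus = consensus, lower = lower, upper = upper,
                 weights = w, freq = mk(freq, "run_frequency"),
                 ranges = as.data.frame(ranges)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble of %d run(s); mean weight %.3f\n",
              length(x$weights), mean(x$weights)))
  print(round(x$ranges, 2))
  invisible(x)
}

#' Map the recorded distribution of a species
#'
#' Marks exactly the cells containing records — the range map to use when
#' records are either too scarce to model or complete enough to need no
#' model — together with the records' EOO and AOO.
#'
#' @param records An [occurrences] object in the stack's coordinates.
#' @param layers A `red_stack` or `red_raster` defining the grid (and
#'   NoData mask).
#' @return A list of class `points_map`: `raster` (binary) and `range`
#'   (`c(eoo = , aoo = )`, km^2).
#' @export
map_points <- function(records, layers) {
  ref <- if (inherits(layers, "red_stack")) layers[[1L]] else layers
  rc <- cell_of(ref, records$x, records$y)
  bad <- which(is.na(rc[, 1L]))
  if (length(bad))
    stop("record(s) ", paste(bad, collapse = ", "), " fall outside the raster extent")
  pres <- matrix(0, n_rows(ref), n_cols(ref))
  pres[is.na(ref$values)] <- NA
  pres[rc] <- 1
  out <- red_raster(pres, xmin = ref$xmin, ymax = ref$ymax,
                    cellsize = ref$cellsize, crs = ref$crs,
                    name = "recorded", proj = ref$proj)
  structure(list(raster = out,
                 range = c(eoo = eoo(records), aoo = aoo(records))),
            class = "points_map")
}
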