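# The Red List Index (RLI): an aggregate measure in [0, 1] of a species
# group's extinction-risk status over time, with bootstrap confidence
# limits and a sign-agreement test for change between assessment dates.

.RLI_WEIGHTS <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 5, EX = 5)

#' Category weight of an IUCN Red List code
#'
#' Weights range from 0 (Least Concern) up the category ladder to 5
#' (Extinct / Extinct in the Wild). Data Deficient (DD) species carry no
#' weight: by default they are excluded from the index (see [rli_point()]).
#'
#' @param code Character vector of category codes (LC, NT, VU, EN, CR,
#'   EW, EX).
#' @return Integer weights 0-5.
#' @examples
#' category_weight(c("LC", "EN", "EX"))
#' @export
category_weight <- function(code) {
  code <- toupper(trimws(code))
  bad <- setdiff(unique(code), c(names(.RLI_WEIGHTS), "DD"))
  if (length(bad)) stop("unknown category code(s): ", paste(bad, collapse = ", "))
  if (any(code == "DD")) stop("DD carries no weight; exclude DD species first")
  unname(.RLI_WEIGHTS[code])
}

# weights with NA for DD; dd = "exclude" drops them from N, dd = "category"
# treats DD as a fixed pseudo-weight (dd_weight).
rli_weights <- function(codes, dd = c("exclude", "category"), dd_weight = 2) {
  dd <- match.arg(dd)
  codes <- toupper(trimws(codes))
  bad <- setdiff(unique(codes), c(names(.RLI_WEIGHTS), "DD"))
  if (length(bad)) stop("unknown category code(s): ", paste(bad, collapse = ", "))
  w <- unname(.RLI_WEIGHTS[codes])
  w[codes == "DD"] <- if (dd == "category") dd_weight else NA_real_
  w
}

#' Red List Index for one assessment date
#'
#' The RLI sums the category weights across species and relates the sum
#' to the worst-case scenario of all species extinct:
#' `RLI = 1 - sum(w) / (5 * N)`. 1 means every species is Least Concern,
#' 0 means all are extinct. DD species are excluded from both the sum and
#' `N` by default.
#'
#' @param categories Character vector of category codes for one date.
#' @param dd `"exclude"` (default) or `"category"` (treat DD as a fixed
#'   weight `dd_weight`).
#' @param dd_weight Weight used when `dd = "category"` (default 2).
#' @return The index in \[0, 1\].
#' @examples
#' rli_point(c("LC", "EN", "EX", "LC", "CR"))  # 0.52
#' @export
rli_point <- function(categories, dd = "exclude", dd_weight = 2) {
  w <- rli_weights(categories, dd, dd_weight)
  w <- w[!is.na(w)]
  if (!length(w)) stop("no assessable species")
  1 - sum(w) / (5 * length(w))
}

# coerce a species x dates category table (matrix or data frame, optional
# leading group column) to list(groups, mat)
as_category_table <- function(table) {
  m <- as.matrix(table)
  groups <- NULL
  is_code <- function(v) all(toupper(trimws(v)) %in% c(names(.RLI_WEIGHTS), "DD"))
  if (ncol(m) >= 2L && !is_code(m[, 1L]) && all(apply(m[, -1L, drop = FALSE], 2L, is_code))) {
    groups <- as.character(m[, 1L])
    m <- m[, -1L, drop = FALSE]
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("date", seq_len(ncol(m)))
  list(groups = groups, mat = m)
}

#' Red List Index with bootstrap confidence limits
#'
#' Computes the per-date RLI and bootstraps it: species (whole rows, so
#' dates stay paired) are resampled with replacement to the original
#' number of species; confidence limits are the 2.5 and 97.5 percentiles
#' of the replicate indices. The change between consecutive dates is
#' declared statistically significant when more than 95\% of the
#' replicate changes share the sign of the observed change (an observed
#' change of exactly zero is never significant).
#'
#' @param table Species x dates character matrix (or data frame) of
#'   category codes; column names are the date labels.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param dd,dd_weight DD handling, as in [rli_point()].
#' @return An object of class `rli_result`: data frame `index` with
#'   columns `date`, `rli`, `lower`, `upper`; logical vector
#'   `significant` (one flag per consecutive date pair); `reps`.
#' @examples
#' tab <- matrix(c("LC","LC","EN","EN","EX","EX","LC","CR","CR","EX"),
#'               ncol = 2, byrow = TRUE,
#'               dimnames = list(NULL, c("2000", "2010")))
#' rli_bootstrap(tab, reps = 200, seed = 1)
#' @export
rli_bootstrap <- function(table, reps = 1000, seed = 1, dd = "exclude",
                          dd_weight = 2) {
  if (reps < 2) stop("reps must be at least 2")
  ct <- as_category_table(table)
  m <- ct$mat
  n <- nrow(m)
  wmat <- apply(m, 2L, rli_weights, dd = dd, dd_weight = dd_weight)
  wmat <- matrix(wmat, nrow = n)
  point <- 1 - colSums(wmat, na.rm = TRUE) / (5 * colSums(!is.na(wmat)))
  if (any(colSums(!is.na(wmat)) == 0)) stop("no assessable species")
  set.seed(seed)
  draw <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
  rep_idx <- t(apply(draw, 1L, function(rows) {
    sub <- wmat[rows, , drop = FALSE]
    1 - colSums(sub, na.rm = TRUE) / (5 * pmax(colSums(!is.na(sub)), 1))
  }))
  rep_idx <- matrix(rep_idx, nrow = reps)
  lims <- apply(rep_idx, 2L, stats::quantile, probs = c(0.025, 0.975))
  sig <- logical(max(ncol(m) - 1L, 0L))
  for (j in seq_along(sig)) {
    d_true <- point[j + 1L] - point[j]
    if (d_true == 0) { sig[j] <- FALSE; next }
    d_rep <- rep_idx[, j + 1L] - rep_idx[, j]
    sig[j] <- mean(sign(d_rep) == sign(d_true)) > 0.95
  }
  names(sig) <- if (length(sig))
    paste(colnames(m)[-ncol(m)], colnames(m)[-1L], sep = "-") else character(0)
  structure(list(index = data.frame(date = colnames(m), rli = unname(point),
                                    lower = unname(lims[1L, ]),
                                    upper = unname(lims[2L, ])),
                 significant = sig, reps = reps,
                 replicates = rep_idx),
            class = "rli_result")
}

#' @export
print.rli_result <- function(x, ...) {
  cat(sprintf("Red List Index (%d bootstrap replicates)\n", x$reps))
  print(transform(x$index, rli = round(rli, 4), lower = round(lower, 4),
                  upper = round(upper, 4)), row.names = FALSE)
  if (length(x$significant)) {
    cat("Significant change (>95% same-sign replicates):\n")
    print(x$significant)
  }
  invisible(x)
}

#' Red List Index for multiple groups
#'
#' Applies [rli_bootstrap()] independently within each group (e.g.
#' taxonomic class), preserving the groups' order of first appearance.
#' Groups with no assessable species yield an `NA` row with a warning
#' rather than an error.
#'
#' @param table Matrix or data frame whose first column is the group
#'   label, remaining columns category codes per date.
#' @param reps,seed,dd,dd_weight As in [rli_bootstrap()].
#' @return Named list of `rli_result` (or `NA`) per group, of class
#'   `rli_multi_result`.
#' @export
rli_multi <- function(table, reps = 1000, seed = 1, dd = "exclude",
                      dd_weight = 2) {
  ct <- as_category_table(table)
  if (is.null(ct$groups)) stop("table has no group column")
  out <- list()
  for (g in unique(ct$groups)) {
    sub <- ct$mat[ct$groups == g, , drop = FALSE]
    out[[g]] <- tryCatch(
      rli_bootstrap(sub, reps = reps, seed = seed, dd = dd,
                    dd_weight = dd_weight),
      error = function(e) {
        warning("group '", g, "': ", conditionMessage(e))
        NA
      })
  }
  structure(out, class = "rli_multi_result")
}

#' @export
print.rli_multi_result <- function(x, ...) {
  for (g in names(x)) {
    cat("== ", g, " ==\n", sep = "")
    if (identical(x[[g]], NA)) cat("  not assessable\n") else print(x[[g]])
  }
  invisible(x)
}

#' Sampled Red List Index accumulation curve
#'
#' When assessing every species of a group is infeasible, the RLI is
#' estimated from a random species sample (the Sampled Red List Index).
#' This computes, for each subsample size n, the 95th percentile (across
#' random subsets) of the worst-date absolute deviation of the SRLI from
#' the full-group RLI, and reports the smallest n whose error statistic
#' is within `max_error`.
#'
#' @param table Species x dates category matrix, as in [rli_bootstrap()].
#' @param max_error Tolerated SRLI error (index units, > 0).
#' @param reps Random subsets per subsample size (default 1000).
#' @param seed Integer seed.
#' @param quantile_prob Probability for the error quantile (default 0.95).
#' @param dd,dd_weight DD handling, as in [rli_point()].
#' @return An object of class `srli_curve`: data frame `curve` with
#'   columns `n` and `error` (the error quantile), and `n_min`, the
#'   smallest adequate subsample size (N when none smaller qualifies).
#' @export
rli_sampled <- function(table, max_error, reps = 1000, seed = 1,
                        quantile_prob = 0.95, dd = "exclude", dd_weight = 2) {
  if (max_error <= 0) stop("max_error must be > 0")
  ct <- as_category_table(table)
  m <- ct$mat
  n_sp <- nrow(m)
  if (n_sp < 3L) stop("need at least 3 species")
  if (max_error >= 1) warning("max_error >= 1 is trivially satisfied")
  wmat <- apply(m, 2L, rli_weights, dd = dd, dd_weight = dd_weight)
  wmat <- matrix(wmat, nrow = n_sp)
  full <- 1 - colSums(wmat, na.rm = TRUE) / (5 * colSums(!is.na(wmat)))
  set.seed(seed)
  sizes <- 2:n_sp
  err <- vapply(sizes, function(k) {
    if (k == n_sp) return(0)
    dev <- vapply(seq_len(reps), function(i) {
      rows <- sample.int(n_sp, k)
      sub <- wmat[rows, , drop = FALSE]
      srli <- 1 - colSums(sub, na.rm = TRUE) / (5 * pmax(colSums(!is.na(sub)), 1))
      max(abs(srli - full))
    }, numeric(1))
    unname(stats::quantile(dev, quantile_prob))
  }, numeric(1))
  ok <- sizes[err <= max_error]
  structure(list(curve = data.frame(n = sizes, error = err),
                 n_min = if (length(ok)) min(ok) else n_sp,
                 full_rli = full, quantile_prob = quantile_prob),
            class = "srli_curve")
}

#' @export
print.srli_curve <- function(x, ...) {
  cat(sprintf("Sampled RLI: minimal adequate subsample n = %d (of %d species)\n",
              x$n_min, max(x$curve$n)))
  invisible(x)
}

#' Read a category table from CSV
#'
#' Columns: optional leading group column, then one column of category
#' codes per assessment date (header = date labels).
#'
#' @param path Path to a CSV file.
#' @return A character matrix (with a leading group column when present).
#' @export
read_category_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  as.matrix(df)
}

#' Plot a sampled-RLI accumulation curve
#'
#' Error quantile against subsample size, with the minimal adequate
#' subsample size marked.
#'
#' @param x An `srli_curve` from [rli_sampled()].
#' @param path Optional .png path; when given the plot is written there.
#' @param ... Unused.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot.srli_curve <- function(x, path = NULL, ...) {
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x$curve$n, x$curve$error, type = "b", pch = 19,
                 xlab = "species sampled", ylab = sprintf(
                   "SRLI error (%gth percentile, worst date)",
                   100 * x$quantile_prob),
                 main = "Sampled RLI accumulation")
  graphics::abline(v = x$n_min, lty = 2)
  invisible(path)
}
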