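# One-step mapping of multiple species: runs the chosen mapping pipeline
# per species, writes map files in asc, png and kml formats, and collects
# EOO, AOO and countries into a summary table.

#' Map multiple species in a single step
#'
#' For each species in a multi-species occurrence table, runs the chosen
#' mapping pipeline ([map_points()], [map_habitat()] or an SDM ensemble
#' via [run_ensemble()] + [consensus_map()]), writes the range map as
#' `<species>.asc`, `<species>.png` and `<species>.kml` in `output_dir`,
#' and appends a summary row with EOO, AOO and the countries occupied.
#' Species failing their pipeline's preconditions (e.g. a single record
#' under SDM) are logged and reported as `NA` rows, not fatal errors.
#'
#' @param records A multi-species [occurrences] object (with a `species`
#'   column), or a data frame with columns species, x, y.
#' @param layers A `red_stack` of predictors (quantitative layers are
#'   used for SDM).
#' @param mode `"points"`, `"habitat"` or `"sdm"`.
#' @param output_dir Output directory (created if missing; must be
#'   writable).
#' @param habitat Binary habitat raster (required for `mode = "habitat"`).
#' @param boundaries Optional [read_boundaries()] polygons for the
#'   countries column.
#' @param runs,seed SDM ensemble size and master seed (mode `"sdm"`).
#' @param ... Further arguments to the per-species mapper.
#' @return Data frame (also written to `summary.csv`): species, eoo,
#'   aoo, countries, status ("ok" or the failure reason).
#' @export
map_easy <- function(records, layers, mode = c("points", "habitat", "sdm"),
                     output_dir, habitat = NULL, boundaries = NULL,
                     runs = 10, seed = 1, ...) {
  mode <- match.arg(mode)
  if (!inherits(records, "occurrences")) {
    records <- occurrences(records[[2L]], records[[3L]],
                           species = records[[1L]])
  }
  if (is.null(records$species)) stop("records need a species column")
  if (mode == "habitat" && is.null(habitat))
    stop("mode 'habitat' needs a habitat raster")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(output_dir, ".write_probe")
  ok_dir <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                     warning = function(w) FALSE)
  if (!isTRUE(ok_dir)) stop("output directory not writable: ", output_dir)
  unlink(probe)
  species <- unique(records$species)
  rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    sub <- records[records$species == sp, c("x", "y")]
    rec <- occurrences(sub$x, sub$y, crs = attr(records, "crs"))
    res <- tryCatch({
      map <- switch(mode,
        points = {
          m <- map_points(rec, layers)
          list(raster = m$raster, eoo = m$range[["eoo"]],
               aoo = m$range[["aoo"]])
        },
        habitat = {
          m <- map_habitat(rec, habitat, ...)
          list(raster = m$raster, eoo = m$modelled[["eoo"]],
               aoo = m$modelled[["aoo"]])
        },
        sdm = {
          ens <- consensus_map(run_ensemble(rec, layers, runs = runs,
                                            seed = seed + i, ...))
          list(raster = ens$consensus, eoo = ens$ranges["consensus", "eoo"],
               aoo = ens$ranges["consensus", "aoo"])
        })
      safe <- gsub("[^A-Za-z0-9_.-]", "_", sp)
      write_asc(map$raster, file.path(output_dir, paste0(safe, ".asc")))
      draw_map(rec, map$raster, file.path(output_dir, paste0(safe, ".png")))
      suppressWarnings(
        write_kml(map$raster, file.path(output_dir, paste0(safe, ".kml")),
                  name = sp))
      ctry <- if (!is.null(boundaries))
        paste(countries_of(map$raster, boundaries), collapse = ";") else ""
      data.frame(species = sp, eoo = map$eoo, aoo = map$aoo,
                 countries = ctry, status = "ok")
    }, error = function(e) {
      message("skipping '", sp, "': ", conditionMessage(e))
      data.frame(species = sp, eoo = NA_real_, aoo = NA_real_,
                 countries = NA_character_,
                 status = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  summary
}
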