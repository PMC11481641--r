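#' Read a monitoring CSV into a validated dataset
#'
#' Expects the wide monitoring schema: columns `well_id`, `year`, `x`, `y`
#' and one numeric column per parameter (`pH`, `EC`, `NH4`, `NO2`, `NO3`,
#' `PO4`, `COD`, `Na` by default). Empty cells become missing values; the
#' sampling period is derived from the sewerage-completion boundary year
#' (pre-sewerage when `year < boundary_year`). Violations of the sample
#' invariants (pH outside (0, 14), negative concentrations, duplicate
#' well-year records) are reported with row numbers, collected together.
#'
#' @param path CSV file (comma delimiter, dot decimal, header row).
#' @param boundary_year First post-sewerage year (default 2014).
#' @param parameters Parameter columns required to be present.
#' @param crs Coordinate-system identifier recorded on the dataset.
#' @return A `wq_dataset` tibble (see [simulate_dataset()]) with
#'   `provenance = "measured"`.
#' @export
read_samples_csv <- function(path, boundary_year = 2014,
                             parameters = c("pH", "EC", "NH4", "NO2", "NO3",
                                            "PO4", "COD", "Na"),
                             crs = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("well_id", "year", "x", "y", parameters)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("monitoring CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  for (col in c("year", "x", "y", parameters)) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed) & v != "")
      if (length(bad) > 0) {
        problems <- c(problems, paste0("column ", col, ": unparseable number",
                                       " in row(s) ",
                                       paste(bad, collapse = ", ")))
      }
      d[[col]] <- parsed
    }
  }
  dup <- duplicated(d[c("well_id", "year")])
  if (any(dup)) {
    problems <- c(problems, paste0("duplicate (well_id, year) in row(s) ",
                                   paste(which(dup), collapse = ", ")))
  }
  bad_ph <- which(!is.na(d$pH) & (d$pH <= 0 | d$pH >= 14))
  if (length(bad_ph) > 0) {
    problems <- c(problems, paste0("pH outside (0, 14) in row(s) ",
                                   paste(bad_ph, collapse = ", ")))
  }
  for (p in setdiff(parameters, "pH")) {
    bad <- which(!is.na(d[[p]]) & d[[p]] < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("negative ", p, " in row(s) ",
                                     paste(bad, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop("invalid monitoring data:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  d <- d |>
    dplyr::mutate(year = as.integer(.data$year),
                  period = ifelse(.data$year < boundary_year,
                                  "pre_sewerage", "post_sewerage"),
                  .after = "year") |>
    dplyr::arrange(.data$year, .data$well_id)
  attr(d, "crs") <- crs
  attr(d, "boundary_year") <- boundary_year
  attr(d, "provenance") <- "measured"
  class(d) <- c("wq_dataset", class(tibble::tibble()))
  d
}

#' Write index results to CSV
#'
#' Columns: `well_id`, `year`, `wqi`, `rank_wqs`, `wqs_label`, `cd`,
#' `rank_cds`, `cds_label`, the per-parameter `q_*` ratings and `cf_*`
#' contamination factors, plus coordinates when present. A read-back of the
#' file reproduces the written fields.
#'
#' @param results A `wq_indices` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(results, path) {
  if (nrow(results) == 0) stop("no index results to write", call. = FALSE)
  lead <- intersect(c("well_id", "year", "x", "y", "period",
                      "wqi", "rank_wqs", "wqs_label",
                      "cd", "rank_cds", "cds_label", "partial"),
                    names(results))
  extras <- grep("^(q|cf)_", names(results), value = TRUE)
  readr::write_csv(results[c(lead, extras)], path, progress = FALSE)
  invisible(path)
}

#' Write well points with index attributes as GeoJSON
#'
#' One `Feature` per sample with a `Point` geometry at `[x, y]` and the
#' index attributes as properties; the coordinate-system identifier is
#' recorded under the top-level `crs_note` member.
#'
#' @param results A `wq_indices` tibble with `x`, `y` columns.
#' @param path Output `.geojson` path.
#' @param crs Coordinate-system note (free text).
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(results, path,
                                 crs = attr(results, "crs") %||% NA_character_) {
  if (nrow(results) == 0) stop("no features to write", call. = FALSE)
  if (!all(c("x", "y") %in% names(results))) {
    stop("results need x and y columns", call. = FALSE)
  }
  props <- intersect(c("well_id", "year", "period", "wqi", "rank_wqs",
                       "wqs_label", "cd", "rank_cds", "cds_label"),
                     names(results))
  features <- purrr::map(seq_len(nrow(results)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(results$x[i], results$y[i])),
      properties = as.list(results[i, props])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.na(crs)) fc$crs_note <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a synthetic-generator configuration from YAML
#'
#' The YAML mirrors the arguments of [synthetic_config()]; a `calibration`
#' block (rows of `year`, `parameter`, `mean`, `q25`, `q75`) overrides the
#' packaged published-summary targets.
#'
#' @param path YAML file.
#' @return A `wq_config`.
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  calibration <- if (!is.null(cfg$calibration)) {
    purrr::map_dfr(cfg$calibration, tibble::as_tibble)
  } else {
    study_parameter_summary()
  }
  effect <- if (!is.null(cfg$effect)) unlist(cfg$effect) else NULL
  synthetic_config(
    n_wells = cfg$n_wells %||% 40,
    extent = unlist(cfg$extent %||% c(0, 2000, 0, 2000)),
    years = unlist(cfg$years %||% c(2013, 2017, 2018, 2019, 2021, 2022)),
    n_per_year = unlist(cfg$n_per_year %||% c(40, 40, 40, 40, 37, 34)),
    boundary_year = cfg$boundary_year %||% 2014,
    calibration = calibration,
    range_m = cfg$range_m %||% 500,
    sill_fraction = cfg$sill_fraction %||% 0.5,
    effect = effect,
    crs = cfg$crs %||% "EPSG:23700"
  )
}
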