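#' Run the full assessment pipeline
#'
#' Executes the whole workflow in one call: obtain data (read a monitoring
#' CSV or simulate from a `wq_config`), compute indices and five-rank
#' classifications, per-year descriptive summaries of parameters and
#' indices, per-year rank counts, the rank-agreement table, Spearman
#' correlation between the indices, the paired pre/post Wilcoxon tests,
#' the two-group discriminant analysis, and per-year kriged plus
#' rank-classified rasters. Every artifact is written under `out_dir`
#' together with a machine-readable run manifest (seed, configuration
#' hash, package version, file list). The run is fully deterministic given
#' the seed.
#'
#' @param input Path to a monitoring CSV, or a `wq_config` from
#'   [synthetic_config()] / [read_synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling simulation.
#' @param standards A `wq_standards` table.
#' @param stats Run the statistical stage (default `TRUE`).
#' @param interpolate Run the interpolation stage (default `TRUE`).
#' @param index_for_maps Which index surface(s) to interpolate:
#'   `c("wqi", "cd")`.
#' @param cellsize Raster cell size in metres.
#' @return Invisibly, a list with the in-memory results: `data`, `indices`,
#'   `parameter_summary`, `index_summary`, `rank_counts_wqs`,
#'   `rank_counts_cds`, `rank_agreement`, `correlation`, `wilcoxon`
#'   (per index), `discriminant`, `rasters`, `manifest`.
#' @export
run_pipeline <- function(input, out_dir, seed = 1,
                         standards = water_standards(),
                         stats = TRUE, interpolate = TRUE,
                         index_for_maps = c("wqi", "cd"), cellsize = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data <- stage("data", {
    if (inherits(input, "wq_config")) simulate_dataset(input, seed = seed)
    else read_samples_csv(input)
  })
  readr::write_csv(data, file.path(out_dir, "samples.csv"), progress = FALSE)

  indices <- stage("indices", wq_indices(data, standards))
  write_index_csv(indices, file.path(out_dir, "indices.csv"))
  write_geojson_points(indices, file.path(out_dir, "wells.geojson"),
                       crs = attr(data, "crs") %||% NA_character_)

  params <- standards$parameter
  parameter_summary <- stage("summaries",
                             descriptive_summary(data, params))
  index_summary <- descriptive_summary(indices, c("wqi", "cd"))
  readr::write_csv(parameter_summary,
                   file.path(out_dir, "parameter_summary.csv"),
                   progress = FALSE)
  readr::write_csv(index_summary, file.path(out_dir, "index_summary.csv"),
                   progress = FALSE)

  results <- list(data = data, indices = indices,
                  parameter_summary = parameter_summary,
                  index_summary = index_summary)

  if (stats) {
    results$rank_counts_wqs <- count_by_rank(indices, "wqs")
    results$rank_counts_cds <- count_by_rank(indices, "cds")
    results$rank_agreement <- rank_agreement(indices)
    results$correlation <- stage("correlation",
                                 spearman_rank(indices$wqi, indices$cd))
    results$wilcoxon <- stage("wilcoxon", list(
      wqi = prepost_wilcoxon(indices, "wqi"),
      cd = prepost_wilcoxon(indices, "cd")
    ))
    results$discriminant <- stage("discriminant",
                                  lda_two_group(indices, params, "period"))
    readr::write_csv(results$rank_counts_wqs,
                     file.path(out_dir, "rank_counts_wqs.csv"),
                     progress = FALSE)
    readr::write_csv(results$rank_counts_cds,
                     file.path(out_dir, "rank_counts_cds.csv"),
                     progress = FALSE)
    readr::write_csv(results$rank_agreement,
                     file.path(out_dir, "rank_agreement.csv"),
                     progress = FALSE)
    readr::write_csv(dplyr::bind_rows(
      tidy(results$wilcoxon$wqi) |> dplyr::mutate(index = "wqi", .before = 1),
      tidy(results$wilcoxon$cd) |> dplyr::mutate(index = "cd", .before = 1)
    ), file.path(out_dir, "wilcoxon.csv"), progress = FALSE)
    readr::write_csv(glance(results$discriminant),
                     file.path(out_dir, "discriminant.csv"), progress = FALSE)
  }

  if (interpolate) {
    results$rasters <- stage("interpolation", {
      purrr::map(stats::setNames(index_for_maps, index_for_maps), function(ix) {
        purrr::map(split(indices, indices$year), function(dy) {
          grid <- grid_from_points(dy, cellsize = cellsize,
                                   crs = attr(data, "crs") %||% NA_character_)
          kr <- ordinary_kriging(dy, ix, grid)
          cls <- classify_raster(kr$prediction,
                                 if (ix == "wqi") "wqi" else "cd")
          yr <- dy$year[1]
          write_esri_ascii(kr$prediction,
                           file.path(out_dir,
                                     sprintf("%s_%d.asc", ix, yr)))
          write_esri_ascii(cls,
                           file.path(out_dir,
                                     sprintf("%s_%d_rank.asc", ix, yr)))
          list(prediction = kr$prediction, classified = cls,
               model = kr$model)
        })
      })
    })
  }

  manifest <- list(
    package = "gwindex",
    version = as.character(utils::packageVersion("gwindex")),
    seed = seed,
    input = if (inherits(input, "wq_config")) "synthetic" else input,
    config_hash = rlang::hash(if (inherits(input, "wq_config")) {
      input[setdiff(names(input), "distributions")]
    } else input),
    stages = list(stats = stats, interpolate = interpolate),
    n_samples = nrow(data),
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
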