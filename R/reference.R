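#' Published per-year descriptive statistics of the monitored parameters
#'
#' The study's monitoring campaign reported, for each sampling year
#' (2013 pre-sewerage; 2017, 2018, 2019, 2021, 2022 post-sewerage) and each
#' of the eight parameters, the sample size, mean, minimum, maximum and the
#' lower/upper quartiles. The raw well measurements themselves are not
#' public, so these printed summaries are the calibration targets of the
#' synthetic monitoring-network generator and the inputs of the
#' mean-vector WQI check.
#'
#' @return A tibble with columns `year`, `parameter`, `n`, `mean`, `min`,
#'   `max`, `q25`, `q75`. Units: uS/cm for EC, dimensionless pH, mg/L
#'   otherwise.
#' @examples
#' study_parameter_summary() |> dplyr::filter(parameter == "EC")
#' @export
study_parameter_summary <- function() {
  rows <- list(
    # year, n, then per parameter c(mean, min, max, q25, q75)
    list(2013, 40,
         pH  = c(8.25, 7.23, 9.42, 7.92, 8.56),
         EC  = c(3032.65, 340, 7670, 1950.25, 4310),
         NH4 = c(0.69, 0.23, 1.89, 0.43, 0.87),
         NO2 = c(0.31, 0.02, 1.28, 0.05, 0.42),
         NO3 = c(187.83, 2.36, 564.82, 50.16, 341.77),
         PO4 = c(1.22, 0.07, 4.07, 0.37, 1.75),
         COD = c(6.85, 2.40, 18.20, 4.03, 8.05),
         Na  = c(237.91, 8.90, 653.20, 132.18, 312.78)),
    list(2017, 40,
         pH  = c(7.51, 7.02, 8.30, 7.29, 7.74),
         EC  = c(2845.78, 876, 9290, 1871.25, 3507.5),
         NH4 = c(0.53, 0.08, 3.42, 0.24, 0.64),
         NO2 = c(0.20, 0.01, 1.86, 0.02, 0.17),
         NO3 = c(142.65, 4.46, 616.64, 37.65, 221.08),
         PO4 = c(0.39, 0.03, 1.54, 0.09, 0.58),
         COD = c(7.65, 2.90, 17.68, 5.24, 9.90),
         Na  = c(377.94, 75.80, 2254.20, 154.15, 422.48)),
    list(2018, 40,
         pH  = c(8.00, 7.21, 8.87, 7.68, 8.29),
         EC  = c(2637.8, 1140, 6380, 1874.25, 3190),
         NH4 = c(0.65, 0.14, 3.97, 0.33, 0.68),
         NO2 = c(0.21, 0.00, 1.37, 0.01, 0.30),
         NO3 = c(109.76, 6.95, 538.30, 23.73, 153.03),
         PO4 = c(0.65, 0.03, 2.76, 0.22, 0.86),
         COD = c(7.16, 1.10, 36.80, 3.59, 8.48),
         Na  = c(352.37, 97.39, 1828.03, 182.32, 447.77)),
    list(2019, 40,
         pH  = c(7.21, 6.81, 7.90, 6.97, 7.42),
         EC  = c(2773.43, 695, 8910, 1511.25, 3792.50),
         NH4 = c(0.52, 0.12, 3.37, 0.29, 0.62),
         NO2 = c(0.26, 0.00, 1.94, 0.02, 0.31),
         NO3 = c(170.73, 7.61, 645.5, 43.1, 244.85),
         PO4 = c(0.48, 0.04, 2.14, 0.14, 0.60),
         COD = c(7.68, 1.66, 16.65, 4.58, 10.12),
         Na  = c(383.68, 52.14, 2019.77, 185.37, 477.99)),
    list(2021, 37,
         pH  = c(7.23, 6.84, 8.00, 7.06, 7.36),
         EC  = c(4128.92, 980, 14830, 1808, 5930),
         NH4 = c(0.47, 0.12, 1.40, 0.25, 0.51),
         NO2 = c(0.24, 0.01, 1.54, 0.03, 0.31),
         NO3 = c(164.52, 16.59, 829.18, 33.19, 185),
         PO4 = c(0.37, 0.04, 1.53, 0.09, 0.48),
         COD = c(4.21, 0.97, 23.18, 2.1, 4.14),
         Na  = c(319.88, 80.53, 1396.35, 157.42, 362.57)),
    list(2022, 34,
         pH  = c(7.27, 6.95, 7.80, 7.08, 7.50),
         EC  = c(3664.21, 1396, 11700, 2163.75, 4623.75),
         NH4 = c(0.64, 0.14, 2.47, 0.38, 0.77),
         NO2 = c(0.20, 0.00, 1.24, 0.04, 0.25),
         NO3 = c(296.1, 9.64, 1186.05, 76.1, 377.27),
         PO4 = c(0.24, 0.03, 0.89, 0.1, 0.32),
         COD = c(2.19, 0.99, 5.11, 1.71, 2.58),
         Na  = c(153.51, 21.71, 295.77, 94.90, 205.26))
  )
  purrr::map_dfr(rows, function(r) {
    params <- r[-(1:2)]
    tibble::tibble(
      year = as.integer(r[[1]]),
      parameter = names(params),
      n = as.integer(r[[2]]),
      mean = unname(purrr::map_dbl(params, 1)),
      min  = unname(purrr::map_dbl(params, 2)),
      max  = unname(purrr::map_dbl(params, 3)),
      q25  = unname(purrr::map_dbl(params, 4)),
      q75  = unname(purrr::map_dbl(params, 5))
    )
  })
}

#' Per-year mean parameter vectors in the wide monitoring schema
#'
#' Convenience pivot of [study_parameter_summary()]: one row per year with
#' the published mean of each parameter as a column, ready to feed to
#' [wq_indices()] (the WQI is linear in every parameter except pH, so the
#' index of the mean vector tracks the mean index closely).
#'
#' @return A tibble with columns `year`, `pH`, `EC`, `NH4`, `NO2`, `NO3`,
#'   `PO4`, `COD`, `Na`.
#' @export
study_mean_vectors <- function() {
  study_parameter_summary() |>
    dplyr::select("year", "parameter", "mean") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "mean")
}
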