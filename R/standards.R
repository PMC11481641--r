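#' Parameter standards registry
#'
#' Load a per-parameter standards profile: for each physicochemical parameter
#' the ideal value \eqn{V_i}, the permissible limit \eqn{V_s} (for pH the
#' upper bound of the permissible range), an optional lower permissible bound
#' (pH only) and the contamination threshold \eqn{C_{Ni}} used by the
#' contamination degree (defaults to \eqn{V_s}).
#'
#' The shipped profile `"hu_6_2009"` carries the Hungarian joint decree
#' 6/2009 (IV. 14.) KvVM-EuM-FVM limits for shallow groundwater:
#' pH 6.5--8.5, EC 2500 uS/cm, NH4 0.5, NO2 0.5, NO3 50, PO4 0.5, COD 4.5
#' and Na 200 mg/L.
#'
#' @param profile Name of a shipped profile (currently `"hu_6_2009"`) or a
#'   path to a YAML registry file with the same structure.
#' @return A tibble of class `wq_standards` with columns `parameter`, `unit`,
#'   `ideal`, `limit`, `lower_limit` (NA when absent) and `cd_limit`.
#' @examples
#' water_standards()
#' @export
water_standards <- function(profile = "hu_6_2009") {
  path <- if (file.exists(profile)) {
    profile
  } else {
    system.file("extdata", paste0("standards_", profile, ".yaml"),
                package = "gwindex")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown standards profile: ", profile, call. = FALSE)
  }
  read_standards(path)
}

#' Read a standards registry file
#'
#' @param path YAML file listing `parameters:` entries with fields `code`,
#'   `unit`, `ideal`, `limit`, optional `lower_limit` and `cd_limit`.
#' @return A `wq_standards` tibble (see [water_standards()]).
#' @export
read_standards <- function(path) {
  reg <- yaml::read_yaml(path)
  if (is.null(reg$parameters) || length(reg$parameters) == 0) {
    stop("standards registry has no parameters: ", path, call. = FALSE)
  }
  specs <- purrr::map_dfr(reg$parameters, function(p) {
    tibble::tibble(
      parameter   = as.character(p$code),
      unit        = as.character(p$unit %||% ""),
      ideal       = as.numeric(p$ideal %||% 0),
      limit       = as.numeric(p$limit),
      lower_limit = as.numeric(p$lower_limit %||% NA_real_),
      cd_limit    = as.numeric(p$cd_limit %||% p$limit)
    )
  })
  attr(specs, "profile") <- reg$profile %||% basename(path)
  validate_standards(specs)
}

#' Validate a standards table
#'
#' Enforces the structural invariants of a parameter-standards table:
#' positive limits above the ideal value, positive contamination thresholds,
#' any lower bound strictly below the upper limit, unique parameter codes.
#'
#' @param specs A data frame with the [water_standards()] columns.
#' @return The validated `wq_standards` tibble (invisibly classed).
#' @export
validate_standards <- function(specs) {
  specs <- tibble::as_tibble(specs)
  required <- c("parameter", "ideal", "limit")
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols) > 0) {
    stop("standards table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(specs) == 0) stop("standards table is empty", call. = FALSE)
  if (!"unit" %in% names(specs)) specs$unit <- ""
  if (!"lower_limit" %in% names(specs)) specs$lower_limit <- NA_real_
  if (!"cd_limit" %in% names(specs)) specs$cd_limit <- specs$limit
  specs$cd_limit[is.na(specs$cd_limit)] <- specs$limit[is.na(specs$cd_limit)]
  if (anyDuplicated(specs$parameter)) {
    stop("duplicate parameter codes in standards table", call. = FALSE)
  }
  if (any(!is.finite(specs$limit)) || any(specs$limit <= 0)) {
    stop("all permissible limits must be finite and > 0", call. = FALSE)
  }
  if (any(specs$limit <= specs$ideal)) {
    stop("permissible limit must exceed the ideal value", call. = FALSE)
  }
  if (any(specs$cd_limit <= 0)) {
    stop("all contamination thresholds must be > 0", call. = FALSE)
  }
  bad_lower <- !is.na(specs$lower_limit) & specs$lower_limit >= specs$limit
  if (any(bad_lower)) {
    stop("lower permissible bound must be below the upper limit", call. = FALSE)
  }
  class(specs) <- c("wq_standards", class(tibble::tibble()))
  specs
}

#' Unit weights of the weighted-arithmetic water quality index
#'
#' Computes the proportionality constant \eqn{k = 1 / \sum 1/V_s} and the
#' per-parameter unit weights \eqn{W_n = k / V_s}. By construction the
#' weights sum to exactly one, so the WQI is a weighted mean of the quality
#' ratings.
#'
#' @param standards A `wq_standards` table (see [water_standards()]).
#' @return A tibble with columns `parameter`, `limit`, `weight`, carrying the
#'   constant `k` as an attribute.
#' @examples
#' w <- unit_weights(water_standards())
#' sum(w$weight) # 1
#' @export
unit_weights <- function(standards) {
  standards <- validate_standards(standards)
  k <- 1 / sum(1 / standards$limit)
  out <- tibble::tibble(
    parameter = standards$parameter,
    limit     = standards$limit,
    weight    = k / standards$limit
  )
  attr(out, "k") <- k
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
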