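#' Quality rating of a single parameter
#'
#' The quality rating scales the deviation of a measured value from its ideal
#' value by the span between ideal value and permissible limit:
#' \deqn{Q_n = 100\,|V_n - V_i| / (V_s - V_i).}
#' The absolute deviation makes the rating symmetric around the ideal value,
#' which only matters for pH (the one parameter with \eqn{V_i \neq 0}); for
#' every concentration it reduces to \eqn{100\,V_n/V_s}. A value at the
#' permissible limit rates exactly 100.
#'
#' @param value Measured value(s) \eqn{V_n} (vectorised).
#' @param ideal Ideal value \eqn{V_i} (default 0).
#' @param limit Permissible limit \eqn{V_s}; must exceed `ideal`.
#' @return Numeric vector of non-negative ratings.
#' @examples
#' quality_rating(7.75, ideal = 7, limit = 8.5) # 50
#' quality_rating(100, limit = 50)              # 200
#' @export
quality_rating <- function(value, ideal = 0, limit) {
  if (any(limit <= ideal)) stop("limit must exceed ideal value", call. = FALSE)
  100 * abs(value - ideal) / (limit - ideal)
}

#' Contamination factor of a single parameter
#'
#' A parameter contributes a contamination factor only when it exceeds its
#' permissible bounds: \eqn{C_{fi} = C_{Ai}/C_{Ni} - 1} above the upper
#' threshold, and (for two-sided parameters such as pH)
#' \eqn{C_{fi} = L/C_{Ai} - 1} below the lower bound \eqn{L}. Values at or
#' within the bounds contribute nothing (`NA` is returned).
#'
#' @param value Analytical value(s) \eqn{C_{Ai}} (vectorised).
#' @param cd_limit Upper permissible concentration \eqn{C_{Ni}}.
#' @param lower_limit Optional lower permissible bound (pH); `NA` disables
#'   the lower branch.
#' @return Numeric vector: positive factors where the value exceeds a bound,
#'   `NA` where it does not (or where `value` is `NA`).
#' @examples
#' contamination_factor(100, cd_limit = 50)   # 1
#' contamination_factor(0.5, cd_limit = 0.5)  # NA: equal does not exceed
#' @export
contamination_factor <- function(value, cd_limit, lower_limit = NA_real_) {
  if (any(cd_limit <= 0)) stop("cd_limit must be > 0", call. = FALSE)
  out <- rep(NA_real_, length(value))
  above <- !is.na(value) & value > cd_limit
  out[above] <- value[above] / cd_limit - 1
  below <- !is.na(value) & !is.na(lower_limit) & value < lower_limit
  if (any(below)) {
    if (any(value[below] <= 0)) {
      stop("values must be > 0 to evaluate a lower-bound exceedance",
           call. = FALSE)
    }
    out[below] <- lower_limit / value[below] - 1
  }
  out
}

#' Rank scales for the two indices
#'
#' Five-rank classification scales. For the WQI the bins are closed on the
#' right (`[0,25]` Excellent, `(25,50]` Good, `(50,75]` Poor, `(75,100]`
#' Very poor, above 100 Unsuitable for any use). For the contamination
#' degree: exactly 0 Excellent, `(0,1)` Low, `[1,3)` Medium, `[3,6]` High,
#' above 6 Very high. Both partitions cover `[0, Inf)` with no gaps.
#'
#' @return A tibble with columns `rank`, `lower`, `upper`, `label`.
#' @export
wqi_rank_scale <- function() {
  tibble::tibble(
    rank  = 1:5,
    lower = c(0, 25, 50, 75, 100),
    upper = c(25, 50, 75, 100, Inf),
    label = c("Excellent", "Good", "Poor", "Very poor",
              "Unsuitable for any use")
  )
}

#' @rdname wqi_rank_scale
#' @export
cd_rank_scale <- function() {
  tibble::tibble(
    rank  = 1:5,
    lower = c(0, 0, 1, 3, 6),
    upper = c(0, 1, 3, 6, Inf),
    label = c("Excellent", "Low", "Medium", "High", "Very high")
  )
}

#' Classify index values into the five ranks
#'
#' @param wqi,cd Non-negative index value(s).
#' @return Integer rank(s) 1--5. Labels come from [wqi_rank_scale()] /
#'   [cd_rank_scale()] via [rank_label()].
#' @examples
#' classify_wqi(c(25, 25.01, 100.01)) # 1 2 5
#' classify_cd(c(0, 0.5, 5.5))        # 1 2 4
#' @export
classify_wqi <- function(wqi) {
  if (any(wqi < 0, na.rm = TRUE)) stop("WQI must be >= 0", call. = FALSE)
  r <- findInterval(wqi, c(0, 25, 50, 75, 100), left.open = TRUE)
  r[!is.na(wqi) & wqi == 0] <- 1L  # left edge of the first closed bin
  r[is.na(wqi)] <- NA_integer_
  as.integer(r)
}

#' @rdname classify_wqi
#' @export
classify_cd <- function(cd) {
  if (any(cd < 0, na.rm = TRUE)) stop("Cd must be >= 0", call. = FALSE)
  r <- ifelse(cd == 0, 1L,
       ifelse(cd < 1, 2L,
       ifelse(cd < 3, 3L,
       ifelse(cd <= 6, 4L, 5L))))
  as.integer(r)
}

#' @param rank Integer rank(s) 1--5.
#' @param index `"wqi"` for water-quality status labels, `"cd"` for
#'   contamination-degree status labels.
#' @rdname classify_wqi
#' @export
rank_label <- function(rank, index = c("wqi", "cd")) {
  index <- match.arg(index)
  scale <- if (index == "wqi") wqi_rank_scale() else cd_rank_scale()
  scale$label[rank]
}

#' Compute WQI and contamination degree for monitoring samples
#'
#' For each sample (row) the weighted-arithmetic water quality index
#' \deqn{WQI = \sum Q_n W_n / \sum W_n} and the contamination degree
#' \deqn{C_d = \sum_i C_{fi}} are computed over the configured parameter
#' set, together with their five-rank classifications.
#'
#' The WQI is defined over the full parameter set: a missing value is an
#' error unless `na_action = "renormalize"`, in which case the unit weights
#' are recomputed over the parameters present in that row and the row is
#' flagged `partial`. The contamination degree simply skips missing values
#' (a value that was not measured cannot exceed its threshold).
#'
#' @param data A data frame with one row per well sample and one numeric
#'   column per parameter code in `standards` (the wide monitoring schema:
#'   `well_id`, `year`, `x`, `y`, `pH`, `EC`, `NH4`, `NO2`, `NO3`, `PO4`,
#'   `COD`, `Na`). Non-parameter columns are passed through.
#' @param standards A `wq_standards` table; defaults to [water_standards()].
#' @param na_action `"error"` (default) or `"renormalize"`.
#' @return A tibble of class `wq_indices`: the pass-through identifier
#'   columns plus `wqi`, `rank_wqs`, `wqs_label`, `cd`, `rank_cds`,
#'   `cds_label`, `partial`, and per-parameter breakdowns `q_<code>`
#'   (quality ratings) and `cf_<code>` (contamination factors, `NA` when
#'   within bounds).
#' @examples
#' d <- tibble::tibble(well_id = "w1", year = 2013, pH = 8.5, EC = 2500,
#'                     NH4 = 0.5, NO2 = 0.5, NO3 = 50, PO4 = 0.5,
#'                     COD = 4.5, Na = 200)
#' wq_indices(d)$wqi # 100: every parameter at its permissible limit
#' @export
wq_indices <- function(data, standards = water_standards(),
                       na_action = c("error", "renormalize")) {
  na_action <- match.arg(na_action)
  standards <- validate_standards(standards)
  data <- tibble::as_tibble(data)
  missing_params <- setdiff(standards$parameter, names(data))
  if (length(missing_params) > 0) {
    stop("data lacks parameter column(s): ",
         paste(missing_params, collapse = ", "), call. = FALSE)
  }
  validate_samples(data, standards)

  vals <- as.matrix(data[standards$parameter])        # n x p
  qmat <- vapply(seq_len(nrow(standards)), function(j) {
    quality_rating(vals[, j], standards$ideal[j], standards$limit[j])
  }, numeric(nrow(vals)))
  qmat <- matrix(qmat, nrow = nrow(vals))
  cfmat <- vapply(seq_len(nrow(standards)), function(j) {
    contamination_factor(vals[, j], standards$cd_limit[j],
                         standards$lower_limit[j])
  }, numeric(nrow(vals)))
  cfmat <- matrix(cfmat, nrow = nrow(vals))

  w <- unit_weights(standards)$weight
  has_na <- rowSums(is.na(vals)) > 0
  if (any(has_na) && na_action == "error") {
    stop("missing parameter value(s) in row(s) ",
         paste(utils::head(which(has_na), 5), collapse = ", "),
         "; use na_action = \"renormalize\" to rescale weights",
         call. = FALSE)
  }
  if (any(has_na)) {
    # renormalise weights over the parameters present in each row
    present <- !is.na(vals)
    if (any(rowSums(present) == 0)) {
      stop("row(s) with no parameter values at all", call. = FALSE)
    }
    wmat <- matrix(rep(w, each = nrow(vals)), nrow = nrow(vals)) * present
    wqi <- rowSums(qmat * wmat, na.rm = TRUE) / rowSums(wmat)
  } else {
    wqi <- as.numeric(qmat %*% w)
  }
  cd <- rowSums(cfmat, na.rm = TRUE)

  colnames(qmat) <- paste0("q_", standards$parameter)
  colnames(cfmat) <- paste0("cf_", standards$parameter)
  out <- dplyr::bind_cols(
    data,
    tibble::tibble(
      wqi = wqi,
      rank_wqs = classify_wqi(wqi),
      cd = cd,
      rank_cds = classify_cd(cd),
      partial = has_na
    ),
    tibble::as_tibble(qmat),
    tibble::as_tibble(cfmat)
  )
  out$wqs_label <- rank_label(out$rank_wqs, "wqi")
  out$cds_label <- rank_label(out$rank_cds, "cd")
  out <- dplyr::relocate(out, "wqs_label", .after = "rank_wqs")
  out <- dplyr::relocate(out, "cds_label", .after = "rank_cds")
  attr(out, "k") <- attr(unit_weights(standards), "k")
  class(out) <- c("wq_indices", class(tibble::tibble()))
  out
}

# sample-level invariants: pH inside (0, 14), concentrations non-negative
validate_samples <- function(data, standards) {
  for (p in standards$parameter) {
    v <- data[[p]]
    bad <- if (p == "pH") {
      !is.na(v) & (v <= 0 | v >= 14)
    } else {
      !is.na(v) & v < 0
    }
    if (any(bad)) {
      stop("invalid ", p, " value in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(data)
}
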