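#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance and averages
#' \eqn{\frac{1}{2}(z_i - z_j)^2} within each bin. Bins without pairs are
#' omitted.
#'
#' @param data Data frame with coordinate columns `x`, `y` and the value
#'   column.
#' @param value Name of the value column.
#' @param n_lags Number of distance bins.
#' @param max_dist Largest pair distance used; defaults to half the maximum
#'   pairwise distance.
#' @return A tibble of class `wq_semivariogram` with columns `lag`
#'   (bin-center distance), `dist` (mean pair distance in the bin), `gamma`
#'   and `n_pairs`; attributes `sample_var` and `max_dist` support fallback
#'   variogram models.
#' @export
empirical_semivariogram <- function(data, value, n_lags = 12,
                                    max_dist = NULL) {
  z <- data[[value]]
  ok <- !is.na(z) & !is.na(data$x) & !is.na(data$y)
  x <- data$x[ok]; y <- data$y[ok]; z <- z[ok]
  if (length(z) < 3) stop("need at least 3 points", call. = FALSE)
  d <- stats::dist(cbind(x, y))
  if (max(d) == 0) stop("all points are coincident", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  dz2 <- 0.5 * stats::dist(z)^2
  dv <- as.numeric(d); gv <- as.numeric(dz2)
  keep <- dv <= max_dist & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  if (length(dv) == 0) stop("no pairs within max_dist", call. = FALSE)
  breaks <- seq(0, max_dist, length.out = n_lags + 1)
  bin <- cut(dv, breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(bin = bin, d = dv, g = gv) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(dist = mean(.data$d), gamma = mean(.data$g),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(lag = (breaks[.data$bin] + breaks[.data$bin + 1]) / 2,
                  .before = 1) |>
    dplyr::select("lag", "dist", "gamma", "n_pairs")
  attr(out, "sample_var") <- stats::var(z)
  attr(out, "max_dist") <- max(stats::dist(cbind(x, y)))
  class(out) <- c("wq_semivariogram", class(tibble::tibble()))
  out
}

#' Theoretical variogram value
#'
#' Evaluates a spherical, exponential or gaussian variogram model
#' \eqn{\gamma(h)} (nugget + partial sill structure) at distances `h`;
#' \eqn{\gamma(0) = 0} by convention (the nugget is a discontinuity at the
#' origin).
#'
#' @param model A `wq_variogram` (see [fit_variogram()]) or a list with
#'   `family`, `nugget`, `psill`, `range`.
#' @param h Non-negative distances.
#' @return Numeric vector of semivariances.
#' @export
variogram_gamma <- function(model, h) {
  g <- with(model, switch(
    family,
    spherical = ifelse(h >= range, psill,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    exponential = psill * (1 - exp(-3 * h / range)),
    gaussian = psill * (1 - exp(-3 * (h / range)^2)),
    stop("unknown variogram family: ", model$family, call. = FALSE)
  ))
  out <- model$nugget + g
  out[h == 0] <- 0
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range of the chosen family to an empirical
#' semivariogram, minimising the pair-count-weighted squared residuals
#' (Cressie-style WLS) under positivity bounds. With fewer than three
#' usable lags, or if the optimiser fails, a fallback model is returned
#' (nugget 0, partial sill = sample variance, range = half the maximum
#' point distance) and flagged.
#'
#' @param emp A `wq_semivariogram` from [empirical_semivariogram()].
#' @param family `"spherical"` (default), `"exponential"` or `"gaussian"`.
#' @return A list of class `wq_variogram`: `family`, `nugget`, `psill`,
#'   `range`, `rss`, `fallback`.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential",
                                          "gaussian")) {
  family <- match.arg(family)
  sv <- attr(emp, "sample_var") %||% stats::var(emp$gamma)
  md <- attr(emp, "max_dist") %||% (max(emp$lag) * 2)
  fallback <- structure(
    list(family = family, nugget = 0, psill = max(sv, 1e-12), range = md / 2,
         rss = NA_real_, fallback = TRUE),
    class = "wq_variogram"
  )
  if (nrow(emp) < 3) {
    warning("fewer than 3 semivariogram lags: returning fallback model")
    return(fallback)
  }
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], psill = par[2],
              range = par[3])
    sum(emp$n_pairs * (emp$gamma - variogram_gamma(m, emp$lag))^2)
  }
  start <- c(nugget = 0, psill = max(sv, 1e-12), range = max(emp$lag) / 2)
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = c(0, 1e-12, max(emp$lag) * 1e-4),
                 upper = c(Inf, Inf, md * 10)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("variogram optimisation failed: returning fallback model")
    return(fallback)
  }
  nugget <- fit$par[[1]]; psill <- fit$par[[2]]; range <- fit$par[[3]]
  if (range < min(emp$lag)) {
    # structure below the first lag is unobservable: fold it into the nugget
    nugget <- nugget + psill
    psill <- 0
    range <- min(emp$lag)
  }
  structure(
    list(family = family, nugget = nugget, psill = psill,
         range = range, rss = fit$value, fallback = FALSE),
    class = "wq_variogram"
  )
}

#' Ordinary kriging onto a raster grid
#'
#' Global ordinary kriging: at every cell center the weights solve the
#' semivariance system augmented with the unbiasedness constraint (Lagrange
#' multiplier), so they sum to one; the kriging variance
#' \eqn{\sigma^2_K = \sum_i \lambda_i \gamma(x_i, x_0) + \mu} is returned
#' per cell. With a zero nugget the predictor honours the data exactly at
#' well locations. Duplicate locations are averaged before solving; no
#' search neighbourhood is used (the monitoring networks targeted have at
#' most a few dozen wells).
#'
#' @param data Data frame with `x`, `y` and the value column.
#' @param value Name of the value column.
#' @param grid A `wq_raster` specification (e.g. [grid_from_points()]).
#' @param model A `wq_variogram`; default fits a spherical model to the
#'   empirical semivariogram of the data.
#' @return A list of class `wq_kriging` with elements `prediction` and
#'   `variance` (both `wq_raster`), `model`, and `max_weight_error` (the
#'   largest deviation of any cell's weight sum from 1).
#' @export
ordinary_kriging <- function(data, value, grid = grid_from_points(data),
                             model = NULL) {
  z <- data[[value]]
  pts <- tibble::tibble(x = data$x, y = data$y, z = z) |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  n <- nrow(pts)
  if (is.null(model)) {
    if (n < 3) stop("need at least 3 distinct points", call. = FALSE)
    model <- fit_variogram(empirical_semivariogram(pts, "z"))
  }
  if (n < 2) stop("need at least 2 distinct points", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  if (max(d) == 0) stop("all points are coincident", call. = FALSE)
  A <- rbind(cbind(variogram_gamma(model, d), 1), c(rep(1, n), 0))
  cc <- grid_coords(grid)
  d0 <- sqrt(outer(pts$x, cc$x, "-")^2 + outer(pts$y, cc$y, "-")^2)
  B <- rbind(matrix(variogram_gamma(model, as.numeric(d0)), n), 1)
  lam <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system (degenerate point configuration)",
         call. = FALSE)
  })
  w <- lam[seq_len(n), , drop = FALSE]
  mu <- lam[n + 1, ]
  pred <- as.numeric(crossprod(w, pts$z))
  kvar <- pmax(colSums(w * matrix(B[seq_len(n), ], n)) + mu, 0)
  structure(
    list(
      prediction = raster_grid(grid$origin, grid$cellsize, grid$nrow,
                               grid$ncol, matrix(pred, grid$nrow, grid$ncol,
                                                 byrow = TRUE)[, , drop = FALSE],
                               crs = grid$crs, nodata = grid$nodata),
      variance = raster_grid(grid$origin, grid$cellsize, grid$nrow,
                             grid$ncol, matrix(kvar, grid$nrow, grid$ncol,
                                               byrow = TRUE),
                             crs = grid$crs, nodata = grid$nodata),
      model = model,
      max_weight_error = max(abs(colSums(w) - 1))
    ),
    class = "wq_kriging"
  )
}

#' Kriging prediction at arbitrary points
#'
#' Same system as [ordinary_kriging()] but evaluated at a set of target
#' points instead of a grid; used for leave-one-out checks.
#'
#' @inheritParams ordinary_kriging
#' @param targets Data frame with `x`, `y` of prediction locations.
#' @return A tibble with `x`, `y`, `pred`, `kvar`, `weight_sum`.
#' @export
krige_points <- function(data, value, targets, model = NULL) {
  z <- data[[value]]
  pts <- tibble::tibble(x = data$x, y = data$y, z = z) |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  n <- nrow(pts)
  if (is.null(model)) {
    if (n < 3) stop("need at least 3 distinct points", call. = FALSE)
    model <- fit_variogram(empirical_semivariogram(pts, "z"))
  }
  if (n < 2) stop("need at least 2 distinct points", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  A <- rbind(cbind(variogram_gamma(model, d), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(pts$x, targets$x, "-")^2 + outer(pts$y, targets$y, "-")^2)
  B <- rbind(matrix(variogram_gamma(model, as.numeric(d0)), n), 1)
  lam <- solve(A, B)
  w <- lam[seq_len(n), , drop = FALSE]
  tibble::tibble(
    x = targets$x, y = targets$y,
    pred = as.numeric(crossprod(w, pts$z)),
    kvar = as.numeric(pmax(colSums(w * matrix(B[seq_len(n), ], n)) +
                             lam[n + 1, ], 0)),
    weight_sum = as.numeric(colSums(w))
  )
}

#' Inverse-distance-weighted interpolation onto a raster grid
#'
#' Weighted mean with weights \eqn{1/d^p}; a cell coinciding with a data
#' point takes that point's value exactly. Predictions are convex
#' combinations of the data, hence bounded by the data range.
#'
#' @inheritParams ordinary_kriging
#' @param power Distance exponent (default 2).
#' @return A `wq_raster` of predictions.
#' @export
idw <- function(data, value, grid = grid_from_points(data), power = 2) {
  z <- data[[value]]
  ok <- !is.na(z)
  x <- data$x[ok]; y <- data$y[ok]; z <- z[ok]
  if (length(z) < 1) stop("need at least 1 point", call. = FALSE)
  cc <- grid_coords(grid)
  d0 <- sqrt(outer(x, cc$x, "-")^2 + outer(y, cc$y, "-")^2)
  pred <- vapply(seq_len(nrow(cc)), function(j) {
    dj <- d0[, j]
    hit <- which(dj == 0)
    if (length(hit) > 0) return(mean(z[hit]))
    w <- 1 / dj^power
    sum(w * z) / sum(w)
  }, numeric(1))
  raster_grid(grid$origin, grid$cellsize, grid$nrow, grid$ncol,
              matrix(pred, grid$nrow, grid$ncol, byrow = TRUE),
              crs = grid$crs, nodata = grid$nodata)
}
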