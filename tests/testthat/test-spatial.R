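test_that("empirical semivariogram matches the pairwise double loop", {
  set.seed(21)
  d <- tibble::tibble(x = stats::runif(18, 0, 100),
                      y = stats::runif(18, 0, 100),
                      z = stats::rnorm(18))
  emp <- empirical_semivariogram(d, "z", n_lags = 6)
  md <- max(dist(cbind(d$x, d$y))) / 2
  oracle <- oracle_semivariogram(d$x, d$y, d$z,
                                 seq(0, md, length.out = 7))
  expect_equal(emp$gamma, oracle$g)
  expect_equal(emp$dist, oracle$d)
  expect_equal(emp$n_pairs, oracle$n_pairs)
  expect_equal(sum(emp$n_pairs), sum(dist(cbind(d$x, d$y)) <= md))
})

test_that("semivariogram handles constant fields and bad input", {
  d <- tibble::tibble(x = c(0, 1, 2, 5), y = c(0, 1, 0, 2), z = rep(4, 4))
  emp <- empirical_semivariogram(d, "z")
  expect_true(all(emp$gamma == 0))
  # a single isolated pair gives the hand value 0.5*(0-2)^2 = 2
  d2 <- tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, 60), z = c(0, 2, 5))
  emp2 <- empirical_semivariogram(d2, "z", n_lags = 1, max_dist = 2)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$n_pairs, 1L)
  expect_error(empirical_semivariogram(
    tibble::tibble(x = c(0, 0, 0), y = c(0, 0, 0), z = 1:3), "z"),
    "coincident")
  expect_error(empirical_semivariogram(d[1:2, ], "z"), "3 points")
})

test_that("variogram fitting recovers noise-free spherical parameters", {
  true <- list(family = "spherical", nugget = 0.4, psill = 2.5, range = 60)
  lags <- seq(5, 100, by = 5)
  emp <- tibble::tibble(lag = lags, dist = lags,
                        gamma = variogram_gamma(true, lags),
                        n_pairs = rep(20L, length(lags)))
  attr(emp, "sample_var") <- 2.9
  attr(emp, "max_dist") <- 200
  fit <- fit_variogram(emp, "spherical")
  expect_false(fit$fallback)
  expect_equal(fit$nugget, true$nugget, tolerance = 0.01)
  expect_equal(fit$psill, true$psill, tolerance = 0.01)
  expect_equal(fit$range, true$range, tolerance = 0.01)
})

test_that("flat semivariograms collapse to a pure-nugget model", {
  lags <- seq(10, 80, by = 10)
  emp <- tibble::tibble(lag = lags, dist = lags, gamma = rep(1.7, 8),
                        n_pairs = rep(10L, 8))
  attr(emp, "sample_var") <- 1.7
  attr(emp, "max_dist") <- 160
  fit <- fit_variogram(emp, "spherical")
  expect_lt(fit$psill, 0.05 * 1.7)
  expect_equal(fit$nugget + fit$psill, 1.7, tolerance = 0.02)
})

test_that("too few lags trigger the flagged fallback model", {
  emp <- tibble::tibble(lag = c(10, 20), dist = c(10, 20), gamma = c(1, 2),
                        n_pairs = c(5L, 5L))
  attr(emp, "sample_var") <- 1.5
  attr(emp, "max_dist") <- 100
  expect_warning(fit <- fit_variogram(emp), "fallback")
  expect_true(fit$fallback)
  expect_equal(fit$nugget, 0)
  expect_equal(fit$psill, 1.5)
  expect_equal(fit$range, 50)
})

test_that("kriging honours data exactly with zero nugget", {
  set.seed(31)
  d <- tibble::tibble(x = stats::runif(12, 0, 100),
                      y = stats::runif(12, 0, 100),
                      z = stats::rnorm(12, 10, 3))
  model <- structure(list(family = "spherical", nugget = 0, psill = 4,
                          range = 50), class = "wq_variogram")
  at_data <- krige_points(d, "z", d, model = model)
  expect_equal(at_data$pred, d$z, tolerance = 1e-8)
  expect_equal(at_data$kvar, rep(0, 12), tolerance = 1e-8)
  expect_equal(at_data$weight_sum, rep(1, 12), tolerance = 1e-8)
})

test_that("kriging a constant field predicts the constant everywhere", {
  d <- tibble::tibble(x = c(0, 40, 80, 20), y = c(0, 10, 60, 90),
                      z = rep(6.5, 4))
  model <- structure(list(family = "exponential", nugget = 0.1, psill = 2,
                          range = 30), class = "wq_variogram")
  kr <- ordinary_kriging(d, "z", raster_grid(c(-10, -10), 20, 6, 6),
                         model = model)
  expect_true(all(abs(kr$prediction$values - 6.5) < 1e-8))
  expect_lt(kr$max_weight_error, 1e-8)
  expect_true(all(kr$variance$values >= 0))
})

test_that("symmetric two-point kriging gives equal weights", {
  # hand-solved 3x3 system: equidistant target from two points
  d <- tibble::tibble(x = c(-10, 10), y = c(0, 0), z = c(4, 8))
  model <- structure(list(family = "spherical", nugget = 0, psill = 1,
                          range = 50), class = "wq_variogram")
  out <- krige_points(d, "z", tibble::tibble(x = 0, y = 0), model = model)
  g20 <- variogram_gamma(model, 20)
  g10 <- variogram_gamma(model, 10)
  A <- rbind(c(0, g20, 1), c(g20, 0, 1), c(1, 1, 0))
  lam <- solve(A, c(g10, g10, 1))
  expect_equal(lam[1:2], c(0.5, 0.5))
  expect_equal(out$pred, 6) # (4 + 8) / 2
  expect_equal(out$kvar, sum(lam[1:2] * g10) + lam[3])
})

test_that("kriging beats the global mean on held-out wells", {
  set.seed(41)
  rmse_k <- c(); rmse_m <- c()
  for (rep in 1:5) {
    pts <- tibble::tibble(x = stats::runif(35, 0, 1000),
                          y = stats::runif(35, 0, 1000))
    pts$z <- simulate_spatial_field(pts, range_m = 400, seed = 500 + rep) +
      5
    hold <- 26:35
    model <- structure(list(family = "exponential", nugget = 0, psill = 1,
                            range = 400), class = "wq_variogram")
    pr <- krige_points(pts[-hold, ], "z", pts[hold, ], model = model)
    rmse_k <- c(rmse_k, sqrt(mean((pr$pred - pts$z[hold])^2)))
    rmse_m <- c(rmse_m, sqrt(mean((mean(pts$z[-hold]) - pts$z[hold])^2)))
  }
  expect_lt(mean(rmse_k), mean(rmse_m))
})

test_that("kriging rejects degenerate configurations", {
  expect_error(ordinary_kriging(
    tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(1, 5)), "z"),
    "3 distinct")
  # duplicate locations are averaged before solving
  d <- tibble::tibble(x = c(0, 0, 50, 90), y = c(0, 0, 20, 80),
                      z = c(2, 4, 6, 8))
  model <- structure(list(family = "spherical", nugget = 0, psill = 1,
                          range = 60), class = "wq_variogram")
  pr <- krige_points(d, "z", tibble::tibble(x = 0, y = 0), model = model)
  expect_equal(pr$pred, 3) # mean of the duplicated location
})

test_that("IDW interpolates exactly at wells and stays within data range", {
  d <- tibble::tibble(x = c(0, 100), y = c(0, 0), z = c(10, 20))
  g <- raster_grid(c(-0.5, -0.5), 1, 1, 101) # row of cells centred y = 0
  r <- idw(d, "z", g, power = 2)
  expect_equal(r$values[1, 1], 10)    # node on the first well
  expect_equal(r$values[1, 51], 15)   # equidistant node
  expect_true(all(r$values >= 10 & r$values <= 20))

  # three-point brute force
  d3 <- tibble::tibble(x = c(0, 10, 0), y = c(0, 0, 10), z = c(1, 5, 9))
  g1 <- raster_grid(c(1.5, 2.5), 1, 1, 1) # single cell centred (2, 3)
  r3 <- idw(d3, "z", g1, power = 2)
  w <- 1 / c(2^2 + 3^2, 8^2 + 3^2, 2^2 + 7^2)
  expect_equal(r3$values[1, 1], sum(w * d3$z) / sum(w))
  expect_error(idw(d3[0, ], "z", g1), "1 point")
})

test_that("raster classification applies the scalar classifier cellwise", {
  vals <- matrix(c(0, 30, 60, 90, 120, NA), 2, 3)
  g <- raster_grid(c(0, 0), 10, 2, 3, vals)
  cls <- classify_raster(g, "wqi")
  expect_equal(as.numeric(cls$values),
               as.numeric(classify_wqi(as.numeric(vals))))
  expect_true(is.na(cls$values[2, 3]))

  const <- raster_grid(c(0, 0), 10, 3, 3, matrix(25, 3, 3))
  expect_true(all(classify_raster(const, "wqi")$values == 1))

  allna <- raster_grid(c(0, 0), 10, 2, 2)
  expect_true(all(is.na(classify_raster(allna, "cd")$values)))

  neg <- raster_grid(c(0, 0), 10, 1, 2, matrix(c(-3, 50), 1, 2))
  expect_warning(cneg <- classify_raster(neg, "wqi"), "negative")
  expect_true(is.na(cneg$values[1, 1]))
  expect_equal(attr(cneg, "n_negative"), 1L)
})

test_that("ESRI ASCII round trip preserves values and georeferencing", {
  set.seed(51)
  vals <- matrix(stats::rnorm(12) * 1e3, 3, 4)
  vals[2, 2] <- NA
  g <- raster_grid(c(123.456789, -987.654321), 12.5, 3, 4, vals,
                   crs = "EPSG:23700")
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  g2 <- read_esri_ascii(path)
  expect_identical(g2$values, g$values)
  expect_identical(g2$origin, g$origin)
  expect_identical(g2$cellsize, g$cellsize)
  expect_equal(g2$crs, "EPSG:23700")
  # grid geometry helpers: row 1 is the northernmost row
  cc <- grid_coords(g)
  expect_equal(max(cc$y), g$origin[2] + (3 - 0.5) * 12.5)
  expect_equal(cc$y[cc$row == 1][1] > cc$y[cc$row == 3][1], TRUE)
})
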