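# shared fixtures and independent oracles used across test files

default_params <- c("pH", "EC", "NH4", "NO2", "NO3", "PO4", "COD", "Na")

# one sample with every parameter at the given named values
sample_row <- function(values, well_id = "w1", year = 2013,
                       x = 0, y = 0) {
  tibble::tibble(well_id = well_id, year = year, x = x, y = y,
                 !!!as.list(values))
}

# sample at the permissible-limit vector (pH at its upper bound)
limit_sample <- function() {
  sample_row(c(pH = 8.5, EC = 2500, NH4 = 0.5, NO2 = 0.5, NO3 = 50,
               PO4 = 0.5, COD = 4.5, Na = 200))
}

# sample at the ideal vector (pH 7, all concentrations 0)
ideal_sample <- function() {
  sample_row(c(pH = 7, EC = 0, NH4 = 0, NO2 = 0, NO3 = 0,
               PO4 = 0, COD = 0, Na = 0))
}

# independent permutation generator (iterative Steinhaus-Johnson-ish
# insertion construction, distinct from the package's recursive one)
oracle_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      t(vapply(seq_len(k), function(pos) {
        append(out[i, ], k, after = pos - 1)
      }, integer(k)))
    }))
  }
  out
}

# brute-force Pearson correlation of average ranks, written out longhand
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact signed-rank two-sided p by explicit enumeration of all 2^n sign
# vectors (matrix expansion, independent of the package's convolution)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# O(n^2) double-loop semivariogram oracle
oracle_semivariogram <- function(x, y, z, breaks) {
  n <- length(z)
  acc <- data.frame(bin = integer(0), d = numeric(0), g = numeric(0))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (dij > 0 && dij <= max(breaks)) {
        b <- findInterval(dij, breaks, left.open = TRUE)
        b <- max(b, 1L)
        acc <- rbind(acc, data.frame(bin = b, d = dij,
                                     g = 0.5 * (z[i] - z[j])^2))
      }
    }
  }
  out <- aggregate(cbind(d, g) ~ bin, acc, mean)
  out$n_pairs <- as.integer(table(acc$bin)[as.character(out$bin)])
  out
}
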