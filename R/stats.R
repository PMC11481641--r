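#' Per-group descriptive summary
#'
#' Reproduces the monitoring-report layout: for each group (by default each
#' sampling year) and each requested variable, the sample size, mean,
#' minimum, maximum and the lower/upper quartiles. Quartiles use linear
#' interpolation between order statistics with inclusive endpoints
#' (`stats::quantile()` type 7, the common spreadsheet definition).
#'
#' @param data A data frame.
#' @param vars Character vector of numeric column names to summarise.
#' @param group Grouping column name (default `"year"`).
#' @return A tibble with columns `<group>`, `variable`, `n`, `mean`, `min`,
#'   `max`, `q25`, `q75`. Missing values are dropped per variable; empty
#'   groups are omitted with a warning.
#' @export
descriptive_summary <- function(data, vars, group = "year") {
  if (!group %in% names(data)) stop("no grouping column ", group, call. = FALSE)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("no such column(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  long <- data |>
    dplyr::select(dplyr::all_of(c(group, vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::filter(!is.na(.data$value))
  if (nrow(long) == 0) {
    warning("no non-missing values to summarise")
    return(tibble::tibble())
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "variable")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      q25 = stats::quantile(.data$value, 0.25, names = FALSE, type = 7),
      q75 = stats::quantile(.data$value, 0.75, names = FALSE, type = 7),
      .groups = "drop"
    ) |>
    dplyr::mutate(variable = factor(.data$variable, levels = vars)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(group)), .data$variable) |>
    dplyr::mutate(variable = as.character(.data$variable))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2}
#' degrees of freedom by default; for small samples (`n <= 8`) an exact
#' permutation p-value (full enumeration of all `n!` orderings, two-sided
#' on `|rho|`) is available.
#'
#' @param x,y Numeric vectors of equal length (>= 3); pairs with a missing
#'   value are dropped.
#' @param method `"t"` (default) or `"exact"` (requires n <= 8).
#' @return A list of class `wq_correlation`: `rho`, `p_value`, `n`,
#'   `method`.
#' @export
spearman_rank <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop("exact permutation limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tt), df = n - 2)
    p_value <- min(1, max(p_value, .Machine$double.xmin))
  }
  structure(list(rho = rho, p_value = p_value, n = n, method = method),
            class = "wq_correlation")
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Wilcoxon signed-rank test for paired pre/post samples
#'
#' Paired two-sided signed-rank test in the reporting convention of classic
#' statistics packages: zero differences are dropped (or down-weighted with
#' `zero_handling = "pratt"`), absolute differences receive average ranks,
#' the test statistic is \eqn{W = \min(W^+, W^-)}, and
#' \deqn{Z = \frac{W^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3-t)/48}}}
#' so that Z is negative when the post values are predominantly lower. For
#' small effective samples (`n <= exact_limit`, default 15) the two-sided
#' p-value is exact, from full enumeration of all \eqn{2^n} sign
#' assignments; otherwise the normal approximation is used.
#'
#' @param pre,post Paired numeric vectors (same wells, same order).
#' @param zero_handling `"drop"` (default) or `"pratt"`.
#' @param exact_limit Largest effective n for the exact branch.
#' @return A list of class `wq_wilcoxon`: `w` (min rank sum), `w_plus`,
#'   `w_minus`, `z`, `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post, zero_handling = c("drop", "pratt"),
                                 exact_limit = 15) {
  zero_handling <- match.arg(zero_handling)
  if (length(pre) != length(post)) stop("unpaired vectors", call. = FALSE)
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  if (zero_handling == "drop") d <- d[d != 0]
  if (length(d) == 0 || all(d == 0)) {
    stop("all paired differences are zero: test degenerate", call. = FALSE)
  }
  r <- rank(abs(d))
  if (zero_handling == "pratt") {
    keep <- d != 0
    d <- d[keep]; r <- r[keep]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  mu <- sum(r) / 2
  sigma2 <- sum(r^2) / 4
  z <- (w_plus - mu) / sqrt(sigma2)
  if (n <= exact_limit) {
    p_value <- exact_signed_rank_p(r, w_plus)
    method <- "exact"
  } else {
    # continuity-corrected tail probability; the reported Z stays uncorrected
    zc <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)
    p_value <- min(1, 2 * stats::pnorm(-max(zc, 0)))
    method <- "normal-approximation"
  }
  structure(
    list(w = w, w_plus = w_plus, w_minus = w_minus, z = z,
         p_value = p_value, n_effective = n, method = method),
    class = "wq_wilcoxon"
  )
}

# exact two-sided p over all 2^n assignments of signs to the rank vector:
# doubled lower/upper tail of W+, capped at 1
exact_signed_rank_p <- function(r, w_plus) {
  n <- length(r)
  total <- 2^n
  # distribution of W+ by iterated convolution over ranks
  sums <- 0
  counts <- 1
  for (ri in r) {
    sums <- c(sums, sums + ri)
    counts <- c(counts, counts)
  }
  lower <- sum(counts[sums <= w_plus + 1e-9]) / total
  upper <- sum(counts[sums >= w_plus - 1e-9]) / total
  min(1, 2 * min(lower, upper))
}

#' Fisher two-group linear discriminant analysis
#'
#' Fisher's discriminant for two groups: the direction solves
#' \eqn{S_W w = \bar{x}_1 - \bar{x}_2} with \eqn{S_W} the pooled
#' within-group scatter; samples are classified by the nearest group mean
#' on the discriminant axis (midpoint cut, equal priors; boundary ties go
#' to the first group level deterministically). Reported alongside:
#' Wilks' \eqn{\Lambda = SSW/(SSB+SSW)} of the discriminant scores with
#' Bartlett's chi-square approximation, confusion matrices and percent
#' correctly classified for the original fit and for leave-one-out
#' cross-validation (the model is refitted n times).
#'
#' If the within-group scatter is singular it is ridge-regularised by
#' `1e-8 * mean diagonal` with a warning before failing.
#'
#' @param data A data frame.
#' @param features Character vector of feature column names.
#' @param group Name of a two-level grouping column (e.g. `period`).
#' @return A list of class `wq_lda`: `coefficients`, `group_levels`,
#'   `group_means` (on the discriminant axis), `cut`, `wilks_lambda`,
#'   `chi_sq`, `df`, `p_value`, `confusion`, `confusion_loo`, `accuracy`,
#'   `accuracy_loo`, `n`, `scores`.
#' @export
lda_two_group <- function(data, features, group) {
  X <- as.matrix(data[features])
  g <- data[[group]]
  if (!is.factor(g) && all(c("pre_sewerage", "post_sewerage") %in% unique(g))) {
    g <- factor(g, levels = c("pre_sewerage", "post_sewerage"))
  }
  g <- factor(g)
  if (nlevels(g) != 2) stop("group must have exactly two levels", call. = FALSE)
  ok <- stats::complete.cases(X) & !is.na(g)
  X <- X[ok, , drop = FALSE]; g <- droplevels(g[ok])
  n <- nrow(X); p <- ncol(X)
  if (any(table(g) < 2) || n <= p + 1) {
    stop("need >= 2 samples per group and more samples than features",
         call. = FALSE)
  }
  fit <- fisher_fit(X, g)
  scores <- as.numeric(X %*% fit$w)
  pred <- factor(classify_scores(scores, fit), levels = levels(g))
  confusion <- table(actual = g, predicted = pred)

  # Wilks' Lambda from the one-dimensional scores
  m1 <- mean(scores[g == levels(g)[1]]); m2 <- mean(scores[g == levels(g)[2]])
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  ssb <- n1 * (m1 - mean(scores))^2 + n2 * (m2 - mean(scores))^2
  ssw <- sum((scores[g == levels(g)[1]] - m1)^2) +
    sum((scores[g == levels(g)[2]] - m2)^2)
  lambda <- ssw / (ssb + ssw)
  chi_sq <- -(n - 1 - (p + 2) / 2) * log(lambda)
  df <- p
  p_value <- stats::pchisq(chi_sq, df, lower.tail = FALSE)

  # leave-one-out: refit without each sample, classify the held-out one
  pred_loo <- vapply(seq_len(n), function(i) {
    f <- fisher_fit(X[-i, , drop = FALSE], g[-i])
    classify_scores(as.numeric(X[i, , drop = FALSE] %*% f$w), f)
  }, character(1))
  pred_loo <- factor(pred_loo, levels = levels(g))
  confusion_loo <- table(actual = g, predicted = pred_loo)

  structure(
    list(
      coefficients = stats::setNames(as.numeric(fit$w), features),
      group_levels = levels(g),
      group_means = c(fit$m1s, fit$m2s),
      cut = fit$cut,
      wilks_lambda = lambda, chi_sq = chi_sq, df = df, p_value = p_value,
      confusion = confusion, confusion_loo = confusion_loo,
      accuracy = 100 * sum(diag(confusion)) / n,
      accuracy_loo = 100 * sum(diag(confusion_loo)) / n,
      n = n, scores = scores
    ),
    class = "wq_lda"
  )
}

fisher_fit <- function(X, g) {
  lv <- levels(g)
  X1 <- X[g == lv[1], , drop = FALSE]
  X2 <- X[g == lv[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sw <- crossprod(scale(X1, center = mu1, scale = FALSE)) +
    crossprod(scale(X2, center = mu2, scale = FALSE))
  w <- tryCatch(solve(Sw, mu1 - mu2), error = function(e) {
    warning("singular within-group scatter: ridge-regularising")
    solve(Sw + diag(1e-8 * mean(diag(Sw)), ncol(Sw)), mu1 - mu2)
  })
  m1s <- sum(mu1 * w); m2s <- sum(mu2 * w)
  list(w = w, lv = lv, m1s = m1s, m2s = m2s, cut = (m1s + m2s) / 2)
}

classify_scores <- function(scores, fit) {
  # group 1 sits on the side of its own projected mean; boundary -> group 1
  if (fit$m1s >= fit$m2s) {
    ifelse(scores >= fit$cut, fit$lv[1], fit$lv[2])
  } else {
    ifelse(scores <= fit$cut, fit$lv[1], fit$lv[2])
  }
}

#' Rank agreement between the two indices
#'
#' Tabulates the per-sample rank difference (WQI rank minus Cd rank) over
#' the five-rank scales, with percentages and the share of samples whose
#' ranks differ by at most two.
#'
#' @param indices A `wq_indices` tibble (needs `rank_wqs` and `rank_cds`).
#' @return A tibble with columns `difference` (-4..4), `n`, `pct`, carrying
#'   attributes `total` and `share_within_2` (percent with |difference| <=
#'   2).
#' @export
rank_agreement <- function(indices) {
  if (nrow(indices) == 0) stop("no index results", call. = FALSE)
  d <- indices$rank_wqs - indices$rank_cds
  tab <- tibble::tibble(difference = -4:4) |>
    dplyr::left_join(
      tibble::tibble(difference = d) |> dplyr::count(.data$difference),
      by = "difference"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = 100 * .data$n / length(d))
  attr(tab, "total") <- length(d)
  attr(tab, "share_within_2") <- 100 * mean(abs(d) <= 2)
  tab
}

#' Per-year counts of samples in each rank
#'
#' @param indices A `wq_indices` tibble with a `year` column.
#' @param index `"wqs"` (WQI ranks) or `"cds"` (contamination-degree ranks).
#' @return A tibble with columns `year`, `rank_1` .. `rank_5`, `n`; row sums
#'   of the rank columns equal the per-year sample counts.
#' @export
count_by_rank <- function(indices, index = c("wqs", "cds")) {
  index <- match.arg(index)
  col <- paste0("rank_", index)
  if (!col %in% names(indices)) stop("no column ", col, call. = FALSE)
  indices |>
    dplyr::count(.data$year, rank = factor(.data[[col]], levels = 1:5),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "rank", values_from = "n",
                       names_prefix = "rank_", values_fill = 0L) |>
    dplyr::mutate(n = .data$rank_1 + .data$rank_2 + .data$rank_3 +
                    .data$rank_4 + .data$rank_5)
}

#' Pre/post comparison of an index, paired by well
#'
#' Pairs each well's pre-sewerage value with the mean of its post-sewerage
#' values and runs the signed-rank test. Wells lacking either period are
#' dropped.
#'
#' @param indices A `wq_indices` tibble with `well_id` and `period` columns.
#' @param value Column to compare (`"wqi"` or `"cd"`).
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return A `wq_wilcoxon` object (see [wilcoxon_signed_rank()]).
#' @export
prepost_wilcoxon <- function(indices, value = "wqi", ...) {
  paired <- indices |>
    dplyr::group_by(.data$well_id, .data$period) |>
    dplyr::summarise(v = mean(.data[[value]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "period", values_from = "v") |>
    dplyr::filter(!is.na(.data$pre_sewerage) & !is.na(.data$post_sewerage))
  if (nrow(paired) == 0) stop("no wells with both periods", call. = FALSE)
  wilcoxon_signed_rank(paired$pre_sewerage, paired$post_sewerage, ...)
}
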