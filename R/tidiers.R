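#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy / glance methods for test objects
#'
#' broom-style accessors: `tidy()` returns a one-row-per-term tibble,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name gwindex-tidiers
NULL

#' @rdname gwindex-tidiers
#' @export
tidy.wq_wilcoxon <- function(x, ...) {
  tibble::tibble(
    statistic = x$w, w_plus = x$w_plus, w_minus = x$w_minus,
    z = x$z, p_value = x$p_value, n_effective = x$n_effective,
    method = x$method
  )
}

#' @rdname gwindex-tidiers
#' @export
glance.wq_wilcoxon <- function(x, ...) tidy(x)

#' @rdname gwindex-tidiers
#' @export
tidy.wq_correlation <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n = x$n,
                 method = x$method)
}

#' @rdname gwindex-tidiers
#' @export
glance.wq_correlation <- function(x, ...) tidy(x)

#' @rdname gwindex-tidiers
#' @export
tidy.wq_lda <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 coefficient = as.numeric(x$coefficients))
}

#' @rdname gwindex-tidiers
#' @export
glance.wq_lda <- function(x, ...) {
  tibble::tibble(
    wilks_lambda = x$wilks_lambda, chi_sq = x$chi_sq, df = x$df,
    p_value = x$p_value, accuracy = x$accuracy,
    accuracy_loo = x$accuracy_loo, n = x$n
  )
}

#' @rdname gwindex-tidiers
#' @export
tidy.wq_variogram <- function(x, ...) {
  tibble::tibble(family = x$family, nugget = x$nugget, psill = x$psill,
                 range = x$range, rss = x$rss, fallback = x$fallback)
}

#' @export
print.wq_wilcoxon <- function(x, ...) {
  cat("Wilcoxon signed-rank test (paired, two-sided)\n")
  cat(sprintf("  W = %g (W+ = %g, W- = %g), Z = %.3f, p = %.4g [%s], n = %d\n",
              x$w, x$w_plus, x$w_minus, x$z, x$p_value, x$method,
              x$n_effective))
  invisible(x)
}

#' @export
print.wq_correlation <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (%s, n = %d)\n",
              x$rho, x$p_value, x$method, x$n))
  invisible(x)
}

#' @export
print.wq_lda <- function(x, ...) {
  cat("Fisher two-group discriminant analysis\n")
  cat(sprintf("  Wilks' Lambda = %.4f, chi-square = %.2f (df %d), p = %.4g\n",
              x$wilks_lambda, x$chi_sq, x$df, x$p_value))
  cat(sprintf("  correctly classified: %.1f%% original, %.1f%% leave-one-out\n",
              x$accuracy, x$accuracy_loo))
  print(x$confusion_loo)
  invisible(x)
}

#' @export
print.wq_variogram <- function(x, ...) {
  cat(sprintf(
    "%s variogram: nugget %.4g, partial sill %.4g, range %.4g%s\n",
    x$family, x$nugget, x$psill, x$range,
    if (isTRUE(x$fallback)) " (fallback)" else ""))
  invisible(x)
}
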