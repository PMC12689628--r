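#' Pearson correlation with p-value and 95% confidence interval
#'
#' Product-moment correlation; two-sided p-value from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom; 95% CI by the
#' Fisher z-transform, z +/- z_{0.975}/sqrt(n-3), back-transformed.
#' This is the statistic reported alongside editing-vs-phenotype
#' scatter plots.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with
#'   nonzero variance.
#' @return list of class `correlation_result`: `r`, `p`, `ci95`
#'   (length-2), `n`.
#' @export
pearson_ci <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 paired observations")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  ci <- if (n > 3) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  structure(list(r = r, p = p, ci95 = ci, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f, p = %.4g, 95%% CI [%.4f, %.4f], n = %d\n",
              x$r, x$p, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Per-group mean, SD and SEM
#'
#' Sample standard deviation (n-1 denominator); SEM = sd/sqrt(n).
#'
#' @param values numeric vector; @param groups group labels.
#' @return data.frame: group, n, mean, sd, sem.
#' @export
group_summary <- function(values, groups) {
  stop_if_not(length(values) == length(groups),
              "values and groups must have equal length")
  stop_if_not(!anyNA(values), "values must not contain NA")
  g <- factor(groups)
  stop_if_not(all(table(g) >= 1), "every group needs at least one value")
  n <- as.vector(table(g))
  mean_ <- as.vector(tapply(values, g, mean))
  sd_ <- as.vector(tapply(values, g, function(v)
    if (length(v) > 1) stats::sd(v) else NA_real_))
  data.frame(group = levels(g), n = n, mean = mean_, sd = sd_,
             sem = sd_ / sqrt(n))
}
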