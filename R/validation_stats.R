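#' Orthogonal-method vs proteomics regression
#'
#' Ordinary least squares of the orthogonal-quantification ratios on the
#' proteomics ratios. R^2 is the squared Pearson correlation; the p-value
#' is the two-sided test of zero slope.
#'
#' @param pairs data.frame (or list) with columns `proteomics_ratio` (x)
#'   and `orthogonal_ratio` (y); at least 3 finite pairs, x not constant.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regression_validation <- function(pairs) {
  x <- pairs$proteomics_ratio
  y <- pairs$orthogonal_ratio
  if (length(x) < 3L || length(x) != length(y)) {
    stop("need at least 3 paired ratios")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0) stop("zero variance in proteomics ratios")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = length(x))
}

#' Group summary statistics
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return A `summary_stats` list.
#' @export
summary_stats <- function(mean, sd, n) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided two-sample t-test using only group means, SDs
#' and sizes, as needed when comparing published cohort demographics.
#' Default is Student's pooled-variance test; `welch = TRUE` uses the
#' Welch statistic with Satterthwaite degrees of freedom. Two groups with
#' identical means and zero spread are identical by construction; that
#' degenerate case returns p = 1 with `degenerate = TRUE`.
#'
#' @param a,b [summary_stats()] objects (or lists with `mean`, `sd`, `n`).
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `df`, `p_value`, `welch`, `degenerate`.
#' @export
summary_ttest <- function(a, b, welch = FALSE) {
  a <- summary_stats(a$mean, a$sd, a$n)
  b <- summary_stats(b$mean, b$sd, b$n)
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) {
      return(list(t = 0, df = a$n + b$n - 2L, p_value = 1,
                  welch = welch, degenerate = TRUE))
    }
    return(list(t = Inf * sign(a$mean - b$mean), df = a$n + b$n - 2L,
                p_value = 0, welch = welch, degenerate = TRUE))
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (welch) {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       welch = welch, degenerate = FALSE)
}
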