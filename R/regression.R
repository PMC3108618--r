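#' Polynomial least-squares regression with overall F test
#'
#' Fits \eqn{y} on \eqn{x, x^2, \ldots, x^{degree}} (raw polynomial terms)
#' with an intercept and reports the overall F test against the
#' intercept-only model, with \eqn{(df_1, df_2) = (degree, n - degree - 1)},
#' and \eqn{R^2}. A quadratic fit at \eqn{n = 70} therefore has F degrees
#' of freedom \eqn{(2, 67)}.
#'
#' @param y outcome vector.
#' @param x predictor vector (no missing values).
#' @param degree polynomial degree (default 1).
#' @return Object of class \code{regression_result}: \code{coefficients},
#'   \code{f}, \code{df1}, \code{df2}, \code{p}, \code{r2}, \code{n}, and
#'   the underlying \code{lm} fit.
#' @export
ols_poly <- function(y, x, degree = 1L) {
  if (anyNA(y) || anyNA(x)) stop("missing values not supported")
  n <- length(y)
  if (length(x) != n) stop("x and y lengths differ")
  if (n <= degree + 1L) stop("need n > degree + 1")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(coefficients = unname(stats::coef(fit)),
                 f = unname(fstat[1L]), df1 = unname(fstat[2L]),
                 df2 = unname(fstat[3L]),
                 p = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                               lower.tail = FALSE),
                 r2 = sm$r.squared, n = n, lm = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Polynomial OLS (degree %d, n = %d): F(%d, %d) = %.4g, p = %.3g, R^2 = %.3f\n",
              x$df1, x$n, x$df1, x$df2, x$f, x$p, x$r2))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Equal-variance two-sample t test with \eqn{df = n_1 + n_2 - 2} (so 70
#' treatment webs against 10 controls give df = 78) and a two-sided
#' p-value.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return Object of class \code{t_test_result}: \code{t}, \code{df},
#'   \code{p}, group \code{means} and \code{n}.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, means = c(mean(a), mean(b)),
                 n = c(length(a), length(b))),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Two-sample t test (pooled): t = %.3f, df = %d, p = %.3g\n",
              x$t, x$df, x$p))
  cat(sprintf("  means %.3f (n = %d) vs %.3f (n = %d)\n",
              x$means[1L], x$n[1L], x$means[2L], x$n[2L]))
  invisible(x)
}
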