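#' Covariance tables
#'
#' A covariance table pairs a labeled sample covariance matrix \eqn{S} with
#' its sample size \eqn{N}. \code{read_covariance} reads a labeled square
#' CSV whose leading comment lines may carry the sample size
#' (\code{# N = 70}); \code{write_covariance} writes that format.
#'
#' @param S symmetric positive-definite matrix with dimnames.
#' @param N sample size (must exceed the number of variables).
#' @return An object of class \code{covariance_table}: list with \code{S}
#'   and \code{N}.
#' @export
covariance_table <- function(S, N) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("S must have identical row and column names")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S is not symmetric")
  S <- (S + t(S)) / 2
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("S is not positive definite")
  N <- as.integer(N)
  if (N < ncol(S) + 1L)
    stop("N must be at least the number of variables + 1")
  structure(list(S = S, N = N), class = "covariance_table")
}

#' @rdname covariance_table
#' @param path CSV file path.
#' @param N_override sample size, overriding any header comment.
#' @export
read_covariance <- function(path, N_override = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  N <- N_override
  if (is.null(N)) {
    m <- regmatches(hdr, regexpr("N\\s*=\\s*[0-9]+", hdr))
    if (!length(m)) stop("no sample size: pass N_override or add '# N = ...'")
    N <- as.integer(sub(".*=\\s*", "", m[[1L]]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  rownames(S) <- as.character(df[[1L]])
  covariance_table(S, N)
}

#' @rdname covariance_table
#' @param ct a \code{covariance_table}.
#' @export
write_covariance <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N = %d", ct$N), con)
  df <- data.frame(variable = rownames(ct$S), as.data.frame(ct$S),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Map unconstrained optimizer parameters u to natural parameters theta.
# Paths are unconstrained; variances are log-transformed to enforce
# positivity; each free covariance is parameterized through a tanh
# correlation so the exogenous block stays positive definite.
.u_to_theta <- function(spec, u) {
  nb <- nrow(spec$paths)
  p <- length(spec$vars)
  nc <- nrow(spec$covs)
  theta <- numeric(nb + p + nc)
  theta[seq_len(nb)] <- u[seq_len(nb)]
  v <- exp(u[nb + seq_len(p)])
  theta[nb + seq_len(p)] <- v
  names(v) <- spec$vars
  for (i in seq_len(nc)) {
    rho <- tanh(u[nb + p + i])
    theta[nb + p + i] <- rho * sqrt(v[[spec$covs$var1[i]]] *
                                      v[[spec$covs$var2[i]]])
  }
  names(theta) <- .param_names(spec)
  theta
}

.fml <- function(spec, theta, S, logdetS) {
  Sigma <- implied_covariance(spec, theta)
  chl <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chl)) return(.Machine$double.xmax / 1e6)
  logdet <- 2 * sum(log(diag(chl)))
  tr <- sum(diag(chol2inv(chl) %*% S))
  logdet + tr - logdetS - ncol(S)
}

#' Fit a path model to a sample covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML}(\theta) = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) -
#' \ln|S| - p} by quasi-Newton optimization on unconstrained parameters
#' (variances log-transformed, free covariances through a tanh
#' correlation). The test statistic is \eqn{\chi^2 = (N-1) F_{ML}(\hat\theta)};
#' standard errors come from the inverse Hessian of
#' \eqn{(N-1)/2 \cdot F_{ML}} via the delta method, with Wald \eqn{z}
#' p-values. Start values: 0.5 for each path, sample variances for
#' variances, 0 covariances; a deterministic schedule of perturbed restarts
#' handles non-convergence. Non-convergence after all restarts is flagged
#' in the result, never silent.
#'
#' @param spec a \code{path_model}.
#' @param cov a \code{covariance_table} covering all of \code{spec$vars}.
#' @param restarts maximum number of perturbed restarts (default 5).
#' @param reltol optimizer relative tolerance.
#' @return An object of class \code{path_fit}: estimates table (estimate,
#'   SE, z, p per parameter), \code{chisq}, \code{df}, \code{p},
#'   \code{converged}, \code{admissible}, \code{Sigma} (fitted), \code{S},
#'   \code{N}, \code{spec}, \code{fml}.
#' @export
fit_ml <- function(spec, cov, restarts = 5L, reltol = 1e-12) {
  stopifnot(inherits(spec, "path_model"), inherits(cov, "covariance_table"))
  missing <- setdiff(spec$vars, rownames(cov$S))
  if (length(missing))
    stop("covariance table lacks variable(s): ",
         paste(missing, collapse = ", "))
  S <- cov$S[spec$vars, spec$vars, drop = FALSE]
  N <- cov$N
  p <- length(spec$vars)
  df <- degrees_of_freedom(spec)
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1L]
  nb <- nrow(spec$paths)
  nc <- nrow(spec$covs)
  obj <- function(u) .fml(spec, .u_to_theta(spec, u), S, logdetS)

  u0 <- c(rep(0.5, nb), log(diag(S)), rep(0, nc))
  # deterministic perturbation schedule: no RNG involved
  perturb <- list(numeric(length(u0)),
                  c(rep(-1, nb), rep(0, p + nc)),
                  c(rep(0.5, nb), rep(0.3, p), rep(0.2, nc)),
                  c(rep(-0.5, nb), rep(-0.3, p), rep(-0.2, nc)),
                  c(rep(1.5, nb), rep(0.6, p), rep(0.4, nc)),
                  c(rep(0, nb), rep(1, p), rep(0, nc)))
  best <- NULL
  for (i in seq_len(min(restarts + 1L, length(perturb)))) {
    opt <- tryCatch(
      stats::optim(u0 + perturb[[i]], obj, method = "BFGS",
                   control = list(reltol = reltol, maxit = 2000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (best$convergence == 0L) break
  }
  if (is.null(best))
    stop("optimization failed for model ", spec$name)
  converged <- best$convergence == 0L
  u_hat <- best$par
  theta <- .u_to_theta(spec, u_hat)
  fml <- max(best$value, 0)
  chisq <- (N - 1) * fml
  if (chisq < 1e-10) chisq <- max(chisq, 0)
  Sigma <- implied_covariance(spec, theta)
  admissible <- min(eigen(Sigma, symmetric = TRUE,
                          only.values = TRUE)$values) > 0 &&
    all(theta[nb + seq_len(p)] > 0)

  # SEs: inverse Hessian of (N-1)/2 * F_ML in u, delta method to theta
  se <- rep(NA_real_, length(theta))
  H <- tryCatch(stats::optimHess(u_hat, obj), error = function(e) NULL)
  if (!is.null(H)) {
    cov_u <- tryCatch(solve((N - 1) / 2 * H), error = function(e) NULL)
    if (!is.null(cov_u)) {
      eps <- 1e-6
      J <- matrix(0, length(theta), length(u_hat))
      for (j in seq_along(u_hat)) {
        up <- u_hat; up[j] <- up[j] + eps
        um <- u_hat; um[j] <- um[j] - eps
        J[, j] <- (.u_to_theta(spec, up) - .u_to_theta(spec, um)) / (2 * eps)
      }
      v <- diag(J %*% cov_u %*% t(J))
      se <- ifelse(v > 0, sqrt(v), NA_real_)
    }
  }
  z <- theta / se
  est <- data.frame(
    param = .param_names(spec),
    type = c(rep("path", nb), rep("variance", p), rep("covariance", nc)),
    estimate = unname(theta), se = unname(se), z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE)
  structure(list(estimates = est, chisq = chisq, df = df,
                 p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
                     else 1,
                 converged = converged, admissible = admissible,
                 Sigma = Sigma, S = S, N = N, spec = spec, fml = fml),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Path model fit:", x$spec$name, "\n")
  cat(sprintf("  chi-square = %.4g on %d df (p = %.3g), N = %d\n",
              x$chisq, x$df, x$p, x$N))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (!x$admissible) cat("  WARNING: inadmissible solution\n")
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Independence-model baseline fit
#'
#' The null model for the CFI: all covariances fixed at zero, all variances
#' free. Its ML solution is closed-form (fitted variances equal sample
#' variances), giving \eqn{\chi^2_0 = -(N-1)\ln|R|} with \eqn{R} the sample
#' correlation matrix and \eqn{df_0 = p(p-1)/2}.
#'
#' @param cov a \code{covariance_table}.
#' @param vars variables to include (default all).
#' @return List with \code{chisq} and \code{df}.
#' @export
independence_fit <- function(cov, vars = rownames(cov$S)) {
  S <- cov$S[vars, vars, drop = FALSE]
  p <- ncol(S)
  R <- stats::cov2cor(S)
  chisq <- -(cov$N - 1) * determinant(R, logarithm = TRUE)$modulus[1L]
  list(chisq = max(chisq, 0), df = (p * (p - 1L)) %/% 2L)
}

#' Chi-square p-value, CFI and BIC for a fitted model
#'
#' \code{p} is the upper tail of the \eqn{\chi^2_{df}} distribution (1 by
#' convention when df = 0). The Comparative Fit Index uses the clamped
#' non-centrality form
#' \eqn{CFI = 1 - \max(\chi^2 - df, 0) / \max(\chi^2 - df, \chi^2_0 - df_0, 0)},
#' so CFI equals 1 exactly when \eqn{\chi^2 \le df}. The Bayesian
#' information criterion is on the chi-square scale:
#' \eqn{BIC = \chi^2 - df \ln N} (more negative is better).
#'
#' @param chisq,df model chi-square and degrees of freedom.
#' @param null_chisq,null_df independence-model chi-square and df (see
#'   \code{\link{independence_fit}}).
#' @param N sample size.
#' @return List with \code{p}, \code{cfi}, \code{bic}.
#' @export
fit_statistics <- function(chisq, df, null_chisq, null_df, N) {
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  num <- max(chisq - df, 0)
  den <- max(chisq - df, null_chisq - null_df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  list(p = p, cfi = cfi, bic = chisq - df * log(N))
}

#' Standardized coefficients and outcome R-squared
#'
#' Standardized coefficient for a path \eqn{x \to y} is
#' \eqn{\hat\beta \hat\sigma_x / \hat\sigma_y} with model-implied standard
#' deviations; \eqn{R^2} of the outcome is one minus its residual variance
#' over its implied variance.
#'
#' @param fit a \code{path_fit}.
#' @param outcome outcome variable name (default \code{"decomp"}).
#' @return List with \code{standardized} (the estimates table plus a
#'   \code{std_estimate} column) and \code{r2}.
#' @export
standardize_and_r2 <- function(fit, outcome = "decomp") {
  stopifnot(outcome %in% fit$spec$vars)
  sds <- sqrt(diag(fit$Sigma))
  if (any(sds <= 0)) stop("zero implied variance")
  est <- fit$estimates
  est$std_estimate <- est$estimate
  pk <- which(est$type == "path")
  est$std_estimate[pk] <- est$estimate[pk] *
    sds[fit$spec$paths$from] / sds[fit$spec$paths$to]
  vk <- which(est$type == "variance")
  est$std_estimate[vk] <- est$estimate[vk] / sds[fit$spec$vars]^2
  ck <- which(est$type == "covariance")
  if (length(ck))
    est$std_estimate[ck] <- est$estimate[ck] /
      (sds[fit$spec$covs$var1] * sds[fit$spec$covs$var2])
  psi_y <- est$estimate[est$param == sprintf("var(%s)", outcome)]
  r2 <- if (outcome %in% fit$spec$paths$to)
    1 - psi_y / fit$Sigma[outcome, outcome] else 0
  list(standardized = est, r2 = r2)
}

#' Rank fitted path models by BIC
#'
#' Produces a ranking table with the familiar column set: chi-square, df,
#' p, CFI, BIC, delta-BIC from the best model, outcome R-squared, and a
#' strong-support flag for delta-BIC strictly below 6.
#'
#' @param fits list of \code{path_fit} objects (names used as model labels).
#' @param outcome outcome for the \eqn{R^2} column (default
#'   \code{"decomp"}; models lacking it get \code{NA}).
#' @return A data frame sorted by ascending BIC.
#' @export
rank_models <- function(fits, outcome = "decomp") {
  if (!length(fits)) stop("no fits to rank")
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$spec$name, "")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    nullf <- independence_fit(covariance_table(f$S, f$N))
    st <- fit_statistics(f$chisq, f$df, nullf$chisq, nullf$df, f$N)
    r2 <- if (outcome %in% f$spec$vars)
      standardize_and_r2(f, outcome)$r2 else NA_real_
    data.frame(model = nm[i], chisq = f$chisq, df = f$df, p = st$p,
               cfi = st$cfi, bic = st$bic, r2 = r2,
               converged = f$converged, admissible = f$admissible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bic), ]
  out$delta_bic <- out$bic - out$bic[1L]
  out$strong_support <- out$delta_bic < 6
  rownames(out) <- NULL
  out[, c("model", "chisq", "df", "p", "cfi", "bic", "delta_bic", "r2",
          "strong_support", "converged", "admissible")]
}
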