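test_that("fitting a model to its own implied covariance recovers the truth", {
  ct <- chain_cov()
  fit <- fit_ml(chain_spec(), ct)
  expect_true(fit$converged)
  expect_true(fit$admissible)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$estimates$estimate, chain_theta(), tolerance = 1e-4)

  # saturated model reproduces S exactly: chi-square 0 on 0 df
  sat <- parse_model("x -> y\nx -> m\nm -> y")
  Ssat <- ct$S[c("x", "m", "y"), c("x", "m", "y")]
  fsat <- fit_ml(sat, covariance_table(Ssat, 200))
  expect_equal(fsat$df, 0)
  expect_lt(fsat$chisq, 1e-6)
  expect_equal(fsat$p, 1)
  expect_equal(fsat$Sigma, Ssat, tolerance = 1e-5)
})

test_that("the optimizer matches a refined grid search of the discrepancy on a 3-variable model", {
  # perturbed covariance so the minimum is not at the generating values
  set.seed(21)
  S <- implied_covariance(chain_spec(), chain_theta())
  E <- matrix(stats::rnorm(9, sd = 0.05), 3)
  S <- S + (E + t(E)) / 2
  diag(S) <- diag(S) + 0.05
  ct <- covariance_table(S, 100)
  fit <- fit_ml(chain_spec(), ct)

  # independent oracle: iteratively refined full-factorial grid over
  # (b1, b2, log phi_x, log psi_m, log psi_y), with the implied
  # covariance written out by hand from the path-tracing rules
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  fml <- function(par) {
    b1 <- par[1]; b2 <- par[2]
    phi <- exp(par[3]); pm <- exp(par[4]); py <- exp(par[5])
    vm <- b1^2 * phi + pm
    Sg <- matrix(c(phi,       b1 * phi,  b1 * b2 * phi,
                   b1 * phi,  vm,        b2 * vm,
                   b1 * b2 * phi, b2 * vm, b2^2 * vm + py), 3, 3)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S)) - logdetS - 3
  }
  center <- c(0, 0, 0, 0, 0)
  width <- c(4, 4, 5, 5, 5)
  for (step in 1:12) {
    grids <- lapply(1:5, function(j)
      seq(center[j] - width[j] / 2, center[j] + width[j] / 2, length.out = 7))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, fml)
    center <- pts[which.min(vals), ]
    width <- width / 2.6
  }
  grid_theta <- c(center[1], center[2], exp(center[3]), exp(center[4]),
                  exp(center[5]))
  expect_equal(unname(fit$estimates$estimate), unname(grid_theta),
               tolerance = 1e-3)
  expect_equal(fit$fml, fml(center), tolerance = 1e-6)
})

test_that("the chi-square is invariant to rescaling any variable of S", {
  ct <- chain_cov()
  set.seed(4)
  S <- ct$S + diag(0.3, 3)  # move off the exact solution
  base <- fit_ml(chain_spec(), covariance_table(S, 100))$chisq
  for (v in c("x", "m", "y")) {
    S2 <- S
    S2[v, ] <- S2[v, ] * 3.7
    S2[, v] <- S2[, v] * 3.7
    chi2 <- fit_ml(chain_spec(), covariance_table(S2, 100))$chisq
    expect_equal(chi2, base, tolerance = 1e-5)
  }
})

test_that("the independence baseline matches an explicit zero-covariance fit", {
  ct <- chain_cov(70)
  S <- ct$S + diag(0.2, 3)
  ct2 <- covariance_table(S, 70)
  closed <- independence_fit(ct2)
  spec0 <- path_model(rownames(S), data.frame(from = character(0),
                                              to = character(0)))
  free <- fit_ml(spec0, ct2)
  expect_equal(closed$chisq, free$chisq, tolerance = 1e-5)
  expect_equal(closed$df, free$df)
})

test_that("fit statistics reproduce the published BIC arithmetic and clamp the CFI", {
  # chi-square 17.78 on 19 df at N = 70: BIC = 17.78 - 19 ln 70
  st <- fit_statistics(17.78, 19, 100, 28, 70)
  expect_equal(round(st$bic, 2), -62.94)
  expect_equal(st$cfi, 1)  # chisq <= df

  st2 <- fit_statistics(1.73, 1, 100, 3, 70)
  expect_equal(round(st2$bic, 2), -2.52)
  expect_lt(st2$cfi, 1)

  # df = 0: p reported as 1 by convention
  expect_equal(fit_statistics(0, 0, 10, 3, 70)$p, 1)
})

test_that("CFI equals 1 exactly when the chi-square is at most its df", {
  set.seed(31)
  for (i in 1:50) {
    chisq <- stats::rchisq(1, df = 5)
    df <- sample(1:10, 1)
    st <- fit_statistics(chisq, df, chisq + 50, 2, 70)
    expect_equal(st$cfi == 1, chisq <= df)
  }
})

test_that("standardized coefficients and R2 follow their closed forms", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  fit <- fit_ml(parse_model("x -> y"), covariance_table(S, 100))
  sr <- standardize_and_r2(fit, outcome = "y")
  expect_equal(sr$standardized$std_estimate[1], 0.6, tolerance = 1e-5)
  expect_equal(sr$r2, 0.36, tolerance = 1e-5)

  # no paths into the outcome: R2 = 0
  fit0 <- fit_ml(path_model(c("x", "y"),
                            data.frame(from = character(0),
                                       to = character(0))),
                 covariance_table(S, 100))
  expect_equal(standardize_and_r2(fit0, "y")$r2, 0)
})

test_that("model ranking orders by BIC with a strict delta-BIC support threshold", {
  mk <- function(name, chisq, df) {
    spec <- structure(list(vars = c("x", "y"),
                           paths = data.frame(from = "x", to = "y"),
                           covs = data.frame(var1 = character(0),
                                             var2 = character(0)),
                           name = name), class = "path_model")
    S <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
    structure(list(estimates = data.frame(
      param = c("x->y", "var(x)", "var(y)"),
      type = c("path", "variance", "variance"),
      estimate = c(0.3, 1, 0.91), se = NA, z = NA, p = NA),
      chisq = chisq, df = df, p = NA, converged = TRUE,
      admissible = TRUE, Sigma = S, S = S, N = 70,
      spec = spec, fml = chisq / 69), class = "path_fit")
  }
  # published pair: -62.94 and -50.75 give delta 12.19
  fits <- list(a = mk("a", 17.78, 19), b = mk("b", 17.23, 16))
  rk <- rank_models(fits, outcome = "y")
  expect_equal(rk$model, c("a", "b"))
  expect_equal(round(rk$bic, 2), c(-62.94, -50.75))
  # the printed delta is the difference of the rounded BICs
  expect_equal(diff(round(rk$bic, 2)), 12.19)
  expect_equal(rk$delta_bic[1], 0)
  expect_equal(rk$delta_bic[2], diff(rk$bic))

  # threshold is strict: 5.9 supported, 6.0 not
  ln70 <- log(70)
  f2 <- list(best = mk("best", 10, 10),
             near = mk("near", 10 + 5.9, 10),
             far = mk("far", 10 + 6.0, 10))
  rk2 <- rank_models(f2, outcome = "y")
  expect_equal(rk2$strong_support, c(TRUE, TRUE, FALSE))
})

test_that("covariance tables round-trip through CSV with their sample size", {
  ct <- chain_cov(70)
  f <- withr::local_tempfile(fileext = ".csv")
  write_covariance(ct, f)
  back <- read_covariance(f)
  expect_equal(back$N, 70L)
  expect_equal(back$S, ct$S, tolerance = 1e-12)
  expect_error(read_covariance(f, N_override = 2), "at least")

  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(covariance_table(bad, 70), "positive definite")
})

test_that("fit errors name missing variables and degenerate inputs", {
  ct <- chain_cov()
  sp <- parse_model("x -> z")
  expect_error(fit_ml(sp, ct), "lacks variable")
})
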