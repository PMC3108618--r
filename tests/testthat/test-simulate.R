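test_that("simulation is reproducible and respects the design's compositions", {
  cfg <- generative_config()
  des <- suppressMessages(sample_design(sarracenia_pool(), sarracenia_web(),
                                        seed = 77))
  d1 <- suppressMessages(simulate_experiment(des, cfg, seed = 5))
  d2 <- suppressMessages(simulate_experiment(des, cfg, seed = 5))
  expect_identical(d1, d2)
  d3 <- suppressMessages(simulate_experiment(des, cfg, seed = 6))
  expect_false(identical(d1$decomp, d3$decomp))

  # absent taxa have abundance zero unless contaminated
  cons <- consumers(sarracenia_pool())
  for (i in seq_len(nrow(d1))) {
    absent <- setdiff(cons, strsplit(d1$composition[i], ";")[[1]])
    expect_true(all(d1[i, absent] == 0))
  }
  expect_true(all(d1$decomp >= 0 & d1$decomp <= 100))
  expect_true(all(d1$antmass > 0))
})

test_that("decomposition clipping is rare under the default configuration", {
  cfg <- generative_config()
  des <- full_web_design(2000L)
  dat <- suppressMessages(simulate_experiment(des, cfg, seed = 42,
                                              compute_td = FALSE))
  expect_lt(attr(dat, "clipped") / nrow(dat), 0.01)
})

test_that("the noise-free limit gives an exact linear decomposition surface", {
  cfg <- generative_config(resid_sd = c(rotifer = 1e-3, protozoa = 1e-3,
                                        decomp = 1e-3))
  dat <- suppressMessages(simulate_experiment(full_web_design(200L), cfg,
                                              seed = 8, compute_td = FALSE))
  ct <- suppressWarnings(sample_covariance(
    dat, generating_spec()$vars, standardize = TRUE))
  fit <- fit_ml(generating_spec(), ct)
  expect_gt(standardize_and_r2(fit)$r2, 0.999)
})

test_that("removing mosquito and midge lowers decomposition by the closed-form cascade effect", {
  cfg <- generative_config()
  cons <- consumers(sarracenia_pool())
  both <- full_web_design(1000L)
  neither <- both
  neither$composition <- paste(setdiff(cons, c("mosquito", "midge")),
                               collapse = ";")
  neither$richness <- 7L
  d_with <- suppressMessages(simulate_experiment(both, cfg, seed = 1,
                                                 compute_td = FALSE))
  d_without <- suppressMessages(simulate_experiment(neither, cfg, seed = 2,
                                                    compute_td = FALSE))
  observed <- mean(d_with$decomp) - mean(d_without$decomp)

  # closed form: with the taxa absent, their standardized abundances sit at
  # -mu/sd; the shift propagates along midge -> decomp and the cascade
  # mosquito -> protozoa -> decomp (the mosquito -> rotifer -> protozoa leg
  # is inert because rotifer -> protozoa is zero under defaults)
  b <- cfg$coefficients
  z_mosq <- -cfg$baseline_mean[["mosquito"]] / cfg$baseline_sd[["mosquito"]]
  z_midge <- -cfg$baseline_mean[["midge"]] / cfg$baseline_sd[["midge"]]
  expected <- -cfg$decomp_sd *
    (b[["midge->decomp"]] * z_midge +
       b[["protozoa->decomp"]] * b[["mosquito->protozoa"]] * z_mosq)
  expect_gt(observed, 0)
  expect_equal(observed, expected, tolerance = 0.12)
})

test_that("sample covariances are symmetric, unbiased-scaled, and flag degeneracy", {
  cfg <- generative_config()
  dat <- suppressMessages(simulate_experiment(full_web_design(50L), cfg,
                                              seed = 3, compute_td = FALSE))
  ct <- sample_covariance(dat, c("mosquito", "midge", "decomp"))
  expect_equal(ct$S, t(ct$S))
  expect_true(all(eigen(ct$S, only.values = TRUE)$values > -1e-10))
  expect_equal(ct$N, 50L)
  # divisor N - 1: matches stats::var on the same transformed column
  expect_equal(ct$S["decomp", "decomp"], stats::var(dat$decomp))

  two <- dat[c(1, 1), ]
  expect_warning(z <- sample_covariance(two, c("mosquito", "decomp")),
                 "constant")
  expect_true(all(z$S == 0))
})

test_that("the long-run covariance of full webs matches the generating structural model", {
  cfg <- generative_config()
  spec <- generating_spec()
  dat <- suppressMessages(simulate_experiment(full_web_design(40000L), cfg,
                                              seed = 13, compute_td = FALSE))
  ct <- sample_covariance(dat, spec$vars, standardize = TRUE)
  Sigma0 <- implied_covariance(spec, true_theta(cfg, spec))
  expect_equal(ct$S[spec$vars, spec$vars], Sigma0, tolerance = 0.04,
               ignore_attr = TRUE)
})

test_that("simulated TD tracks final species richness tightly", {
  cfg <- generative_config()
  des <- suppressMessages(sample_design(sarracenia_pool(), sarracenia_web(),
                                        seed = 19))
  dat <- suppressMessages(simulate_experiment(des, cfg, seed = 19))
  expect_gt(stats::cor(dat$td_raw, dat$richness_final,
                       method = "spearman"), 0.7)
  # contamination: microflagellates establish in most webs
  expect_gt(mean(dat$microflagellates > 0), 0.75)
  expect_lt(mean(dat$cyclidium > 0), 0.3)
})

test_that("parameter recovery reports near-unbiased estimates for the generating model", {
  cfg <- generative_config()
  rec <- parameter_recovery(cfg, full_web_design(70L),
                            build_paper_models()[["indirect_full_web_antmass"]],
                            n_reps = 40L, seed = 101)
  expect_gt(rec$n_converged, 35)
  expect_true(all(abs(rec$params$bias) < 0.05))
  expect_true(all(rec$params$rmse < 0.25))
  expect_equal(rec$params$true[rec$params$param == "midge->decomp"], 0.5)
})

test_that("an invalid configuration or design is rejected", {
  expect_error(generative_config(resid_sd = c(rotifer = -1, protozoa = 1,
                                              decomp = 1)))
  cfg <- generative_config()
  bad <- data.frame(web_id = 1, richness = 1, composition = "dragonfly")
  expect_error(suppressMessages(simulate_experiment(bad, cfg)),
               "not in the interaction matrix pool")
})
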