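#' Configuration of the synthetic experiment generator
#'
#' The generator draws per-web final abundances from the linear structural
#' equation system that the path analysis assumes, on the
#' \eqn{\log_{10}(N+1)} scale. Coefficients are on the standardized
#' (z-score) scale, with z-scores defined against fixed per-taxon baseline
#' means and standard deviations, so every structural coefficient is
#' exactly the path coefficient a correctly specified model should recover.
#' Default truth encodes the qualitative structure reported for the system:
#' an active trophic cascade (mosquito suppresses protozoa, protozoa
#' suppress bacterial decomposition), a positive midge shredding effect, a
#' negative initial-ant-mass effect, a negative mosquito effect on
#' rotifers, and inert copepod and mite paths. Coefficient magnitudes are
#' configuration values, not estimates taken from any dataset. Baseline
#' abundances are order-of-magnitude values for 10 ml of pitcher fluid.
#'
#' @param coefficients named numeric vector of structural coefficients,
#'   names \code{"from->to"}; unlisted paths of the full system default to 0.
#' @param resid_sd named residual standard deviations (z-scale) for the
#'   endogenous variables \code{rotifer}, \code{protozoa}, \code{decomp}.
#' @param baseline_mean,baseline_sd named \eqn{\log_{10}(N+1)}-scale
#'   baselines per taxon (protozoa is the summed cultured-protozoan pool).
#' @param richness_slopes optional named per-species effect of initial
#'   richness (z-scale) on the species' abundance when present; default 0
#'   (richness-abundance coupling then arises from the combinatorial
#'   design alone).
#' @param antmass_mean,antmass_sd initial ant mass distribution in mg,
#'   truncated at 0.
#' @param decomp_mean,decomp_sd location and scale (percent mass lost)
#'   mapping the structural z-score of decomposition to the percent scale.
#' @param contamination named probabilities per web that a contaminant
#'   taxon (microflagellates, cyclidium, peranema) establishes.
#' @return A list of class \code{generative_config}.
#' @export
generative_config <- function(
    coefficients = c("mosquito->rotifer" = -0.4,
                     "mosquito->protozoa" = -0.5,
                     "copepod->protozoa" = 0,
                     "rotifer->protozoa" = 0,
                     "protozoa->decomp" = -0.4,
                     "midge->decomp" = 0.5,
                     "mite->decomp" = 0,
                     "antmass->decomp" = -0.3,
                     "mosquito->decomp" = 0,
                     "copepod->decomp" = 0,
                     "rotifer->decomp" = 0),
    resid_sd = c(rotifer = 0.9, protozoa = 0.8, decomp = 0.7),
    baseline_mean = c(mosquito = 0.8, midge = 0.8, mite = 0.5,
                      copepod = 0.5, rotifer = 1.7, protozoa = 3.0,
                      microflagellates = 2.0, cyclidium = 1.0,
                      peranema = 1.0),
    baseline_sd = c(mosquito = 0.3, midge = 0.3, mite = 0.3,
                    copepod = 0.3, rotifer = 0.5, protozoa = 0.5,
                    microflagellates = 0.5, cyclidium = 0.4,
                    peranema = 0.4),
    richness_slopes = NULL,
    antmass_mean = 25, antmass_sd = 8,
    decomp_mean = 60, decomp_sd = 14,
    contamination = c(microflagellates = 0.9, cyclidium = 0.1,
                      peranema = 0.1)) {
  stopifnot(all(resid_sd > 0), all(baseline_sd > 0),
            antmass_sd > 0, decomp_sd > 0,
            all(contamination >= 0 & contamination <= 1))
  cfg <- list(coefficients = coefficients, resid_sd = resid_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              richness_slopes = richness_slopes,
              antmass_mean = antmass_mean, antmass_sd = antmass_sd,
              decomp_mean = decomp_mean, decomp_sd = decomp_sd,
              contamination = contamination)
  # the implied covariance of the full structural system must be admissible
  spec <- generating_spec()
  theta <- true_theta(cfg, spec)
  ev <- eigen(implied_covariance(spec, theta), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("configuration implies a non-positive-definite covariance")
  structure(cfg, class = "generative_config")
}

#' @rdname generative_config
#' @details \code{generating_spec} returns the combined full food-web model
#'   with ant mass — the structural system every candidate model restricts.
#' @export
generating_spec <- function() {
  build_paper_models()[["combined_full_web_antmass"]]
}

#' @rdname generative_config
#' @param config a \code{generative_config}.
#' @param spec a \code{path_model} whose free parameters should be filled
#'   with the generator's true values (z-scale): structural coefficients
#'   for paths, residual/exogenous variances, zero exogenous covariances.
#' @return \code{true_theta}: named numeric vector conformable with
#'   \code{spec}.
#' @export
true_theta <- function(config, spec) {
  beta <- function(from, to) {
    key <- paste0(from, "->", to)
    if (key %in% names(config$coefficients)) config$coefficients[[key]] else 0
  }
  b <- mapply(beta, spec$paths$from, spec$paths$to)
  v <- vapply(spec$vars, function(vv) {
    if (vv %in% spec$paths$to) {
      sd <- if (vv %in% names(config$resid_sd)) config$resid_sd[[vv]] else 1
      sd^2
    } else 1  # exogenous z-scores have unit variance
  }, numeric(1))
  theta <- c(b, v, rep(0, nrow(spec$covs)))
  names(theta) <- .param_names(spec)
  theta
}

# Interaction matrix extended with the contaminant taxa, whose trophic
# profile mirrors a cultured protozoan (prey of mosquito and copepod,
# grazers of bacteria and yeast).
.extended_matrix <- function(m, contaminants) {
  if (!length(contaminants)) return(m)
  base <- unclass(m)
  n <- nrow(base)
  k <- length(contaminants)
  out <- matrix(0L, n + k, n + k,
                dimnames = list(c(rownames(base), contaminants),
                                c(rownames(base), contaminants)))
  out[1:n, 1:n] <- base
  for (ct in contaminants) {
    prof <- base["protozoa1", ]
    out[ct, colnames(base)] <- prof
    out[colnames(base), ct] <- prof
  }
  pool <- attr(m, "pool")
  pool2 <- species_pool(c(pool$taxon, contaminants),
                        c(pool$role, rep("consumer", k)))
  interaction_matrix(out, pool = pool2)
}

#' Simulate a synthetic decomposition experiment
#'
#' For each web of the design, draws exogenous \eqn{\log_{10}(N+1)}
#' abundances for the present taxa (absent taxa have abundance 0),
#' propagates the endogenous variables (rotifer, summed protozoa,
#' decomposition) through the linear structural equations with Gaussian
#' residuals, draws an initial ant mass (truncated normal, mg), computes
#' decomposition as percent mass lost (clipped to [0, 100], clip events
#' counted), applies contaminant establishment, and recomputes final
#' richness and final trophic diversity from the final community
#' composition including contaminants.
#'
#' @param design a \code{design_table} (needs columns \code{richness} and
#'   \code{composition}).
#' @param config a \code{generative_config}.
#' @param m interaction matrix for final-TD computation; default
#'   \code{\link{sarracenia_web}()}.
#' @param seed optional integer seed.
#' @param compute_td compute final TD per web (the slow step; disable for
#'   large calibration runs that do not use TD).
#' @return A data frame of class \code{experiment_dataset}: identifiers,
#'   per-taxon final counts, summed protozoan count, \code{antmass} (mg),
#'   \code{decomp} (percent mass lost), \code{richness_final},
#'   \code{td_raw}/\code{td_std} (when computed). Attribute
#'   \code{clipped} counts decomposition clip events.
#' @export
simulate_experiment <- function(design, config, m = sarracenia_web(),
                                seed = NULL, compute_td = TRUE) {
  stopifnot(inherits(config, "generative_config"),
            all(c("richness", "composition") %in% names(design)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  comp <- strsplit(ifelse(is.na(design$composition), "",
                          design$composition), ";", fixed = TRUE)
  cons <- consumers(attr(m, "pool"))
  unknown <- setdiff(unique(unlist(comp)), cons)
  if (length(unknown))
    stop("design taxa not in the interaction matrix pool: ",
         paste(unknown, collapse = ", "))
  pres <- sapply(cons, function(tx)
    vapply(comp, function(s) tx %in% s, logical(1)))
  pres <- matrix(pres, nrow = n, dimnames = list(NULL, cons))
  prot_taxa <- grep("^protozoa", cons, value = TRUE)
  pres_prot <- rowSums(pres[, prot_taxa, drop = FALSE]) > 0

  mu <- config$baseline_mean
  sdv <- config$baseline_sd
  bb <- function(from, to) {
    key <- paste0(from, "->", to)
    if (key %in% names(config$coefficients)) config$coefficients[[key]] else 0
  }
  rich0 <- design$richness
  slope <- function(tx) {
    if (is.null(config$richness_slopes)) return(0)
    if (tx %in% names(config$richness_slopes))
      config$richness_slopes[[tx]] else 0
  }
  zr <- (rich0 - mean(rich0)) / max(stats::sd(rich0), 1e-9)

  # exogenous consumers: log-abundance mu + sd*(slope*z_rich + eps) if present
  xcol <- function(tx, present) {
    x <- ifelse(present,
                mu[[tx]] + sdv[[tx]] *
                  (slope(tx) * zr + stats::rnorm(n)), 0)
    pmax(x, 0)
  }
  x_mosq <- xcol("mosquito", pres[, "mosquito"])
  x_midge <- xcol("midge", pres[, "midge"])
  x_mite <- xcol("mite", pres[, "mite"])
  x_cope <- xcol("copepod", pres[, "copepod"])
  z <- function(x, tx) (x - mu[[tx]]) / sdv[[tx]]
  z_mosq <- z(x_mosq, "mosquito")
  z_midge <- z(x_midge, "midge")
  z_mite <- z(x_mite, "mite")
  z_cope <- z(x_cope, "copepod")

  # endogenous: rotifer <- mosquito; protozoa <- mosquito, copepod, rotifer
  z_rot_s <- bb("mosquito", "rotifer") * z_mosq +
    config$resid_sd[["rotifer"]] * stats::rnorm(n)
  x_rot <- ifelse(pres[, "rotifer"],
                  pmax(mu[["rotifer"]] + sdv[["rotifer"]] * z_rot_s, 0), 0)
  z_rot <- z(x_rot, "rotifer")
  z_prot_s <- bb("mosquito", "protozoa") * z_mosq +
    bb("copepod", "protozoa") * z_cope +
    bb("rotifer", "protozoa") * z_rot +
    config$resid_sd[["protozoa"]] * stats::rnorm(n)
  x_prot <- ifelse(pres_prot,
                   pmax(mu[["protozoa"]] + sdv[["protozoa"]] * z_prot_s, 0), 0)
  z_prot <- z(x_prot, "protozoa")

  antmass <- config$antmass_mean + config$antmass_sd * stats::rnorm(n)
  bad <- which(antmass <= 0)
  while (length(bad)) {  # truncation at zero
    antmass[bad] <- config$antmass_mean +
      config$antmass_sd * stats::rnorm(length(bad))
    bad <- which(antmass <= 0)
  }
  z_ant <- (antmass - config$antmass_mean) / config$antmass_sd

  z_dec <- bb("protozoa", "decomp") * z_prot +
    bb("midge", "decomp") * z_midge +
    bb("mite", "decomp") * z_mite +
    bb("antmass", "decomp") * z_ant +
    bb("mosquito", "decomp") * z_mosq +
    bb("copepod", "decomp") * z_cope +
    bb("rotifer", "decomp") * z_rot +
    config$resid_sd[["decomp"]] * stats::rnorm(n)
  decomp_raw <- config$decomp_mean + config$decomp_sd * z_dec
  decomp <- pmin(pmax(decomp_raw, 0), 100)
  clipped <- sum(decomp != decomp_raw)
  if (clipped > 0)
    message(clipped, " decomposition value(s) clipped to [0, 100]")

  # contamination
  cts <- names(config$contamination)
  contam <- sapply(cts, function(ct)
    stats::runif(n) < config$contamination[[ct]])
  contam <- matrix(contam, nrow = n, dimnames = list(NULL, cts))
  x_ct <- sapply(cts, function(ct)
    ifelse(contam[, ct], pmax(mu[[ct]] + sdv[[ct]] * stats::rnorm(n), 0), 0))
  x_ct <- matrix(x_ct, nrow = n, dimnames = list(NULL, cts))

  back <- function(x) round(pmax(10^x - 1, 0))
  counts_prot_total <- back(x_prot)
  out <- data.frame(
    web_id = if ("web_id" %in% names(design)) design$web_id else seq_len(n),
    richness_initial = rich0,
    composition = vapply(comp, paste, "", collapse = ";"))
  out$mosquito <- back(x_mosq)
  out$midge <- back(x_midge)
  out$mite <- back(x_mite)
  out$copepod <- back(x_cope)
  out$rotifer <- back(x_rot)
  # split the summed protozoan count evenly among present cultured taxa
  for (ptx in prot_taxa) out[[ptx]] <- 0
  for (i in seq_len(n)) {
    pp <- prot_taxa[pres[i, prot_taxa]]
    if (length(pp))
      for (ptx in pp) out[i, ptx] <- round(counts_prot_total[i] / length(pp))
  }
  out$protozoa <- counts_prot_total
  for (ct in cts) out[[ct]] <- back(x_ct[, ct])
  out$antmass <- antmass
  out$decomp <- decomp
  # exact transformed abundances; counts above are their rounded
  # back-transforms, kept for file realism
  out$log_mosquito <- x_mosq
  out$log_midge <- x_midge
  out$log_mite <- x_mite
  out$log_copepod <- x_cope
  out$log_rotifer <- x_rot
  out$log_protozoa <- x_prot
  for (ct in cts) out[[paste0("log_", ct)]] <- x_ct[, ct]

  final_present <- cbind(pres, contam) &
    as.matrix(out[, c(cons, cts)]) > 0
  out$richness_final <- rowSums(final_present)
  if (compute_td) {
    mx <- .extended_matrix(m, cts)
    key <- apply(final_present, 1L, function(r)
      paste(colnames(final_present)[r], collapse = ";"))
    ukey <- unique(key)
    tds <- vapply(ukey, function(k) {
      tx <- strsplit(k, ";", fixed = TRUE)[[1L]]
      trophic_diversity(mx, tx)$raw
    }, numeric(1), USE.NAMES = FALSE)
    out$td_raw <- tds[match(key, ukey)]
    out$td_std <- if (diff(range(out$td_raw)) > 0)
      standardize_td(out$td_raw) else rep(0, n)
  }
  structure(out, class = c("experiment_dataset", "data.frame"),
            clipped = clipped, config = config)
}

# Transformed model variable matrix: species abundances on the
# log10(N+1) scale (exact simulated values when the dataset carries them,
# otherwise recomputed from counts); antmass, decomp, richness (final)
# and td on their native scales.
.model_frame <- function(data, variables) {
  direct <- c(antmass = "antmass", decomp = "decomp",
              richness = "richness_final", td = "td_std")
  cols <- lapply(variables, function(v) {
    if (v %in% names(direct)) {
      if (!direct[[v]] %in% names(data))
        stop("dataset lacks column ", direct[[v]])
      data[[direct[[v]]]]
    } else if (paste0("log_", v) %in% names(data)) {
      data[[paste0("log_", v)]]
    } else {
      if (!v %in% names(data)) stop("dataset lacks species column ", v)
      log10(data[[v]] + 1)
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- variables
  mat
}

#' Sample covariance of transformed experiment variables
#'
#' Computes the unbiased (divisor \eqn{N-1}) covariance matrix of the
#' selected variables. Species names select \eqn{\log_{10}(N+1)}
#' abundances (\code{"protozoa"} is the summed protozoan pool);
#' \code{"antmass"}, \code{"decomp"}, \code{"richness"} and \code{"td"}
#' select those columns on their native scales. Constant variables are
#' retained with a warning.
#'
#' With \code{standardize = TRUE} each variable is z-scored against the
#' generator's fixed baseline constants (not the sample moments), so the
#' fitted path coefficients estimate the configuration's standardized
#' coefficients directly; this requires the dataset to carry its
#' \code{generative_config} attribute and supports only variables with
#' baselines (species, \code{antmass}, \code{decomp}).
#'
#' @param data an \code{experiment_dataset}.
#' @param variables character vector of variable names.
#' @param standardize z-score by the generator's baseline constants?
#' @return A \code{covariance_table} (unvalidated when degenerate).
#' @export
sample_covariance <- function(data, variables, standardize = FALSE) {
  if (nrow(data) < 2L) stop("need at least 2 webs")
  mat <- .model_frame(data, variables)
  if (standardize) {
    config <- attr(data, "config")
    if (is.null(config))
      stop("standardize = TRUE needs the dataset's generative_config")
    for (v in variables) {
      if (v %in% names(config$baseline_mean)) {
        mat[, v] <- (mat[, v] - config$baseline_mean[[v]]) /
          config$baseline_sd[[v]]
      } else if (v == "antmass") {
        mat[, v] <- (mat[, v] - config$antmass_mean) / config$antmass_sd
      } else if (v == "decomp") {
        mat[, v] <- (mat[, v] - config$decomp_mean) / config$decomp_sd
      } else stop("no baseline constants for variable ", v)
    }
  }
  cst <- variables[apply(mat, 2L, function(x) stats::sd(x) == 0)]
  if (length(cst))
    warning("constant variable(s) retained: ", paste(cst, collapse = ", "))
  S <- stats::cov(mat)
  structure(list(S = S, N = nrow(mat)), class = "covariance_table")
}

#' Parameter recovery study for the path-analysis pipeline
#'
#' Repeats simulate -> covariance -> ML fit and summarizes, per free path
#' coefficient, the mean bias, RMSE and 95 percent Wald-interval coverage
#' against the generator's true values. Optionally refits a candidate
#' model set each replicate and reports how often each candidate attains
#' the minimum BIC. Non-convergent replicates are excluded and counted.
#'
#' @param config a \code{generative_config}.
#' @param design design table passed to \code{\link{simulate_experiment}}.
#' @param spec the \code{path_model} to fit (typically the generating
#'   model, or \code{\link{recovery_spec}()} when the design correlates the
#'   exogenous abundances).
#' @param n_reps number of replicates (>= 100 recommended).
#' @param m interaction matrix (only used if the spec needs TD).
#' @param seed integer seed.
#' @param candidates optional named list of \code{path_model}s for
#'   BIC-based model selection per replicate.
#' @return List of class \code{recovery_report}: \code{params} data frame
#'   (true value, mean bias, RMSE, coverage), \code{n_converged},
#'   \code{n_excluded}, and \code{selection} (table of minimum-BIC
#'   winners, when candidates are given).
#' @export
parameter_recovery <- function(config, design, spec, n_reps = 100L,
                               m = sarracenia_web(), seed = NULL,
                               candidates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- true_theta(config, spec)
  pk <- grepl("->", names(truth), fixed = TRUE)
  need_td <- "td" %in% spec$vars
  est <- se <- matrix(NA_real_, n_reps, sum(pk),
                      dimnames = list(NULL, names(truth)[pk]))
  winners <- character(0)
  n_excluded <- 0L
  for (r in seq_len(n_reps)) {
    dat <- suppressMessages(simulate_experiment(design, config, m = m,
                                                compute_td = need_td))
    ct <- suppressWarnings(sample_covariance(dat, spec$vars,
                                             standardize = TRUE))
    fit <- tryCatch(fit_ml(spec, ct), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_excluded <- n_excluded + 1L; next }
    est[r, ] <- fit$estimates$estimate[pk]
    se[r, ] <- fit$estimates$se[pk]
    if (!is.null(candidates)) {
      fits <- lapply(candidates, function(sp)
        tryCatch(fit_ml(sp, suppressWarnings(
          sample_covariance(dat, sp$vars))), error = function(e) NULL))
      fits <- Filter(Negate(is.null), fits)
      if (length(fits)) winners <- c(winners, rank_models(fits)$model[1L])
    }
  }
  ok <- stats::complete.cases(est)
  tr <- truth[pk]
  cover <- colMeans(abs(est[ok, , drop = FALSE] -
                          rep(tr, each = sum(ok))) <=
                      1.96 * se[ok, , drop = FALSE], na.rm = TRUE)
  params <- data.frame(
    param = names(tr), true = unname(tr),
    bias = colMeans(est[ok, , drop = FALSE]) - tr,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(tr, each = sum(ok)))^2)),
    coverage = unname(cover), stringsAsFactors = FALSE)
  rownames(params) <- NULL
  structure(list(params = params, n_converged = sum(ok),
                 n_excluded = n_excluded,
                 selection = if (length(winners)) table(winners) else NULL),
            class = "recovery_report")
}

#' @rdname parameter_recovery
#' @details \code{recovery_spec} augments the indirect full food-web model
#'   with ant mass with free covariances among all exogenous consumer
#'   abundances, for recovery studies on designs whose presence/absence
#'   structure correlates the exogenous variables.
#' @export
recovery_spec <- function() {
  base <- build_paper_models()[["indirect_full_web_antmass"]]
  exo <- c("mosquito", "copepod", "mite", "midge")
  pairs <- utils::combn(exo, 2L)
  covs <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                     stringsAsFactors = FALSE)
  path_model(base$vars, base$paths, covs, name = "recovery")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery:", x$n_converged, "converged replicates (",
      x$n_excluded, "excluded )\n")
  print(x$params, digits = 3)
  if (!is.null(x$selection)) {
    cat("Minimum-BIC winners:\n")
    print(x$selection)
  }
  invisible(x)
}

#' @rdname simulate_experiment
#' @param data an \code{experiment_dataset}.
#' @param path CSV path.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
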