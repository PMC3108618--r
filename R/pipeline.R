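#' Pipeline run configuration
#'
#' Assembles and validates the options for \code{\link{run_pipeline}}.
#' Unknown option names are rejected.
#'
#' @param matrix_path interaction matrix CSV (default: the shipped
#'   reconstruction).
#' @param covariance_path optional covariance CSV; when given the
#'   simulation stage is skipped and models are fitted to this matrix.
#' @param output_dir directory for the output bundle (created if needed).
#' @param seed integer seed recorded in all outputs.
#' @param replicates,levels design dimensions (default 7 and 7).
#' @param metric,linkage,mode,include_basal TD options; \code{metric} and
#'   \code{linkage} default to \code{"auto"}, meaning selection by
#'   cophenetic correlation.
#' @param restarts,tolerance optimizer options for \code{\link{fit_ml}}.
#' @param verbose print stage progress?
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(matrix_path = NULL, covariance_path = NULL,
                       output_dir = tempfile("pitcherwebs_run_"),
                       seed = 1L, replicates = 7L, levels = 7L,
                       metric = "auto", linkage = "auto",
                       mode = "recluster", include_basal = TRUE,
                       restarts = 5L, tolerance = 1e-12,
                       verbose = TRUE) {
  cfg <- list(matrix_path = matrix_path, covariance_path = covariance_path,
              output_dir = output_dir, seed = as.integer(seed),
              replicates = as.integer(replicates),
              levels = as.integer(levels), metric = metric,
              linkage = linkage, mode = mode,
              include_basal = isTRUE(include_basal),
              restarts = as.integer(restarts), tolerance = tolerance,
              verbose = isTRUE(verbose))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of options (keys as in \code{run_config}).
#' @export
read_run_config <- function(path) {
  opts <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(opts), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, opts)
}

.stage <- function(cfg, name, expr) {
  if (cfg$verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: load the interaction matrix, select the TD
#' method by cophenetic correlation, enumerate all webs and their TD, draw
#' the stratified 70-web design, simulate a synthetic experiment (or load a
#' user covariance matrix instead), fit all 32 a priori path models, rank
#' them by BIC, and run the univariate regressions of decomposition on
#' final richness (quadratic) and TD (linear). All outputs are written to
#' \code{output_dir} as CSV/JSON with the seed recorded, and returned
#' invisibly as a list.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return Invisibly, a list with \code{selection}, \code{enumeration},
#'   \code{design}, \code{dataset} (or \code{NULL}), \code{covariance},
#'   \code{ranking}, \code{regressions}, \code{fits}.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  m <- .stage(cfg, "matrix",
              if (is.null(cfg$matrix_path)) sarracenia_web()
              else read_interaction_matrix(cfg$matrix_path,
                                           pool = sarracenia_pool()))
  pool <- attr(m, "pool")
  sel <- .stage(cfg, "method-selection", select_method(m))
  metric <- if (cfg$metric == "auto") attr(sel, "metric") else cfg$metric
  linkage <- if (cfg$linkage == "auto") attr(sel, "linkage") else cfg$linkage
  utils::write.csv(as.data.frame(sel),
                   file.path(cfg$output_dir, "method_selection.csv"),
                   row.names = FALSE)
  enum <- .stage(cfg, "td-enumeration",
                 enumerate_all_webs(pool, m, mode = cfg$mode,
                                    metric = metric, linkage = linkage,
                                    include_basal = cfg$include_basal))
  utils::write.csv(enum, file.path(cfg$output_dir, "td_enumeration.csv"),
                   row.names = FALSE)
  design <- .stage(cfg, "design",
                   sample_design(pool, m, replicates = cfg$replicates,
                                 k = cfg$levels, mode = cfg$mode,
                                 metric = metric, linkage = linkage,
                                 include_basal = cfg$include_basal))
  write_design(design, file.path(cfg$output_dir, "design.csv"))

  dataset <- NULL
  regressions <- NULL
  if (is.null(cfg$covariance_path)) {
    gcfg <- generative_config()
    dataset <- .stage(cfg, "simulate",
                      simulate_experiment(design, gcfg, m = m))
    write_dataset(dataset, file.path(cfg$output_dir, "dataset.csv"))
    vars <- c("mosquito", "copepod", "rotifer", "protozoa", "mite",
              "midge", "antmass", "decomp", "richness", "td",
              paste0("protozoa", 1:4),
              names(gcfg$contamination))
    ct <- .stage(cfg, "covariance",
                 suppressWarnings(sample_covariance(dataset, vars)))
    regressions <- .stage(cfg, "regressions", list(
      richness_quadratic = ols_poly(dataset$decomp,
                                    dataset$richness_final, 2L),
      td_linear = ols_poly(dataset$decomp, dataset$td_std, 1L),
      td_vs_richness = ols_poly(dataset$td_std,
                                dataset$richness_final, 1L)))
  } else {
    if (cfg$verbose) message("[simulate] skipped: covariance input given")
    ct <- .stage(cfg, "covariance", read_covariance(cfg$covariance_path))
  }
  write_covariance(ct, file.path(cfg$output_dir, "covariance.csv"))

  models <- build_paper_models()
  fits <- .stage(cfg, "fit-models", {
    out <- list()
    for (nm in names(models)) {
      sp <- models[[nm]]
      if (!all(sp$vars %in% rownames(ct$S))) next
      sub <- covariance_table(ct$S[sp$vars, sp$vars, drop = FALSE], ct$N)
      out[[nm]] <- fit_ml(sp, sub, restarts = cfg$restarts,
                          reltol = cfg$tolerance)
    }
    out
  })
  ranking <- .stage(cfg, "rank", rank_models(fits))
  utils::write.csv(ranking, file.path(cfg$output_dir, "ranking.csv"),
                   row.names = FALSE)
  meta <- list(seed = cfg$seed, metric = metric, linkage = linkage,
               mode = cfg$mode, include_basal = cfg$include_basal,
               n_models = length(fits))
  if (!is.null(regressions))
    meta$regressions <- lapply(regressions, function(r)
      list(f = r$f, df1 = r$df1, df2 = r$df2, p = r$p, r2 = r$r2))
  jsonlite::write_json(meta, file.path(cfg$output_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(selection = sel, enumeration = enum, design = design,
                 dataset = dataset, covariance = ct, ranking = ranking,
                 regressions = regressions, fits = fits))
}
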