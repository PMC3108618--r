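#' Parse a path-model specification
#'
#' The model DSL has one statement per line: \code{X -> Y} declares a
#' directed path with a free coefficient; \code{X <-> Y} (distinct
#' variables) declares a free exogenous covariance; \code{X <-> X} declares
#' a free variance, which is redundant (every variable always carries
#' exactly one free variance — an exogenous variance or a residual
#' variance), and is accepted for round-tripping. Blank lines and \code{#}
#' comments are ignored. Every unlisted covariance is fixed at zero. The
#' path graph must be acyclic (a recursive model).
#'
#' @param text model text (single string with newlines, or a character
#'   vector of lines).
#' @param name optional model name.
#' @return An object of class \code{path_model}: list with \code{vars}
#'   (topological order), \code{paths} (data frame \code{from}, \code{to}),
#'   \code{covs} (data frame \code{var1}, \code{var2}), \code{name}.
#' @examples
#' parse_model("richness -> midge\nmidge -> decomp\nantmass -> decomp")
#' @export
parse_model <- function(text, name = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  paths <- covs <- list()
  vars <- character(0)
  note <- function(v) vars <<- union(vars, v)
  for (ln in lines) {
    if (grepl("<->", ln, fixed = TRUE)) {
      ab <- trimws(strsplit(ln, "<->", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || any(!nzchar(ab)))
        stop("cannot parse line: ", ln)
      note(ab)
      if (ab[1L] != ab[2L])
        covs[[length(covs) + 1L]] <- sort(ab)
    } else if (grepl("->", ln, fixed = TRUE)) {
      ab <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || any(!nzchar(ab)))
        stop("cannot parse line: ", ln)
      if (ab[1L] == ab[2L]) stop("self-loop: ", ln)
      note(ab)
      paths[[length(paths) + 1L]] <- ab
    } else stop("cannot parse line: ", ln)
  }
  paths <- if (length(paths))
    data.frame(from = vapply(paths, `[`, "", 1L),
               to = vapply(paths, `[`, "", 2L), stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0))
  if (anyDuplicated(paths))
    stop("duplicate path: ",
         paste(paths[duplicated(paths), ], collapse = " -> "))
  covs <- if (length(covs))
    unique(data.frame(var1 = vapply(covs, `[`, "", 1L),
                      var2 = vapply(covs, `[`, "", 2L),
                      stringsAsFactors = FALSE))
  else data.frame(var1 = character(0), var2 = character(0))
  path_model(vars, paths, covs, name = name)
}

#' @rdname parse_model
#' @param vars character vector of observed variables.
#' @param paths data frame with columns \code{from}, \code{to}.
#' @param covs data frame with columns \code{var1}, \code{var2} of free
#'   exogenous covariances.
#' @export
path_model <- function(vars, paths, covs =
                         data.frame(var1 = character(0), var2 = character(0)),
                       name = NULL) {
  vars <- unique(as.character(vars))
  stopifnot(all(c(paths$from, paths$to, covs$var1, covs$var2) %in% vars))
  # topological sort; detects cycles
  order <- character(0)
  remaining <- vars
  while (length(remaining)) {
    # variables with no incoming edge from a not-yet-placed variable
    free <- remaining[!(remaining %in% paths$to[paths$from %in% remaining])]
    if (!length(free))
      stop("path model contains a cycle among: ",
           paste(remaining, collapse = ", "))
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  endo <- unique(paths$to)
  in_cov <- unique(c(covs$var1, covs$var2))
  if (any(in_cov %in% endo))
    stop("free covariances are only allowed between exogenous variables: ",
         paste(intersect(in_cov, endo), collapse = ", "))
  structure(list(vars = order, paths = paths, covs = covs,
                 name = if (is.null(name)) "model" else name),
            class = "path_model")
}

#' @rdname parse_model
#' @param spec a \code{path_model}.
#' @export
serialize_model <- function(spec) {
  paste(c(sprintf("%s -> %s", spec$paths$from, spec$paths$to),
          sprintf("%s <-> %s", spec$covs$var1, spec$covs$var2)),
        collapse = "\n")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model:", x$name, "\n")
  cat(" ", length(x$vars), "observed variables:",
      paste(x$vars, collapse = ", "), "\n")
  cat(" ", nrow(x$paths), "paths;", nrow(x$covs),
      "free exogenous covariance(s); df =", degrees_of_freedom(x), "\n")
  invisible(x)
}

#' Model degrees of freedom
#'
#' \eqn{p(p+1)/2} non-redundant covariance moments minus the number of free
#' parameters: one coefficient per path, one variance per variable
#' (exogenous or residual), and one parameter per declared free exogenous
#' covariance.
#'
#' @param spec a \code{path_model}.
#' @return Integer df (error if negative: over-parameterized model).
#' @export
degrees_of_freedom <- function(spec) {
  p <- length(spec$vars)
  df <- (p * (p + 1L)) %/% 2L - (nrow(spec$paths) + p + nrow(spec$covs))
  if (df < 0L)
    stop("over-parameterized model: df = ", df)
  as.integer(df)
}

# Free-parameter names in canonical order: paths, variances, covariances.
.param_names <- function(spec) {
  c(sprintf("%s->%s", spec$paths$from, spec$paths$to),
    sprintf("var(%s)", spec$vars),
    sprintf("cov(%s,%s)", spec$covs$var1, spec$covs$var2))
}

# Split a named theta vector into B and Psi matrices.
.theta_matrices <- function(spec, theta) {
  p <- length(spec$vars)
  B <- Psi <- matrix(0, p, p, dimnames = list(spec$vars, spec$vars))
  nb <- nrow(spec$paths)
  for (i in seq_len(nb))
    B[spec$paths$to[i], spec$paths$from[i]] <- theta[i]
  diag(Psi) <- theta[nb + seq_len(p)]
  nc <- nrow(spec$covs)
  for (i in seq_len(nc)) {
    v <- theta[nb + p + i]
    Psi[spec$covs$var1[i], spec$covs$var2[i]] <- v
    Psi[spec$covs$var2[i], spec$covs$var1[i]] <- v
  }
  list(B = B, Psi = Psi)
}

#' Model-implied covariance matrix
#'
#' For a recursive path model with coefficient matrix \eqn{B} and
#' (co)variance matrix \eqn{\Psi},
#' \eqn{\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-T}}.
#'
#' @param spec a \code{path_model}.
#' @param theta numeric vector of free parameters in the order given by the
#'   fit (paths, then variances in variable order, then covariances).
#' @return The implied covariance matrix over \code{spec$vars}.
#' @export
implied_covariance <- function(spec, theta) {
  p <- length(spec$vars)
  nfree <- nrow(spec$paths) + p + nrow(spec$covs)
  if (length(theta) != nfree)
    stop("theta must have length ", nfree)
  mats <- .theta_matrices(spec, theta)
  IB <- diag(p) - mats$B
  Ainv <- solve(IB)  # acyclic B => unit-triangular under topological order
  Sigma <- Ainv %*% mats$Psi %*% t(Ainv)
  dimnames(Sigma) <- list(spec$vars, spec$vars)
  (Sigma + t(Sigma)) / 2
}

# Species entering the sampling-effect model family: the nine consumers
# plus the three recurrent contaminant taxa censused in final communities.
.sampling_species <- function() {
  c("mosquito", "midge", "mite", "copepod", "rotifer",
    paste0("protozoa", 1:4),
    "microflagellates", "cyclidium", "peranema")
}

#' Build the a priori decomposition path models
#'
#' Constructs the full candidate set: 12 sampling-effect models (one per
#' species: richness determines the species' abundance, which determines
#' decomposition) and 4 food-web models — the indirect and combined
#' top-down trophic cascade models (mosquito, copepod and rotifer releasing
#' bacteria from protozoan grazing) and the indirect and combined full
#' food-web models (adding mite and midge paths to decomposition). Protozoan
#' abundances enter the food-web models as one summed variable. Every model
#' is emitted with and without a direct initial-ant-mass path to
#' decomposition, giving 32 specifications. Food-web models carry one free
#' exogenous covariance, mosquito with copepod (the two predators share the
#' same prey); all other exogenous covariances are fixed at zero.
#'
#' @return Named list of \code{path_model} objects.
#' @export
build_paper_models <- function() {
  models <- list()
  for (sp in .sampling_species()) {
    base <- data.frame(from = c("richness", sp),
                       to = c(sp, "decomp"), stringsAsFactors = FALSE)
    models[[paste0("sampling_", sp)]] <-
      path_model(c("richness", sp, "decomp"), base,
                 name = paste0("sampling_", sp))
    models[[paste0("sampling_", sp, "_antmass")]] <-
      path_model(c("richness", sp, "antmass", "decomp"),
                 rbind(base, data.frame(from = "antmass", to = "decomp")),
                 name = paste0("sampling_", sp, "_antmass"))
  }
  cascade <- data.frame(
    from = c("mosquito", "mosquito", "copepod", "rotifer", "protozoa"),
    to   = c("rotifer", "protozoa", "protozoa", "protozoa", "decomp"),
    stringsAsFactors = FALSE)
  direct <- data.frame(from = c("mosquito", "copepod", "rotifer"),
                       to = rep("decomp", 3L), stringsAsFactors = FALSE)
  fullweb <- data.frame(from = c("mite", "midge"),
                        to = rep("decomp", 2L), stringsAsFactors = FALSE)
  mc_cov <- data.frame(var1 = "mosquito", var2 = "copepod",
                       stringsAsFactors = FALSE)
  fam <- list(
    indirect_top_down = list(vars = c("mosquito", "copepod", "rotifer",
                                      "protozoa", "decomp"),
                             paths = cascade),
    combined_top_down = list(vars = c("mosquito", "copepod", "rotifer",
                                      "protozoa", "decomp"),
                             paths = rbind(cascade, direct)),
    indirect_full_web = list(vars = c("mosquito", "copepod", "rotifer",
                                      "protozoa", "mite", "midge", "decomp"),
                             paths = rbind(cascade, fullweb)),
    combined_full_web = list(vars = c("mosquito", "copepod", "rotifer",
                                      "protozoa", "mite", "midge", "decomp"),
                             paths = rbind(cascade, direct, fullweb))
  )
  for (nm in names(fam)) {
    f <- fam[[nm]]
    models[[nm]] <- path_model(f$vars, f$paths, mc_cov, name = nm)
    models[[paste0(nm, "_antmass")]] <-
      path_model(append(f$vars, "antmass", after = length(f$vars) - 1L),
                 rbind(f$paths, data.frame(from = "antmass", to = "decomp")),
                 mc_cov, name = paste0(nm, "_antmass"))
  }
  models
}
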