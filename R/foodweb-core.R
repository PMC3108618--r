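#' Species pools for inquiline food webs
#'
#' A species pool is an ordered set of taxon labels, each tagged with a role:
#' \code{"consumer"} for manipulable consumer taxa or \code{"basal"} for
#' resources present in every web (bacteria, detritus, particulate organic
#' matter, yeast).
#'
#' @param taxa character vector of unique taxon labels.
#' @param roles character vector, same length, each \code{"consumer"} or
#'   \code{"basal"}.
#' @return An object of class \code{species_pool}: a data frame with columns
#'   \code{taxon} and \code{role}, in the given order.
#' @examples
#' species_pool(c("mosquito", "bacteria"), c("consumer", "basal"))
#' @export
species_pool <- function(taxa, roles) {
  taxa <- as.character(taxa)
  roles <- as.character(roles)
  if (length(taxa) != length(roles))
    stop("`taxa` and `roles` must have the same length")
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  bad <- setdiff(unique(roles), c("consumer", "basal"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  structure(data.frame(taxon = taxa, role = roles, stringsAsFactors = FALSE),
            class = c("species_pool", "data.frame"))
}

#' @rdname species_pool
#' @param pool a \code{species_pool}.
#' @export
consumers <- function(pool) pool$taxon[pool$role == "consumer"]

#' @rdname species_pool
#' @export
basal_taxa <- function(pool) pool$taxon[pool$role == "basal"]

#' The canonical Sarracenia purpurea inquiline species pool
#'
#' Nine consumer taxa (the pitcher-plant mosquito \emph{Wyeomyia smithii},
#' the midge \emph{Metriocnemus knabi}, the mite \emph{Sarraceniopus
#' gibsoni}, an unidentified copepod, the rotifer \emph{Habrotrocha rosa},
#' and four cultured protozoan taxa, labelled generically) plus four basal
#' resources: bacteria, detritus (ant carcasses), particulate organic matter
#' (POM), and yeast.
#'
#' @return A \code{species_pool} of 13 taxa.
#' @export
sarracenia_pool <- function() {
  species_pool(
    c("mosquito", "midge", "mite", "copepod", "rotifer",
      paste0("protozoa", 1:4),
      "bacteria", "detritus", "pom", "yeast"),
    c(rep("consumer", 9L), rep("basal", 4L))
  )
}

#' Read or write a species pool as YAML
#'
#' The YAML file is a flat mapping from taxon label to role.
#'
#' @param path file path.
#' @return \code{read_species_pool} returns a \code{species_pool};
#'   \code{write_species_pool} returns \code{path} invisibly.
#' @export
read_species_pool <- function(path) {
  m <- yaml::read_yaml(path)
  species_pool(names(m), unlist(m, use.names = FALSE))
}

#' @rdname read_species_pool
#' @param pool a \code{species_pool}.
#' @export
write_species_pool <- function(pool, path) {
  yaml::write_yaml(as.list(stats::setNames(pool$role, pool$taxon)), path)
  invisible(path)
}

#' Binary trophic interaction matrices
#'
#' An interaction matrix is a square, symmetric 0/1 matrix over a taxon set:
#' entry \eqn{a_{ij} = 1} when the species in row \eqn{i} consumes or is
#' consumed by the species in column \eqn{j}, 0 otherwise. The diagonal is
#' zero (no cannibalism links).
#'
#' @param m a square numeric matrix with identical row and column names.
#' @param pool optional \code{species_pool}; when given, the matrix taxa must
#'   match the pool's taxa and the pool is attached as an attribute.
#' @return An object of class \code{interaction_matrix} (an integer matrix).
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' interaction_matrix(m)
#' @export
interaction_matrix <- function(m, pool = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop("interaction matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("interaction matrix must have row and column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon label: ", rownames(m)[duplicated(rownames(m))][1L])
  if (!identical(rownames(m), colnames(m)))
    stop("row and column taxon labels differ")
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("interaction matrix entries must be 0 or 1")
  asym <- which(m != t(m) & upper.tri(m), arr.ind = TRUE)
  if (nrow(asym))
    stop("interaction matrix is asymmetric at pair (",
         rownames(m)[asym[1L, 1L]], ", ", colnames(m)[asym[1L, 2L]], ")")
  if (any(diag(m) != 0L))
    stop("interaction matrix diagonal must be zero")
  if (!is.null(pool)) {
    if (!setequal(pool$taxon, rownames(m)))
      stop("matrix taxa do not match the species pool")
    attr(m, "pool") <- pool
  }
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' Read or write an interaction matrix CSV
#'
#' First row and first column carry taxon labels; cells are 0/1; the file is
#' validated on read (symmetry, zero diagonal, binary entries).
#'
#' @param path CSV file path.
#' @param pool optional \code{species_pool} to validate against and attach.
#' @return \code{read_interaction_matrix} returns an
#'   \code{interaction_matrix}, taxon order as in the file.
#' @export
read_interaction_matrix <- function(path, pool = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labs
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m))
    stop("non-numeric or missing cell in ", path)
  interaction_matrix(m, pool = pool)
}

#' @rdname read_interaction_matrix
#' @param m an \code{interaction_matrix}.
#' @export
write_interaction_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The reconstructed Sarracenia interaction matrix
#'
#' Loads the package's 13-taxon interaction matrix for the pitcher-plant
#' inquiline web. This fixture is a \emph{synthetic reconstruction} assembled
#' from well-documented trophic links of the system (mosquito and copepod
#' preying on protozoa and rotifers; rotifers, protozoa and the mite feeding
#' on bacteria; the midge shredding detritus into POM; bacteria decomposing
#' detritus, POM and yeast; rotifers and protozoa grazing yeast; the mite
#' feeding on detritus and POM), not a copy of any published supplementary
#' table.
#'
#' @return An \code{interaction_matrix} with the \code{\link{sarracenia_pool}}
#'   attached.
#' @export
sarracenia_web <- function() {
  path <- system.file("extdata", "sarracenia_interaction_matrix.csv",
                      package = "pitcherwebs", mustWork = TRUE)
  read_interaction_matrix(path, pool = sarracenia_pool())
}

#' Extract the trophic profile of a species subset
#'
#' Returns the rows of the parent matrix for the taxa present in a web. With
#' \code{column_mode = "full_pool"} (default) the columns span the whole
#' parent pool, so absent species still contribute to each row's trophic
#' identity; \code{"restricted"} keeps only the present taxa's columns.
#' Basal taxa are appended to \code{present} by default because every
#' experimental web contains them.
#'
#' @param m an \code{interaction_matrix} (with a pool attached if
#'   \code{include_basal} is used).
#' @param present character vector of present taxa.
#' @param column_mode \code{"full_pool"} or \code{"restricted"}.
#' @param include_basal append the pool's basal taxa to \code{present}?
#' @return A 0/1 matrix with one row per present taxon.
#' @export
subweb <- function(m, present, column_mode = c("full_pool", "restricted"),
                   include_basal = TRUE) {
  column_mode <- match.arg(column_mode)
  present <- as.character(present)
  unknown <- setdiff(present, rownames(m))
  if (length(unknown))
    stop("unknown taxon: ", paste(unknown, collapse = ", "))
  if (include_basal) {
    pool <- attr(m, "pool")
    if (!is.null(pool))
      present <- union(present, basal_taxa(pool))
  }
  if (!length(present))
    stop("empty species subset")
  present <- rownames(m)[rownames(m) %in% present]  # parent order
  cols <- if (column_mode == "full_pool") rownames(m) else present
  out <- unclass(m)[present, cols, drop = FALSE]
  attr(out, "pool") <- NULL
  out
}
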