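#' Pairwise trophic distance between species' interaction profiles
#'
#' Converts a rectangular 0/1 profile matrix (rows = species, columns =
#' potential interaction partners) into a symmetric distance matrix.
#' Euclidean distance is \eqn{d_{ij} = \sqrt{\sum_k (a_{ik} - a_{jk})^2}};
#' Jaccard distance is one minus the ratio of the intersection to the union
#' of the rows' 1-sets. Two all-zero rows have an empty union; their Jaccard
#' distance is defined as 0 (with a warning), since species with no recorded
#' interactions are trophically indistinguishable.
#'
#' @param profile 0/1 matrix with row names.
#' @param metric \code{"euclidean"} or \code{"jaccard"}.
#' @return A \code{dist} object with attribute \code{metric}.
#' @export
trophic_distance <- function(profile, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  profile <- as.matrix(unclass(profile))
  if (nrow(profile) < 1L)
    stop("empty profile matrix")
  if (metric == "euclidean") {
    d <- stats::dist(profile, method = "euclidean")
  } else {
    d <- stats::dist(profile, method = "binary")
    if (sum(rowSums(profile != 0) == 0) >= 2L)
      warning("all-zero rows: Jaccard distance between them set to 0 ",
              "(empty union)")
    if (anyNA(d)) d[is.na(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

.linkage_methods <- c(upgma = "average", ward = "ward.D2",
                      single = "single", complete = "complete")

#' Hierarchical clustering of a trophic distance matrix
#'
#' Agglomerative clustering with node height equal to the inter-cluster
#' distance at each merge and leaves at height 0, so the tree is ultrametric.
#' \code{"upgma"} is average linkage; \code{"ward"} uses the squared-distance
#' update (\code{ward.D2}) with heights reported on the distance scale;
#' tie-breaking follows \code{\link[stats]{hclust}}'s deterministic
#' first-index rule, so results are reproducible for a fixed taxon order.
#'
#' @param d a \code{dist} object (e.g. from \code{\link{trophic_distance}}).
#' @param linkage one of \code{"upgma"}, \code{"ward"}, \code{"single"},
#'   \code{"complete"}.
#' @return An \code{hclust} object with attribute \code{linkage}, or for a
#'   single taxon a degenerate object of class \code{td_leaf}.
#' @export
td_cluster <- function(d, linkage = c("upgma", "ward", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (anyNA(d))
    stop("distance matrix contains NA")
  n <- attr(d, "Size")
  if (is.null(n)) stop("`d` must be a dist object")
  if (n == 1L) {
    return(structure(list(labels = attr(d, "Labels")), class = "td_leaf",
                     linkage = linkage))
  }
  h <- stats::hclust(d, method = .linkage_methods[[linkage]])
  attr(h, "linkage") <- linkage
  h
}

#' Cophenetic correlation between a distance matrix and its dendrogram
#'
#' Pearson correlation between the \eqn{n(n-1)/2} original pairwise
#' distances and the cophenetic distances (the merge height of each pair's
#' lowest common ancestor). Values near 1 mean the tree faithfully
#' represents the distance matrix.
#'
#' @param d a \code{dist} object over at least 3 taxa.
#' @param tree an \code{hclust} tree built on the same taxa.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
cophenetic_correlation <- function(d, tree) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L)
    stop("cophenetic correlation needs at least 3 taxa")
  cd <- stats::cophenetic(tree)
  x <- as.vector(d)
  y <- as.vector(cd)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cophenetic correlation undefined: zero variance in distances")
  stats::cor(x, y)
}

#' Total branch length of a dendrogram
#'
#' Sum over all edges of (parent height minus child height), with leaves at
#' height 0. This is the quantity used as trophic diversity: a two-leaf tree
#' merged at height \eqn{h} has total branch length \eqn{2h}; a single leaf
#' has length 0.
#'
#' @param tree an \code{hclust} object (or single-leaf \code{td_leaf}).
#' @return Nonnegative total branch length.
#' @export
total_branch_length <- function(tree) {
  if (inherits(tree, "td_leaf")) return(0)
  stopifnot(inherits(tree, "hclust"))
  merge <- tree$merge
  height <- tree$height
  total <- 0
  for (k in seq_len(nrow(merge))) {
    for (child in merge[k, ]) {
      child_h <- if (child < 0) 0 else height[child]
      total <- total + (height[k] - child_h)
    }
  }
  total
}

#' Select the distance/linkage combination by cophenetic correlation
#'
#' Evaluates Euclidean and Jaccard distances crossed with UPGMA, Ward,
#' single and complete linkage on the full-pool interaction matrix and
#' returns the combination with maximum cophenetic correlation. Ties are
#' broken in a fixed order with (euclidean, upgma) first.
#'
#' @param m an \code{interaction_matrix}.
#' @return A data frame of class \code{td_method_selection} with columns
#'   \code{metric}, \code{linkage}, \code{cophenetic_r}, sorted by
#'   decreasing correlation, and attributes \code{metric}/\code{linkage} for
#'   the winner.
#' @export
select_method <- function(m) {
  metrics <- c("euclidean", "jaccard")
  linkages <- c("upgma", "ward", "single", "complete")
  grid <- expand.grid(metric = metrics, linkage = linkages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # fixed tie order: euclidean before jaccard, upgma first
  grid <- grid[order(match(grid$linkage, linkages), match(grid$metric, metrics)), ]
  grid$cophenetic_r <- NA_real_
  for (i in seq_len(nrow(grid))) {
    r <- tryCatch({
      d <- trophic_distance(unclass(m), grid$metric[i])
      cophenetic_correlation(d, td_cluster(d, grid$linkage[i]))
    }, error = function(e) {
      warning("skipping ", grid$metric[i], "/", grid$linkage[i], ": ",
              conditionMessage(e))
      NA_real_
    })
    grid$cophenetic_r[i] <- r
  }
  if (all(is.na(grid$cophenetic_r)))
    stop("cophenetic correlation undefined for every metric/linkage pair")
  ord <- order(-grid$cophenetic_r)  # stable: preserves tie order
  grid <- grid[ord, ]
  rownames(grid) <- NULL
  structure(grid, class = c("td_method_selection", "data.frame"),
            metric = grid$metric[1L], linkage = grid$linkage[1L])
}

# Sum of branch lengths of the minimal subtree spanning `leaves`
# (and their lowest common ancestor) in an hclust tree. An edge
# parent -> child is in the spanning subtree iff the child's cluster
# contains at least one but not all selected leaves.
.spanning_length <- function(tree, leaves) {
  labs <- tree$labels
  sel <- labs %in% leaves
  n_sel <- sum(sel)
  if (n_sel <= 1L) return(0)
  merge <- tree$merge
  height <- tree$height
  count <- integer(nrow(merge))  # selected leaves under each internal node
  total <- 0
  for (k in seq_len(nrow(merge))) {
    for (child in merge[k, ]) {
      if (child < 0) {
        c_cnt <- as.integer(sel[-child])
        c_h <- 0
      } else {
        c_cnt <- count[child]
        c_h <- height[child]
      }
      count[k] <- count[k] + c_cnt
      if (c_cnt >= 1L && c_cnt < n_sel)
        total <- total + (height[k] - c_h)
    }
  }
  total
}

#' Trophic diversity of a species composition
#'
#' Computes the raw trophic diversity (TD) of a web: the total branch length
#' of a dendrogram clustering species by their trophic interaction profiles.
#' In \code{"recluster"} mode (default) the distance matrix and tree are
#' rebuilt on the composition's own profile, mirroring an analysis that
#' constructs an interaction matrix per species combination. In
#' \code{"master_subtree"} mode one tree is built on the full pool and TD is
#' the summed length of the branches spanning the composition's leaves (the
#' functional-diversity convention), which is monotone non-decreasing as
#' taxa are added.
#'
#' @param m an \code{interaction_matrix} with a pool attached.
#' @param composition character vector of present consumer taxa (may be
#'   empty when \code{include_basal} is \code{TRUE}).
#' @param mode \code{"recluster"} or \code{"master_subtree"}.
#' @param metric,linkage passed to \code{\link{trophic_distance}} and
#'   \code{\link{td_cluster}}.
#' @param include_basal treat the pool's basal taxa as always present
#'   (default) and as dendrogram leaves.
#' @param column_mode column handling for the profile, see
#'   \code{\link{subweb}}.
#' @return A list of class \code{td_result}: \code{raw} branch length,
#'   \code{composition}, \code{mode}, \code{metric}, \code{linkage},
#'   \code{include_basal}, and the \code{tree} used.
#' @export
trophic_diversity <- function(m, composition,
                              mode = c("recluster", "master_subtree"),
                              metric = "euclidean", linkage = "upgma",
                              include_basal = TRUE,
                              column_mode = "full_pool") {
  mode <- match.arg(mode)
  composition <- as.character(composition)
  if (!length(composition) && !include_basal)
    stop("empty composition with include_basal = FALSE")
  if (mode == "recluster") {
    prof <- subweb(m, composition, column_mode = column_mode,
                   include_basal = include_basal)
    if (nrow(prof) == 1L) {
      tree <- structure(list(labels = rownames(prof)), class = "td_leaf")
      raw <- 0
    } else {
      d <- trophic_distance(prof, metric)
      tree <- td_cluster(d, linkage)
      raw <- total_branch_length(tree)
    }
  } else {
    prof <- subweb(m, rownames(m), column_mode = "full_pool",
                   include_basal = include_basal)
    d <- trophic_distance(prof, metric)
    tree <- td_cluster(d, linkage)
    leaves <- composition
    if (include_basal) {
      pool <- attr(m, "pool")
      if (!is.null(pool)) leaves <- union(leaves, basal_taxa(pool))
    }
    raw <- if (setequal(leaves, rownames(m))) total_branch_length(tree)
           else .spanning_length(tree, leaves)
  }
  structure(list(raw = raw, composition = composition, mode = mode,
                 metric = metric, linkage = linkage,
                 include_basal = include_basal, tree = tree),
            class = "td_result")
}

#' @export
print.td_result <- function(x, ...) {
  cat("Trophic diversity (", x$mode, ", ", x$metric, "+", x$linkage,
      if (x$include_basal) ", basal taxa included" else "", ")\n", sep = "")
  cat("  composition:", if (length(x$composition))
    paste(x$composition, collapse = ", ") else "(basal only)", "\n")
  cat("  raw branch length:", format(x$raw), "\n")
  invisible(x)
}

#' Standardize raw TD values to the unit interval
#'
#' Min–max scaling over an enumerated set of webs:
#' \eqn{(x - \min)/(\max - \min)}, so the least trophically diverse web in
#' the set scores 0 and the most diverse scores 1.
#'
#' @param raw numeric vector of raw TD values with at least 2 distinct
#'   values.
#' @return Numeric vector in \eqn{[0, 1]}.
#' @export
standardize_td <- function(raw) {
  rng <- range(raw)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("cannot standardize constant TD values")
  (raw - rng[1L]) / diff(rng)
}

#' Export a dendrogram to Newick format
#'
#' Branch lengths are height differences with leaves at height 0 (so a
#' pair merged at height 2 becomes \code{"(A:2,B:2);"} and the branch
#' lengths of the whole file sum to the tree's total branch length). All
#' cophenetic distances are recoverable from the file: the merge height of
#' a pair is the length of the path from either leaf up to their most
#' recent common ancestor.
#'
#' @param tree an \code{hclust} object (or single-leaf \code{td_leaf}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "td_leaf")) {
    writeLines(paste0(tree$labels, ";"), path)
    return(invisible(path))
  }
  stopifnot(inherits(tree, "hclust"))
  merge <- tree$merge
  height <- tree$height
  node_str <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%s", tree$labels[-node], format(parent_h)))
    h <- height[node]
    kids <- vapply(merge[node, ], node_str, "", parent_h = h)
    sprintf("(%s):%s", paste(kids, collapse = ","), format(parent_h - h))
  }
  root <- nrow(merge)
  kids <- vapply(merge[root, ], node_str, "", parent_h = height[root])
  writeLines(sprintf("(%s);", paste(kids, collapse = ",")), path)
  invisible(path)
}
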