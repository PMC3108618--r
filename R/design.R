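#' Enumerate all consumer combinations at one richness level
#'
#' All \eqn{\binom{9}{k}} consumer subsets of the pool at richness \eqn{k},
#' in deterministic lexicographic order (by consumer position in the pool).
#'
#' @param pool a \code{species_pool}.
#' @param richness integer, 0 to the number of consumers.
#' @return A list of character vectors (richness 0 gives one empty
#'   composition: the bacteria-only web).
#' @export
enumerate_webs <- function(pool, richness) {
  cons <- consumers(pool)
  if (length(richness) != 1L || richness < 0 || richness > length(cons))
    stop("richness must be between 0 and ", length(cons))
  if (richness == 0L) return(list(character(0)))
  idx <- utils::combn(length(cons), richness, simplify = FALSE)
  lapply(idx, function(i) cons[i])
}

#' Enumerate every web and its trophic diversity
#'
#' Evaluates raw TD for every consumer subset at every richness level
#' (\eqn{2^9 = 512} webs for the canonical pool) and standardizes TD by
#' min–max over the whole enumeration.
#'
#' @param pool a \code{species_pool}.
#' @param m an \code{interaction_matrix} over the pool.
#' @param ... passed to \code{\link{trophic_diversity}} (mode, metric,
#'   linkage, include_basal, column_mode).
#' @return A data frame with columns \code{richness}, \code{composition}
#'   (taxa joined by \code{";"}), \code{td_raw}, \code{td_std}.
#' @export
enumerate_all_webs <- function(pool, m, ...) {
  rows <- list()
  for (r in 0:length(consumers(pool))) {
    for (comp in enumerate_webs(pool, r)) {
      td <- trophic_diversity(m, comp, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(richness = r,
                   composition = paste(comp, collapse = ";"),
                   td_raw = td$raw, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$td_std <- standardize_td(out$td_raw)
  out
}

#' Bin TD values into k equal-width levels
#'
#' Divides the range of one richness level's TD values into \code{k}
#' equal-width intervals from the lowest to the highest value. Interval
#' \eqn{i} is \eqn{[\min + (i-1)w, \min + iw)} with the last interval closed
#' on the right. Degenerate all-equal input puts every web in bin 1 with a
#' warning.
#'
#' @param td numeric TD values.
#' @param k number of levels (default 7).
#' @return Integer bin labels in \code{1:k}.
#' @export
bin_td <- function(td, k = 7L) {
  if (!length(td)) stop("no TD values to bin")
  if (k < 1L) stop("k must be >= 1")
  rng <- range(td)
  if (diff(rng) == 0) {
    warning("constant TD values: all webs assigned to bin 1")
    return(rep(1L, length(td)))
  }
  edges <- rng[1L] + diff(rng) * (0:k) / k
  as.integer(findInterval(td, edges, rightmost.closed = TRUE,
                          all.inside = TRUE))
}

#' Default initial abundances for macro-invertebrates
#'
#' Initial individual counts for the taxa that do not reproduce inside the
#' pitcher over the experiment (mosquito and midge larvae, mites, copepods).
#' The default counts are order-of-magnitude placeholders in the realistic
#' range for 10 ml of pitcher fluid, not values claimed from any census;
#' they are configurable.
#'
#' @param counts named integer vector taxon -> initial count (>= 1).
#' @return Named integer vector of class \code{abundance_template}.
#' @export
abundance_template <- function(counts = c(mosquito = 5L, midge = 5L,
                                          mite = 2L, copepod = 2L)) {
  counts <- round(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by taxon")
  if (any(counts < 1L))
    stop("initial counts must be >= 1")
  structure(as.integer(counts), names = names(counts),
            class = "abundance_template")
}

#' Draw a TD-stratified randomized experimental design
#'
#' Reproduces the study's stratified design: for each richness level 1-9,
#' raw TD is computed for every consumer combination, binned into \code{k}
#' equal-width levels, and one web is drawn uniformly at random from each
#' bin; empty bins (possible at extreme richness where few distinct TD
#' values exist) are backfilled from the nearest non-empty bin. Richness 0
#' contributes \code{replicates} bacteria-only webs. Row order (the
#' \code{position} column) is randomized, emulating randomized placement of
#' pitchers.
#'
#' @param pool a \code{species_pool}.
#' @param m an \code{interaction_matrix} over the pool.
#' @param replicates webs per richness level (default 7; must equal \code{k}).
#' @param k number of TD levels per richness treatment (default 7).
#' @param seed integer seed for the random draws.
#' @param template an \code{\link{abundance_template}} used to fill initial
#'   abundance columns.
#' @param ... TD options passed to \code{\link{trophic_diversity}}.
#' @return A data frame of class \code{design_table} with one row per web:
#'   \code{web_id}, \code{position}, \code{richness}, \code{td_level},
#'   \code{td_raw}, \code{td_std}, \code{composition}, and one initial
#'   abundance column per template taxon.
#' @export
sample_design <- function(pool, m, replicates = 7L, k = 7L, seed = NULL,
                          template = abundance_template(), ...) {
  if (replicates != k)
    stop("replicates must equal k (one web per TD level); no other ",
         "backfill policy is defined")
  if (!is.null(seed)) set.seed(seed)
  enum <- enumerate_all_webs(pool, m, ...)
  rows <- list()
  for (r in 0:length(consumers(pool))) {
    lev <- enum[enum$richness == r, , drop = FALSE]
    if (r == 0L) {
      for (j in seq_len(replicates))
        rows[[length(rows) + 1L]] <-
          data.frame(richness = r, td_level = NA_integer_,
                     td_raw = lev$td_raw[1L], td_std = lev$td_std[1L],
                     composition = "", stringsAsFactors = FALSE)
      next
    }
    bins <- suppressWarnings(bin_td(lev$td_raw, k))
    for (b in seq_len(k)) {
      cand <- which(bins == b)
      if (!length(cand)) {
        # backfill: nearest non-empty bin (ties toward lower bin)
        occupied <- sort(unique(bins))
        nearest <- occupied[which.min(abs(occupied - b))]
        cand <- which(bins == nearest)
        message("richness ", r, ": TD level ", b,
                " empty, backfilled from level ", nearest)
      }
      pick <- cand[sample.int(length(cand), 1L)]
      rows[[length(rows) + 1L]] <-
        data.frame(richness = r, td_level = b,
                   td_raw = lev$td_raw[pick], td_std = lev$td_std[pick],
                   composition = lev$composition[pick],
                   stringsAsFactors = FALSE)
    }
    # backfilled draws can land out of order; levels label the TD rank of
    # the selected webs, so reassign them monotonically
    idx <- (length(rows) - k + 1L):length(rows)
    sel <- do.call(rbind, rows[idx])
    sel <- sel[order(sel$td_raw), ]
    sel$td_level <- seq_len(k)
    rows[idx] <- split(sel, seq_len(k))
  }
  out <- do.call(rbind, rows)
  out <- cbind(web_id = seq_len(nrow(out)), out)
  out$position <- sample.int(nrow(out))
  for (taxon in names(template)) {
    present <- vapply(strsplit(out$composition, ";", fixed = TRUE),
                      function(s) taxon %in% s, logical(1))
    out[[paste0("init_", taxon)]] <- ifelse(present, template[[taxon]], 0L)
  }
  structure(out, class = c("design_table", "data.frame"))
}

#' @rdname sample_design
#' @param x a \code{design_table}.
#' @param path CSV path.
#' @export
write_design <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sample_design
#' @export
read_design <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out$composition[is.na(out$composition)] <- ""
  structure(out, class = c("design_table", "data.frame"))
}
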