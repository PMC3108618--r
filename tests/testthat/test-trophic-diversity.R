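test_that("trophic distances match hand-computed values", {
  prof <- rbind(a = c(1, 0, 0, 1), b = c(1, 1, 0, 0), c = c(1, 0, 0, 1))
  d_e <- trophic_distance(prof, "euclidean")
  expect_equal(as.matrix(d_e)["a", "c"], 0)
  expect_equal(as.matrix(d_e)["a", "b"], sqrt(2))

  prof2 <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  d_j <- trophic_distance(prof2, "jaccard")
  expect_equal(as.vector(d_j), 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(as.vector(trophic_distance(rbind(a = c(1, 1), b = c(1, 1)),
                                          "jaccard")), 0)

  expect_error(trophic_distance(matrix(nrow = 0, ncol = 3)), "empty")
  expect_warning(
    dz <- trophic_distance(rbind(a = c(0, 0), b = c(0, 0)), "jaccard"),
    "all-zero")
  expect_equal(as.vector(dz), 0)
})

test_that("clustering reproduces hand-run UPGMA and single linkage", {
  tr <- td_cluster(dist_ultra3(), "upgma")
  expect_equal(tr$height, c(2, 4))
  # A,B merge first
  expect_setequal(tr$labels[-tr$merge[1, ]], c("A", "B"))

  tr2 <- td_cluster(dist_tri3(), "upgma")
  expect_equal(tr2$height, c(2, 3.5))  # C joins at (3+4)/2
  tr3 <- td_cluster(dist_tri3(), "single")
  expect_equal(tr3$height, c(2, 3))    # C joins at min(3,4)

  leaf <- td_cluster(stats::dist(matrix(0, 1, 2,
                                        dimnames = list("A", NULL))))
  expect_s3_class(leaf, "td_leaf")
  expect_equal(total_branch_length(leaf), 0)

  dna <- dist_ultra3(); dna[1] <- NA
  expect_error(td_cluster(dna), "NA")
})

test_that("cophenetic correlation is 1 for ultrametric input and errors on degenerate input", {
  d <- dist_ultra3()
  tr <- td_cluster(d, "upgma")
  expect_equal(cophenetic_correlation(d, tr), 1)
  expect_equal(as.vector(stats::cophenetic(tr)), as.vector(d))

  deq <- make_dist(matrix(2, 3, 3) - diag(2, 3), c("A", "B", "C"))
  expect_error(cophenetic_correlation(deq, td_cluster(deq, "upgma")),
               "zero variance")
  d2 <- make_dist(matrix(c(0, 1, 1, 0), 2, 2), c("A", "B"))
  expect_error(cophenetic_correlation(d2, td_cluster(d2, "upgma")),
               "at least 3")
})

test_that("total branch length follows the edge-sum definition", {
  d2 <- make_dist(matrix(c(0, 2, 2, 0), 2, 2), c("A", "B"))
  expect_equal(total_branch_length(td_cluster(d2, "upgma")), 4)   # 2 + 2
  tr <- td_cluster(dist_ultra3(), "upgma")
  expect_equal(total_branch_length(tr), 10)  # 2 + 2 + (4 - 2) + 4
})

test_that("edge-sum branch length agrees with an independent oracle on random trees", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    prof <- matrix(stats::rbinom(n * 8, 1, 0.5), n,
                   dimnames = list(paste0("t", 1:n), NULL))
    d <- trophic_distance(prof, "euclidean")
    if (stats::sd(d) == 0) next
    for (lk in c("upgma", "ward", "single", "complete")) {
      tr <- td_cluster(d, lk)
      expect_equal(total_branch_length(tr), vegan::treeheight(tr),
                   tolerance = 1e-10)
    }
  }
})

test_that("produced trees are ultrametric: cophenetic distances satisfy the three-point condition", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    prof <- matrix(stats::rbinom(n * 6, 1, 0.4), n,
                   dimnames = list(paste0("t", 1:n), NULL))
    d <- trophic_distance(prof, "euclidean")
    tr <- td_cluster(d, sample(c("upgma", "ward", "complete"), 1))
    cd <- as.matrix(stats::cophenetic(tr))
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n)
      expect_lte(cd[a, cc], max(cd[a, b], cd[b, cc]) + 1e-10)
  }
})

test_that("method selection picks euclidean + UPGMA on the fixture and on ties", {
  m <- sarracenia_web()
  sel <- select_method(m)
  expect_equal(attr(sel, "metric"), "euclidean")
  expect_equal(attr(sel, "linkage"), "upgma")
  expect_equal(nrow(sel), 8)
  # UPGMA represents the euclidean distances at least as well as single linkage
  r_upgma <- sel$cophenetic_r[sel$metric == "euclidean" & sel$linkage == "upgma"]
  r_single <- sel$cophenetic_r[sel$metric == "euclidean" & sel$linkage == "single"]
  expect_gte(r_upgma, r_single)

  # ultrametric toy input: several combinations tie at r = 1, tie order rules
  ultra <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ultra["A", "B"] <- ultra["B", "A"] <- 0L
  ultra["A", "C"] <- ultra["C", "A"] <- 1L
  ultra["B", "C"] <- ultra["C", "B"] <- 1L
  sel2 <- select_method(interaction_matrix(ultra))
  expect_equal(attr(sel2, "metric"), "euclidean")
  expect_equal(attr(sel2, "linkage"), "upgma")

  two <- interaction_matrix(matrix(c(0L, 1L, 1L, 0L), 2, 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(suppressWarnings(select_method(two)), "undefined")
})

test_that("trophic diversity modes agree at the full pool and order compositions sensibly", {
  m <- sarracenia_web()
  cons <- consumers(sarracenia_pool())
  f1 <- trophic_diversity(m, cons, mode = "recluster")
  f2 <- trophic_diversity(m, cons, mode = "master_subtree")
  expect_equal(f1$raw, f2$raw)

  expect_equal(trophic_diversity(m, "mosquito", include_basal = FALSE)$raw, 0)

  # the midge is trophically distant from the mosquito; the copepod shares
  # the mosquito's prey, so it adds no branch length
  td_mm <- trophic_diversity(m, c("mosquito", "midge"),
                             mode = "master_subtree",
                             include_basal = FALSE)$raw
  td_mc <- trophic_diversity(m, c("mosquito", "copepod"),
                             mode = "master_subtree",
                             include_basal = FALSE)$raw
  expect_gt(td_mm, td_mc)
})

test_that("master-subtree TD is monotone under adding taxa and matches a pruned-tree oracle", {
  skip_if_not_installed("ape")
  m <- sarracenia_web()
  set.seed(3)
  prof <- subweb(m, rownames(m))
  tr <- td_cluster(trophic_distance(prof, "euclidean"), "upgma")
  phy <- ape::as.phylo(tr)  # ape halves heights: lengths scale by 2
  for (i in 1:10) {
    s <- sample(rownames(m), sample(2:11, 1))
    td_s <- trophic_diversity(m, s, mode = "master_subtree",
                              include_basal = FALSE)$raw
    expect_equal(td_s, 2 * sum(ape::keep.tip(phy, s)$edge.length),
                 tolerance = 1e-10)
    extra <- sample(setdiff(rownames(m), s), 1)
    td_more <- trophic_diversity(m, c(s, extra), mode = "master_subtree",
                                 include_basal = FALSE)$raw
    expect_gte(td_more, td_s - 1e-12)
  }
})

test_that("standardized TD is a min-max rescaling", {
  expect_equal(standardize_td(c(0, 5, 10)), c(0, 0.5, 1))
  expect_error(standardize_td(c(3, 3, 3)), "constant")
})

test_that("newick export preserves the dendrogram and its cophenetic distances", {
  skip_if_not_installed("ape")
  f <- withr::local_tempfile(fileext = ".nwk")
  leaf <- structure(list(labels = "A"), class = "td_leaf")
  write_newick(leaf, f)
  expect_equal(readLines(f), "A;")

  d2 <- make_dist(matrix(c(0, 2, 2, 0), 2, 2), c("A", "B"))
  write_newick(td_cluster(d2, "upgma"), f)
  expect_equal(readLines(f), "(A:2,B:2);")

  tr <- td_cluster(dist_ultra3(), "upgma")
  write_newick(tr, f)
  phy <- ape::read.tree(f)
  # patristic distance through the root is twice the merge height
  pat <- ape::cophenetic.phylo(phy) / 2
  cd <- as.matrix(stats::cophenetic(tr))
  expect_equal(pat[rownames(cd), colnames(cd)], cd, ignore_attr = TRUE)
  expect_equal(sum(phy$edge.length), total_branch_length(tr))
})
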