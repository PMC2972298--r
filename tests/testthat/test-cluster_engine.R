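toy_profiles <- function(values, r = seq_len(nrow(values))) {
  df <- data.frame(tc_id = sprintf("TC%03d", seq_len(nrow(values))),
                   r_value = r, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(values))) df[[paste0("m.e", j)]] <- values[, j]
  attr(df, "reporters") <- stats::setNames(
    lapply(df$tc_id, function(x) list(genechip = paste0("r_", x))), df$tc_id)
  attr(df, "platforms") <- "genechip"
  class(df) <- c("combined_profiles", "data.frame")
  df
}

toy_config <- function(...) {
  run_config(experiments = data.frame(matrix_id = "m", column = c("e1", "e2"),
                                      stringsAsFactors = FALSE), ...)
}

test_that("feature matrix has R first and z-scores with the sample sd", {
  p <- toy_profiles(matrix(c(1, 3, 2, 5), ncol = 2), r = c(0, 4))
  fm <- build_feature_matrix(p, toy_config())
  expect_identical(dim(fm), c(2L, 3L))
  expect_identical(colnames(fm)[1], "R")
  expect_equal(unname(fm[, "m.e1"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(mean(fm[, "m.e1"]), 0)
  pc <- toy_profiles(matrix(c(1, 3, 5, 5), ncol = 2), r = c(0, 4))
  expect_warning(fm2 <- build_feature_matrix(pc, toy_config()), "constant")
  expect_equal(unname(fm2[, "m.e2"]), c(0, 0))
  expect_error(build_feature_matrix(p[1, ], toy_config()), "at least 2")
  # standardization off by default when R is excluded
  fm3 <- build_feature_matrix(p, toy_config(include_r_in_features = FALSE))
  expect_equal(unname(fm3[, "m.e1"]), c(1, 3))
})

test_that("ward merges identical rows first at height zero, then nearest pairs", {
  x <- matrix(c(0, 0, 5, 0, 0, 5), ncol = 2)
  rownames(x) <- c("a", "b", "c")
  d <- ward_cluster(x)
  expect_identical(sort(d$merge[1, ]), c(-2L, -1L))
  expect_equal(d$height[1], 0)
  y <- matrix(c(0, 1, 10), ncol = 1)
  rownames(y) <- c("p0", "p1", "p10")
  d2 <- ward_cluster(y)
  expect_identical(sort(d2$merge[1, ]), c(-2L, -1L))
  xbad <- x; xbad[2, 1] <- NaN
  expect_error(ward_cluster(xbad), "non-finite")
})

test_that("merge sequence and heights match the exhaustive Ward stepper (n <= 8)", {
  set.seed(404)
  for (i in 1:12) {
    n <- sample(3:8, 1)
    X <- matrix(stats::rnorm(n * sample(1:4, 1)), nrow = n)
    rownames(X) <- paste0("t", seq_len(n))
    d <- ward_cluster(X)
    o <- oracle_ward(X)
    expect_equal(d$height, o$heights, tolerance = 1e-9)
    expect_identical(hclust_leaf_sets(d), o$sets)
  }
})

test_that("ward heights are monotone nondecreasing", {
  set.seed(17)
  X <- matrix(stats::rnorm(60 * 3), ncol = 3)
  rownames(X) <- paste0("t", 1:60)
  d <- ward_cluster(X)
  expect_true(all(diff(d$height) >= -1e-12))
})

test_that("dendrogram cuts are labelled by leaf order and nest across k", {
  set.seed(29)
  X <- matrix(stats::rnorm(40 * 2), ncol = 2)
  rownames(X) <- sprintf("t%02d", 1:40)
  d <- ward_cluster(X)
  expect_identical(cut_dendrogram(d, 1)$sizes, 40L)
  expect_identical(cut_dendrogram(d, 40)$sizes, rep(1L, 40))
  expect_error(cut_dendrogram(d, 0), "k must be")
  expect_error(cut_dendrogram(d, 41), "k must be")
  # label 1 is the cluster of the leftmost leaf
  a4 <- cut_dendrogram(d, 4)
  expect_identical(unname(a4$labels[d$labels[d$order[1]]]), 1L)
  expect_identical(sum(a4$sizes), 40L)
  for (k in 1:7) {
    fine <- cut_dendrogram(d, k + 1)$labels
    coarse <- cut_dendrogram(d, k)$labels
    expect_true(refines_with_one_split(fine, coarse))
  }
})

test_that("row-permuted input yields the same partition for every k", {
  set.seed(31)
  X <- matrix(stats::rnorm(25 * 3), ncol = 3)
  rownames(X) <- sprintf("t%02d", 1:25)
  d1 <- ward_cluster(X)
  p <- sample(25)
  d2 <- ward_cluster(X[p, ])
  for (k in c(2, 4, 7)) {
    l1 <- cut_dendrogram(d1, k)$labels
    l2 <- cut_dendrogram(d2, k)$labels[names(l1)]
    expect_equal(rand_index(l1, l2), 1)
  }
})

test_that("dendrogram serializations round-trip (merge TSV and Newick)", {
  set.seed(37)
  X <- matrix(stats::rnorm(12 * 2), ncol = 2)
  rownames(X) <- sprintf("t%02d", 1:12)
  d <- ward_cluster(X)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dendrogram(d, f)
  back <- read_dendrogram(f)
  expect_identical(back$merge, d$merge)
  expect_identical(back$height, d$height)
  expect_identical(back$labels, d$labels)
  expect_identical(back$order, d$order)
  for (k in c(2, 5)) {
    expect_identical(cut_dendrogram(back, k)$labels, cut_dendrogram(d, k)$labels)
  }
  fn <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(d, fn)
  phy <- ape::read.tree(fn)
  want <- ape::as.phylo(stats::as.hclust(d))
  expect_true(ape::all.equal.phylo(phy, want, use.edge.length = TRUE,
                                   tolerance = 1e-6))
})

test_that("coordinate export projects three experiments with cluster labels", {
  p <- toy_profiles(matrix(stats::rnorm(12), ncol = 3))
  names(p)[3:5] <- c("m.e1", "m.e2", "m.e3")
  cfg <- run_config(experiments = data.frame(matrix_id = "m",
                                             column = c("e1", "e2", "e3"),
                                             stringsAsFactors = FALSE))
  d <- ward_cluster(build_feature_matrix(p, cfg))
  a <- cut_dendrogram(d, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  export_coordinates(p, a, c("m.e1", "m.e2", "m.e3"), f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 4L)
  expect_equal(back$x, p$m.e1)
  expect_equal(back$z, p$m.e3)
  expect_identical(back$cluster, unname(a$labels[back$tc_id]))
  expect_error(export_coordinates(p, a, c("m.e1", "m.e1", "m.e2"), f), "distinct",
               class = "estarray_config_error")
  expect_error(export_coordinates(p, a, c("m.e1", "m.e2", "nope"), f), "nope")
})
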