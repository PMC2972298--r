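# In-code fixtures and independent oracles shared across the suite.
# Oracles are deliberately coded from the definitions, not via the
# production code paths they check.

tiny_catalog <- function() {
  library_catalog(id = c("#9CR", "#ARB", "#IP8"),
                  name = c("mycorrhized roots", "MTGIM", "NOLLY"),
                  total_ests = c(100L, 300L, 200L))
}

# random composition set over a catalog; guarantees total >= 1 per TC
random_tcs <- function(n_tc, catalog, max_count = 5) {
  lapply(seq_len(n_tc), function(i) {
    repeat {
      x <- stats::rpois(nrow(catalog), 0.8)
      x[x > max_count] <- max_count
      if (sum(x) >= 1) break
    }
    tc_composition(sprintf("TC%04d", i), stats::setNames(x, catalog$id))
  })
}

random_selection <- function(catalog) {
  library_selection(
    catalog,
    must = sample(catalog$id, sample(0:2, 1)),
    must_not = character(0)) -> sel
  # move some MAY libraries to MUST_NOT
  may <- names(sel)[sel == "MAY"]
  mn <- sample(may, min(length(may), sample(0:2, 1)))
  library_selection(catalog, must = names(sel)[sel == "MUST"], must_not = mn)
}

# clause-by-clause filter oracle (independent enumeration)
oracle_filter <- function(tcs, selection) {
  must <- names(selection)[selection == "MUST"]
  must_not <- names(selection)[selection == "MUST_NOT"]
  Filter(function(tc) {
    full <- stats::setNames(rep(0, length(selection)), names(selection))
    full[names(tc$counts)] <- tc$counts
    clause1 <- if (length(must) == 0) TRUE else any(full[must] >= 1)
    clause2 <- all(full[must_not] == 0)
    clause1 && clause2
  }, tcs)
}

# direct evaluation of the Stekel log-likelihood ratio
oracle_r <- function(x, N) {
  keep <- N > 0
  x <- x[keep]; N <- N[keep]
  f <- sum(x) / sum(N)
  if (sum(x) == 0) return(0)
  s <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0) s <- s + x[i] * log(x[i] / (N[i] * f))
  }
  s
}

# exhaustive Ward stepper: at every step evaluate the increase in total
# within-cluster sum of squares for all cluster pairs and merge the minimum
oracle_ward <- function(X) {
  cl <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  sets <- list()
  while (length(cl) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(cl)) {
      for (j in seq_along(cl)) {
        if (i < j) {
          A <- cl[[i]]; B <- cl[[j]]
          mA <- colMeans(X[A, , drop = FALSE])
          mB <- colMeans(X[B, , drop = FALSE])
          d <- (length(A) * length(B) / (length(A) + length(B))) * sum((mA - mB)^2)
          if (d < best) { best <- d; bi <- i; bj <- j }
        }
      }
    }
    heights <- c(heights, sqrt(2 * best))
    sets[[length(sets) + 1]] <- sort(c(cl[[bi]], cl[[bj]]))
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  list(heights = heights, sets = sets)
}

# leaf sets per merge of an hclust-style tree, for comparison with the oracle
hclust_leaf_sets <- function(h) {
  out <- list()
  for (i in seq_len(nrow(h$merge))) {
    f <- function(v) if (v < 0) -v else out[[v]]
    out[[i]] <- sort(c(f(h$merge[i, 1]), f(h$merge[i, 2])))
  }
  out
}

# Rand index from pair counts (closed form, independent of any library)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

# every cluster of partition `fine` lies within one cluster of `coarse`,
# and exactly one coarse cluster is split in two
refines_with_one_split <- function(fine, coarse) {
  stopifnot(identical(names(fine), names(coarse)))
  split_map <- tapply(fine, coarse, function(v) length(unique(v)))
  nested <- all(tapply(coarse, fine, function(v) length(unique(v))) == 1)
  nested && sum(split_map == 2) == 1 && all(split_map %in% c(1, 2))
}

# a small but complete in-memory study used by join / pipeline tests
small_study <- function(seed = 42) {
  generate_fixture(simulation_config(
    n_libraries = 8, library_size_range = c(300, 600), n_tcs = 120,
    n_condition_tcs = 20, n_condition_libraries = 3,
    n_experiments = c(genechip = 2, oligo = 2),
    reporter_dropout = 0.1, seed = seed))
}

# write a small fixture to fxdir and run the file-level pipeline into outdir
run_small_pipeline <- function(outdir, fxdir, seed = 42) {
  fx <- generate_fixture(simulation_config(
    n_libraries = 8, library_size_range = c(300, 600), n_tcs = 120,
    n_condition_tcs = 20, n_condition_libraries = 3,
    n_experiments = c(genechip = 2, oligo = 2),
    reporter_dropout = 0.1, seed = seed), outdir = fxdir)
  mats <- lapply(fx$matrices, function(m) {
    list(path = fx$files[[m$matrix_id]], platform = m$platform)
  })
  names(mats) <- vapply(fx$matrices, `[[`, "", "matrix_id")
  res <- run_pipeline(catalog_file = fx$files[["catalog"]],
                      compositions_file = fx$files[["compositions"]],
                      selection_file = fx$files[["selection"]],
                      reporter_map_file = fx$files[["reporter_map"]],
                      matrix_files = mats,
                      config_file = fx$files[["config"]],
                      outdir = outdir, go_file = fx$files[["go"]])
  list(fx = fx, res = res)
}

# deterministic fixture with an exact retained / joined count: `n_retained`
# TCs pass the filter, `n_no_reporter` of them lack reporters, plus
# `n_filtered_out` TCs that fail the MUST clause
exact_drop_study <- function(n_retained, n_no_reporter, n_filtered_out = 10) {
  catalog <- library_catalog(c("MUSTLIB", "OTHER"), total_ests = c(10000L, 10000L))
  selection <- library_selection(catalog, must = "MUSTLIB")
  n <- n_retained + n_filtered_out
  tcs <- lapply(seq_len(n), function(i) {
    cnt <- if (i <= n_retained) c(MUSTLIB = 1 + i %% 4, OTHER = i %% 3)
           else c(OTHER = 1 + i %% 3)
    tc_composition(sprintf("TC%05d", i), cnt)
  })
  with_rep <- sprintf("TC%05d", seq_len(n_retained - n_no_reporter))
  map <- data.frame(tc_id = with_rep, platform = "genechip",
                    reporter_id = paste0("rep_", with_rep), score = 500,
                    stringsAsFactors = FALSE)
  class(map) <- c("reporter_map", "data.frame")
  set.seed(99)
  vals <- matrix(round(stats::rnorm(length(with_rep) * 2), 4), ncol = 2,
                 dimnames = list(paste0("rep_", with_rep), c("e1", "e2")))
  mat <- structure(list(matrix_id = "gc", platform = "genechip",
                        columns = c("e1", "e2"), values = vals),
                   class = "expression_matrix")
  config <- run_config(experiments = data.frame(matrix_id = "gc",
                                                column = c("e1", "e2"),
                                                stringsAsFactors = FALSE))
  list(catalog = catalog, selection = selection, tcs = tcs, map = map,
       matrices = list(mat), config = config)
}
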