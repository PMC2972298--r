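write_blast <- function(path, rows) {
  # qseqid sseqid pident length mism gapo qstart qend sstart send evalue bitscore
  writeLines(vapply(rows, function(r) {
    paste(r$q, r$s, "98.5", "120", "1", "0", "1", "120", "10", "130", "1e-30",
          r$bits, sep = "\t")
  }, character(1)), path)
}

test_that("simple reporter-map dialect reads rows verbatim", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tc_id\tplatform\treporter_id\tscore",
               "TC1\tgenechip\tmtr.1.s_at\t750.5",
               "TC2\toligo\tMT000123\t310"), f)
  map <- read_reporter_map(f)
  expect_equal(nrow(map), 2)
  expect_identical(map$reporter_id, c("mtr.1.s_at", "MT000123"))
  expect_equal(map$score, c(750.5, 310))
  expect_error(read_reporter_map(f, dialect = "bogus"), "dialect",
               class = "estarray_config_error")
})

test_that("blast_tab dialect keeps the best HSP per (reporter, TC) pair", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_blast(f, list(list(q = "rep1", s = "TC1", bits = "200.1"),
                      list(q = "rep1", s = "TC1", bits = "450.3"),
                      list(q = "rep2", s = "TC1", bits = "99.0")))
  map <- read_reporter_map(f, dialect = "blast_tab", platform = "genechip")
  expect_equal(nrow(map), 2)
  expect_equal(map$score[map$reporter_id == "rep1"], 450.3)
  expect_identical(unique(map$platform), "genechip")
  writeLines("rep1\tTC1\tonly-three-fields", f)
  expect_error(read_reporter_map(f, dialect = "blast_tab", platform = "p"),
               "line 1")
})

test_that("mixed-platform map equals concatenation of per-platform subsets", {
  fx <- small_study()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reporter_map(fx$reporter_map, f)
  whole <- read_reporter_map(f)
  parts <- do.call(rbind, lapply(unique(whole$platform), function(p) {
    whole[whole$platform == p, , drop = FALSE]
  }))
  key <- function(d) sort(paste(d$tc_id, d$platform, d$reporter_id, d$score))
  expect_identical(key(parts), key(whole))
})

join_toy <- function(map_rows, values, missing_policy = "drop",
                     aggregation = "mean") {
  catalog <- library_catalog(c("A", "B"), total_ests = c(100L, 100L))
  selection <- library_selection(catalog, must = "A")
  tcs <- lapply(sort(unique(c(map_rows$tc_id, "TCX"))), function(id) {
    tc_composition(id, c(A = 5))
  })
  rres <- compute_r_all(tcs, selection, catalog)
  class(map_rows) <- c("reporter_map", "data.frame")
  mat <- structure(list(matrix_id = "gc", platform = "genechip",
                        columns = colnames(values), values = values),
                   class = "expression_matrix")
  config <- run_config(experiments = data.frame(matrix_id = "gc",
                                                column = colnames(values),
                                                stringsAsFactors = FALSE),
                       missing_policy = missing_policy, aggregation = aggregation)
  join_profiles(tcs, rres, map_rows, list(mat), config)
}

test_that("multi-reporter values aggregate by policy; single reporter is policy-free", {
  map <- data.frame(tc_id = c("TC1", "TC1", "TC2"), platform = "genechip",
                    reporter_id = c("r1", "r2", "r3"), score = 500,
                    stringsAsFactors = FALSE)
  vals <- matrix(c(1, 3, 7), ncol = 1, dimnames = list(c("r1", "r2", "r3"), "e1"))
  for (pol in c("mean", "median", "max")) {
    got <- join_toy(map, vals, aggregation = pol)
    expect_equal(got$profiles[got$profiles$tc_id == "TC2", "gc.e1"], 7)
  }
  expect_equal(join_toy(map, vals)$profiles[1, "gc.e1"], 2)          # mean of 1, 3
  expect_equal(join_toy(map, vals, aggregation = "max")$profiles[1, "gc.e1"], 3)
})

test_that("TCs without reporters or with missing values drop with reason codes", {
  map <- data.frame(tc_id = c("TC1", "TC2"), platform = "genechip",
                    reporter_id = c("r1", "r2"), score = 500,
                    stringsAsFactors = FALSE)
  vals <- matrix(c(1.5, NA), ncol = 1, dimnames = list(c("r1", "r2"), "e1"))
  got <- join_toy(map, vals)  # TCX exists in compositions but not in the map
  expect_identical(sort(got$dropped$tc_id), c("TC2", "TCX"))
  expect_identical(got$dropped$reason[got$dropped$tc_id == "TCX"], "NO_REPORTER")
  expect_identical(got$dropped$reason[got$dropped$tc_id == "TC2"], "MISSING_VALUE")
  expect_identical(got$profiles$tc_id, "TC1")
  # impute policy keeps TC2 using the column mean of the matrix
  got2 <- join_toy(map, vals, missing_policy = "impute_column_mean")
  expect_true("TC2" %in% got2$profiles$tc_id)
  expect_equal(got2$profiles[got2$profiles$tc_id == "TC2", "gc.e1"], 1.5)
})

test_that("a configured experiment that does not exist aborts before any work", {
  fx <- small_study()
  bad <- run_config(experiments = data.frame(matrix_id = "genechip_expr",
                                             column = "no_such_column",
                                             stringsAsFactors = FALSE))
  retained <- filter_tcs(fx$compositions, fx$selection)
  rres <- compute_r_all(retained, fx$selection, fx$catalog)
  expect_error(join_profiles(retained, rres, fx$reporter_map, fx$matrices, bad),
               "no_such_column", class = "estarray_config_error")
})

test_that("joined profile count equals a brute-force recount on a random fixture", {
  fx <- generate_fixture(simulation_config(
    n_libraries = 6, library_size_range = c(200, 400), n_tcs = 100,
    n_condition_tcs = 15, n_condition_libraries = 2,
    reporter_dropout = 0.2, seed = 5))
  retained <- filter_tcs(fx$compositions, fx$selection)
  rres <- compute_r_all(retained, fx$selection, fx$catalog)
  got <- join_profiles(retained, rres, fx$reporter_map, fx$matrices, fx$run_config)
  platforms <- vapply(fx$matrices, `[[`, "", "platform")
  recount <- sum(vapply(retained, function(tc) {
    covered <- vapply(platforms, function(p) {
      any(fx$reporter_map$tc_id == tc$tc_id & fx$reporter_map$platform == p)
    }, logical(1))
    all(covered)  # fixture matrices have complete values for mapped reporters
  }, logical(1)))
  expect_identical(nrow(got$profiles), recount)
  expect_identical(nrow(got$profiles) + nrow(got$dropped), length(retained))
  expect_true(all(got$dropped$reason %in% c("NO_REPORTER", "MISSING_VALUE")))
})

test_that("profile export round-trips values at full precision in rank order", {
  fx <- small_study()
  retained <- filter_tcs(fx$compositions, fx$selection)
  rres <- compute_r_all(retained, fx$selection, fx$catalog)
  got <- join_profiles(retained, rres, fx$reporter_map, fx$matrices, fx$run_config)
  f <- withr::local_tempfile(fileext = ".csv")
  export_profiles(got$profiles, f)
  back <- read_profiles_csv(f)
  ord <- order(-got$profiles$r_value, got$profiles$tc_id)
  expect_identical(back$tc_id, got$profiles$tc_id[ord])
  expect_identical(back$r_value, got$profiles$r_value[ord])
  for (e in profile_experiments(got$profiles)) {
    expect_identical(back[[e]], got$profiles[[e]][ord])
  }
  expect_identical(attr(back, "reporters")[[back$tc_id[1]]],
                   attr(got$profiles, "reporters")[[back$tc_id[1]]])
  # empty profile list still yields a parseable header-only file
  empty <- got$profiles[0, ]
  attr(empty, "reporters") <- list(); attr(empty, "platforms") <- character()
  expect_warning(export_profiles(empty, f), "empty")
  expect_equal(nrow(utils::read.csv(f)), 0)
})
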