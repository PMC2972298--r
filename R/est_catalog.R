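#' Read a cDNA library catalog
#'
#' A library catalog lists the cDNA libraries of a gene index: for each
#' library its id token (DFCI-style ids such as `"#9CR"` are legal: `'#'` is
#' never treated as a comment character), a free-text name, and the total
#' number of ESTs sequenced from it (the library size N_i used by the
#' likelihood-ratio statistic).
#'
#' @param path Path to a tab-separated file with header columns
#'   `id`, `name`, `total_ests`.
#' @return A `library_catalog`: a data frame with columns `id` (character),
#'   `name` (character) and `total_ests` (integer), one row per library, in
#'   file order.
#' @export
read_library_catalog <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("id", "name", "total_ests")
  if (!all(need %in% names(df))) {
    stop_data("catalog ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("empty library catalog: ", path)
    return(library_catalog(character(), character(), integer()))
  }
  totals <- suppressWarnings(as.numeric(df$total_ests))
  bad <- which(is.na(totals) | totals < 0 | totals != floor(totals))
  if (length(bad)) {
    stop_data("catalog ", path, ": total_ests must be a nonnegative integer (data row ",
              bad[1], ")")
  }
  library_catalog(df$id, df$name, as.integer(totals))
}

#' Construct a library catalog in memory
#'
#' @param id Character vector of unique, non-empty library ids.
#' @param name Character vector of library names.
#' @param total_ests Integer vector of library sizes (ESTs sequenced).
#' @return A `library_catalog` data frame.
#' @export
library_catalog <- function(id, name = id, total_ests = 0L) {
  id <- as.character(id)
  if (any(!nzchar(id))) stop_data("library id must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop_data("duplicate library id: ", dup[1])
  total_ests <- as.integer(total_ests)
  if (any(is.na(total_ests) | total_ests < 0)) {
    stop_data("total_ests must be nonnegative")
  }
  out <- data.frame(id = id, name = as.character(name), total_ests = total_ests,
                    stringsAsFactors = FALSE)
  class(out) <- c("library_catalog", "data.frame")
  out
}

#' Write a library catalog to TSV
#' @param catalog A `library_catalog`.
#' @param path Output path.
#' @export
write_library_catalog <- function(catalog, path) {
  write_tsv_raw(as.data.frame(catalog)[, c("id", "name", "total_ests")], path)
  invisible(path)
}

#' Construct one TC composition
#'
#' A tentative consensus sequence (TC) is an assembled contig of ESTs; its
#' composition records how many ESTs from each library were assembled into it.
#' Zero counts are omitted; a TC must contain at least one EST.
#'
#' @param tc_id TC identifier, e.g. `"TC142142"`.
#' @param counts Named numeric vector, names are library ids, values EST counts.
#' @return A `tc_composition` object.
#' @export
tc_composition <- function(tc_id, counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0 || sum(counts) < 1) {
    stop_data("TC ", tc_id, " has no ESTs (all counts zero)")
  }
  if (any(counts < 0 | counts != floor(counts))) {
    stop_data("TC ", tc_id, ": counts must be nonnegative integers")
  }
  structure(list(tc_id = as.character(tc_id),
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "tc_composition")
}

#' Read TC compositions (wide layout)
#'
#' Wide layout: first column `tc_id`, one further column per library id,
#' integer EST counts in the cells. Zero cells are dropped from the counts
#' map; a TC whose whole row is zero is rejected.
#'
#' @param path Path to the TSV file.
#' @param catalog The `library_catalog`; every count column must name a
#'   library of this catalog.
#' @return List of `tc_composition`, in file order.
#' @export
read_tc_compositions <- function(path, catalog) {
  df <- read_tsv_raw(path)
  if (names(df)[1] != "tc_id") stop_data(path, ": first column must be tc_id")
  libs <- names(df)[-1]
  unknown <- setdiff(libs, catalog$id)
  if (length(unknown)) {
    stop_data(path, ": column '", unknown[1], "' is not a library of the catalog")
  }
  lapply(seq_len(nrow(df)), function(i) {
    x <- suppressWarnings(as.numeric(unlist(df[i, -1, drop = FALSE])))
    if (any(is.na(x))) stop_data(path, ": non-numeric count in data row ", i)
    if (sum(x) < 1) stop_data(path, ": TC ", df$tc_id[i], " has an all-zero row")
    tc_composition(df$tc_id[i], stats::setNames(x, libs))
  })
}

#' Read TC compositions (long layout)
#'
#' Long layout: columns `tc_id`, `library_id`, `count`, one row per nonzero
#' cell. Normalizes to the same representation as the wide reader; TCs keep
#' first-appearance order.
#'
#' @inheritParams read_tc_compositions
#' @return List of `tc_composition`.
#' @export
read_tc_compositions_long <- function(path, catalog) {
  df <- read_tsv_raw(path)
  need <- c("tc_id", "library_id", "count")
  if (!all(need %in% names(df))) {
    stop_data(path, " must have columns: ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(df$library_id), catalog$id)
  if (length(unknown)) {
    stop_data(path, ": unknown library id '", unknown[1], "'")
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt))) stop_data(path, ": non-numeric count")
  ids <- unique(df$tc_id)
  lapply(ids, function(tc) {
    sel <- df$tc_id == tc
    x <- tapply(cnt[sel], df$library_id[sel], sum)
    tc_composition(tc, stats::setNames(as.numeric(x), names(x)))
  })
}

#' Write TC compositions to a wide TSV
#'
#' @param tcs List of `tc_composition`.
#' @param catalog The `library_catalog` defining the column set and order.
#' @param path Output path.
#' @export
write_tc_compositions <- function(tcs, catalog, path) {
  mat <- composition_matrix(tcs, catalog)
  df <- data.frame(tc_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

#' Dense TC-by-library count matrix
#'
#' @inheritParams write_tc_compositions
#' @return Integer matrix, rows TCs (input order), columns catalog libraries.
#' @export
composition_matrix <- function(tcs, catalog) {
  mat <- matrix(0L, nrow = length(tcs), ncol = nrow(catalog),
                dimnames = list(vapply(tcs, `[[`, "", "tc_id"), catalog$id))
  for (i in seq_along(tcs)) {
    cc <- tcs[[i]]$counts
    mat[i, names(cc)] <- cc
  }
  mat
}

#' Construct a three-state library selection
#'
#' Each library of the catalog is assigned one of the states `MUST`
#' (retained TCs must have at least one EST from the MUST group, OR
#' semantics), `MUST_NOT` (no EST from any such library allowed) or `MAY`
#' (ignored). Libraries not listed default to `MAY`, the neutral state.
#'
#' @param catalog A `library_catalog`.
#' @param must Character vector of MUST library ids.
#' @param must_not Character vector of MUST_NOT library ids.
#' @return A `library_selection`: named character vector over all catalog ids.
#' @export
library_selection <- function(catalog, must = character(), must_not = character()) {
  unknown <- setdiff(c(must, must_not), catalog$id)
  if (length(unknown)) stop_data("selection names unknown library: ", unknown[1])
  both <- intersect(must, must_not)
  if (length(both)) stop_data("library in both MUST and MUST_NOT: ", both[1])
  states <- stats::setNames(rep("MAY", nrow(catalog)), catalog$id)
  states[must] <- "MUST"
  states[must_not] <- "MUST_NOT"
  structure(states, class = "library_selection")
}

#' Read a library selection from TSV
#'
#' Columns `id`, `state` with state in MUST / MUST_NOT / MAY. Catalog
#' libraries absent from the file default to MAY.
#'
#' @param path Path to the selection TSV.
#' @param catalog The `library_catalog`.
#' @return A `library_selection`.
#' @export
read_library_selection <- function(path, catalog) {
  df <- read_tsv_raw(path)
  if (!all(c("id", "state") %in% names(df))) {
    stop_data(path, " must have columns id, state")
  }
  bad <- setdiff(unique(df$state), c("MUST", "MUST_NOT", "MAY"))
  if (length(bad)) stop_data(path, ": invalid state '", bad[1], "'")
  library_selection(catalog,
                    must = df$id[df$state == "MUST"],
                    must_not = df$id[df$state == "MUST_NOT"])
}

#' Write a library selection to TSV
#' @param selection A `library_selection`.
#' @param path Output path.
#' @export
write_library_selection <- function(selection, path) {
  write_tsv_raw(data.frame(id = names(selection), state = as.character(selection),
                           stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Summarize a selection by state
#'
#' @param selection A `library_selection`.
#' @return Named integer vector `c(MUST = , MUST_NOT = , MAY = )`; the three
#'   counts sum to the catalog size.
#' @export
selection_summary <- function(selection) {
  s <- factor(as.character(selection), levels = c("MUST", "MUST_NOT", "MAY"))
  stats::setNames(as.integer(table(s)), levels(s))
}

#' Run configuration
#'
#' Bundles the knobs of a combined analysis: which experiment columns to
#' join, the cluster count, whether the likelihood ratio R enters the
#' clustering features, standardization, the multi-reporter aggregation
#' policy and the missing-value policy.
#'
#' @param experiments Data frame with columns `matrix_id`, `column`; the
#'   expression columns to join, in order.
#' @param k Cluster count (`NULL` means produce every cut from 2 to 8).
#' @param include_r_in_features Include R as the first clustering feature.
#' @param standardize Z-score feature columns; default `NULL` means on when
#'   R is mixed with expression columns, off otherwise.
#' @param aggregation Multi-reporter policy: `"mean"`, `"median"` or `"max"`.
#' @param missing_policy `"drop"` (exclude TCs with missing joined values)
#'   or `"impute_column_mean"`.
#' @param min_score Optional minimum reporter-mapping score.
#' @param seed Integer seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(experiments, k = NULL, include_r_in_features = TRUE,
                       standardize = NULL, aggregation = "mean",
                       missing_policy = "drop", min_score = NULL, seed = 1L) {
  experiments <- as.data.frame(experiments, stringsAsFactors = FALSE)
  if (!all(c("matrix_id", "column") %in% names(experiments)) || nrow(experiments) < 1) {
    stop_config("experiments must be a non-empty data frame with matrix_id, column")
  }
  if (!is.null(k) && (k < 1 || k != floor(k))) stop_config("k must be an integer >= 1")
  if (!aggregation %in% c("mean", "median", "max")) {
    stop_config("unknown aggregation policy: ", aggregation)
  }
  if (!missing_policy %in% c("drop", "impute_column_mean")) {
    stop_config("unknown missing policy: ", missing_policy)
  }
  structure(list(experiments = experiments,
                 k = if (is.null(k)) NULL else as.integer(k),
                 include_r_in_features = isTRUE(include_r_in_features),
                 standardize = standardize,
                 aggregation = aggregation,
                 missing_policy = missing_policy,
                 min_score = min_score,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file mirroring the [run_config()] fields;
#'   `experiments` is a list of `{matrix_id, column}` entries.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$experiments)) stop_config(path, ": config must list experiments")
  exps <- do.call(rbind, lapply(y$experiments, function(e) {
    data.frame(matrix_id = as.character(e$matrix_id), column = as.character(e$column),
               stringsAsFactors = FALSE)
  }))
  run_config(experiments = exps,
             k = y$k,
             include_r_in_features = if (is.null(y$include_r_in_features)) TRUE else y$include_r_in_features,
             standardize = y$standardize,
             aggregation = if (is.null(y$aggregation)) "mean" else y$aggregation,
             missing_policy = if (is.null(y$missing_policy)) "drop" else y$missing_policy,
             min_score = y$min_score,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  y <- list(experiments = lapply(seq_len(nrow(config$experiments)), function(i) {
    list(matrix_id = config$experiments$matrix_id[i],
         column = config$experiments$column[i])
  }))
  for (f in c("k", "include_r_in_features", "standardize", "aggregation",
              "missing_policy", "min_score", "seed")) {
    if (!is.null(config[[f]])) y[[f]] <- config[[f]]
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Validate a catalog/composition pair
#'
#' Checks the conservation constraint: for every library, the ESTs assembled
#' into TCs cannot exceed the library size (ESTs in no TC are singletons).
#' Violations are reported, not raised.
#'
#' @param catalog A `library_catalog`.
#' @param tcs List of `tc_composition`.
#' @return Data frame with one row per library: `id`, `total_ests`,
#'   `assembled` (sum over TCs) and logical `violation`.
#' @export
validate_fixture <- function(catalog, tcs) {
  assembled <- colSums(composition_matrix(tcs, catalog))
  out <- data.frame(id = catalog$id,
                    total_ests = catalog$total_ests,
                    assembled = as.integer(assembled[catalog$id]),
                    stringsAsFactors = FALSE)
  out$violation <- out$assembled > out$total_ests
  out
}
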