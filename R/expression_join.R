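#' Read a TC-to-reporter map
#'
#' Two dialects. `simple`: TSV with columns `tc_id`, `platform`,
#' `reporter_id`, `score`. `blast_tab`: standard 12-column tabular BLAST
#' output (query = reporter, subject = TC); the score is the bit score
#' (column 12) and only the best alignment per (reporter, TC) pair is kept;
#' the platform is supplied via `platform` because BLAST output carries none.
#'
#' @param path Path to the map file.
#' @param dialect `"simple"` or `"blast_tab"`.
#' @param platform Platform token, required for `blast_tab`.
#' @return A `reporter_map`: data frame with columns `tc_id`, `platform`,
#'   `reporter_id`, `score`; (tc, platform, reporter) triples unique.
#' @export
read_reporter_map <- function(path, dialect = "simple", platform = NULL) {
  if (!dialect %in% c("simple", "blast_tab")) {
    stop_config("unknown reporter-map dialect: ", dialect)
  }
  if (dialect == "simple") {
    df <- read_tsv_raw(path)
    need <- c("tc_id", "platform", "reporter_id", "score")
    if (!all(need %in% names(df))) {
      stop_data(path, " must have columns: ", paste(need, collapse = ", "))
    }
    score <- suppressWarnings(as.numeric(df$score))
    bad <- which(is.na(score))
    if (length(bad)) stop_data(path, ": non-numeric score on data row ", bad[1])
    out <- data.frame(tc_id = df$tc_id, platform = df$platform,
                      reporter_id = df$reporter_id, score = score,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(platform)) stop_config("blast_tab dialect requires a platform token")
    if (!file.exists(path)) stop_config("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    rows <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(rows)
    if (any(nf != 12)) {
      stop_data(path, ": malformed tabular BLAST row (line ", which(nf != 12)[1],
                ", expected 12 fields, got ", nf[nf != 12][1], ")")
    }
    m <- do.call(rbind, rows)
    bits <- suppressWarnings(as.numeric(m[, 12]))
    if (any(is.na(bits))) {
      stop_data(path, ": non-numeric bit score (line ", which(is.na(bits))[1], ")")
    }
    out <- data.frame(tc_id = m[, 2], platform = platform, reporter_id = m[, 1],
                      score = bits, stringsAsFactors = FALSE)
    # best HSP per (reporter, TC) pair
    out <- out[order(out$tc_id, out$reporter_id, -out$score), , drop = FALSE]
    out <- out[!duplicated(out[, c("tc_id", "reporter_id")]), , drop = FALSE]
  }
  dup <- duplicated(out[, c("tc_id", "platform", "reporter_id")])
  if (any(dup)) stop_data(path, ": duplicate (tc_id, platform, reporter_id) triple")
  rownames(out) <- NULL
  class(out) <- c("reporter_map", "data.frame")
  out
}

#' Write a reporter map (simple dialect)
#' @param map A `reporter_map`.
#' @param path Output path.
#' @export
write_reporter_map <- function(map, path) {
  df <- as.data.frame(map)
  df$score <- format_num(df$score)
  write_tsv_raw(df, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with first column `reporter_id`, remaining header fields the
#' experiment (column) ids; cells are real expression values, empty cells
#' mean missing. The value semantics (e.g. log2 expression ratio for
#' GeneChip contrasts, significance-test mean for two-channel oligo arrays)
#' are carried as platform metadata only; no renormalization is done.
#'
#' @param path Path to the TSV.
#' @param matrix_id Token identifying this matrix in run configs.
#' @param platform Platform token the reporters belong to.
#' @return An `expression_matrix`: list with `matrix_id`, `platform`,
#'   `columns` and `values` (numeric matrix, rownames = reporter ids,
#'   `NA` = missing).
#' @export
read_expression_matrix <- function(path, matrix_id, platform) {
  df <- read_tsv_raw(path)
  if (names(df)[1] != "reporter_id") stop_data(path, ": first column must be reporter_id")
  cols <- names(df)[-1]
  if (anyDuplicated(cols)) stop_data(path, ": duplicate experiment column id")
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- NA
  storage.mode(vals) <- "numeric"
  rownames(vals) <- df$reporter_id
  structure(list(matrix_id = as.character(matrix_id),
                 platform = as.character(platform),
                 columns = cols, values = vals),
            class = "expression_matrix")
}

#' Write an expression matrix to TSV
#' @param mat An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(reporter_id = rownames(mat$values), stringsAsFactors = FALSE)
  for (cl in mat$columns) df[[cl]] <- format_num(mat$values[, cl])
  write_tsv_raw(df, path)
  invisible(path)
}

experiment_key <- function(matrix_id, column) paste(matrix_id, column, sep = ".")

#' Join TCs to their reporter expression values
#'
#' Assembles the combined profile table: for each retained TC its likelihood
#' ratio R plus one value per configured experiment column. Reporters are
#' matched per platform (optionally score-filtered); multiple reporter
#' values for one experiment are aggregated by the configured policy
#' (default arithmetic mean). A TC with no reporter on a required platform
#' is dropped with reason `NO_REPORTER`; one with a missing joined value
#' under `missing_policy = "drop"` is dropped with reason `MISSING_VALUE`.
#' Retained = joined + dropped, always.
#'
#' @param retained List of `tc_composition` (the filter output).
#' @param rres R results covering `retained` (from [compute_r_all()]).
#' @param map A `reporter_map`.
#' @param matrices List of `expression_matrix`.
#' @param config A `run_config` naming the experiments.
#' @return List with `profiles` (a `combined_profiles` data frame: `tc_id`,
#'   `r_value`, one column per experiment key `matrix_id.column`, plus a
#'   `reporters` attribute mapping tc_id -> platform -> reporter ids) and
#'   `dropped` (data frame `tc_id`, `reason`).
#' @export
join_profiles <- function(retained, rres, map, matrices, config) {
  names(matrices) <- vapply(matrices, `[[`, "", "matrix_id")
  exps <- config$experiments
  for (i in seq_len(nrow(exps))) {
    m <- matrices[[exps$matrix_id[i]]]
    if (is.null(m)) stop_config("configured matrix not found: ", exps$matrix_id[i])
    if (!exps$column[i] %in% m$columns) {
      stop_config("configured experiment not found: ",
                  experiment_key(exps$matrix_id[i], exps$column[i]))
    }
  }
  keys <- experiment_key(exps$matrix_id, exps$column)
  required_platforms <- unique(vapply(exps$matrix_id, function(id) matrices[[id]]$platform, ""))

  if (!is.null(config$min_score)) map <- map[map$score >= config$min_score, , drop = FALSE]
  agg <- switch(config$aggregation,
                mean = function(v) mean(v),
                median = function(v) stats::median(v),
                max = function(v) max(v))
  col_means <- lapply(matrices, function(m) colMeans(m$values, na.rm = TRUE))

  rmap <- stats::setNames(rres$r_value, rres$tc_id)
  tc_ids <- vapply(retained, `[[`, "", "tc_id")
  values <- matrix(NA_real_, nrow = length(tc_ids), ncol = length(keys),
                   dimnames = list(tc_ids, keys))
  reporters_used <- vector("list", length(tc_ids))
  names(reporters_used) <- tc_ids
  reason <- rep(NA_character_, length(tc_ids))

  for (t in seq_along(tc_ids)) {
    tc <- tc_ids[t]
    ent <- map[map$tc_id == tc, , drop = FALSE]
    by_platform <- split(ent$reporter_id, ent$platform)
    if (!all(required_platforms %in% names(by_platform))) {
      reason[t] <- "NO_REPORTER"
      next
    }
    reporters_used[[t]] <- lapply(by_platform[required_platforms], sort)
    for (e in seq_len(nrow(exps))) {
      m <- matrices[[exps$matrix_id[e]]]
      reps <- intersect(by_platform[[m$platform]], rownames(m$values))
      v <- m$values[reps, exps$column[e]]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        if (config$missing_policy == "impute_column_mean") {
          values[t, e] <- col_means[[exps$matrix_id[e]]][exps$column[e]]
        }
        # else stays NA -> MISSING_VALUE below
      } else {
        values[t, e] <- agg(v)
      }
    }
    if (anyNA(values[t, ])) reason[t] <- "MISSING_VALUE"
  }

  keep <- is.na(reason)
  profiles <- data.frame(tc_id = tc_ids[keep],
                         r_value = unname(rmap[tc_ids[keep]]),
                         stringsAsFactors = FALSE)
  for (j in seq_along(keys)) profiles[[keys[j]]] <- values[keep, j]
  attr(profiles, "reporters") <- reporters_used[keep]
  attr(profiles, "platforms") <- required_platforms
  class(profiles) <- c("combined_profiles", "data.frame")
  dropped <- data.frame(tc_id = tc_ids[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(profiles = profiles, dropped = dropped)
}

#' Experiment keys of a profile table
#' @param profiles A `combined_profiles` data frame.
#' @return Character vector of `matrix_id.column` keys, in config order.
#' @export
profile_experiments <- function(profiles) {
  setdiff(names(profiles), c("tc_id", "r_value"))
}

#' Export combined profiles to CSV
#'
#' One row per TC in descending-R order: `tc_id`, one semicolon-joined
#' reporter column per platform, `r_value`, one column per experiment, and
#' optional annotation text.
#'
#' @param profiles A `combined_profiles` data frame.
#' @param path Output path.
#' @param annotation Optional data frame with columns `tc_id`, `annotation`.
#' @return The path, invisibly.
#' @export
export_profiles <- function(profiles, path, annotation = NULL) {
  reporters <- attr(profiles, "reporters")
  platforms <- attr(profiles, "platforms")
  if (nrow(profiles) == 0) warning("exporting an empty profile table")
  ord <- order(-profiles$r_value, profiles$tc_id)
  out <- data.frame(tc_id = profiles$tc_id[ord], stringsAsFactors = FALSE)
  for (p in platforms) {
    out[[paste0("reporters_", p)]] <- vapply(out$tc_id, function(tc) {
      paste(reporters[[tc]][[p]], collapse = ";")
    }, character(1))
  }
  out$r_value <- profiles$r_value[ord]
  for (e in profile_experiments(profiles)) out[[e]] <- profiles[[e]][ord]
  if (!is.null(annotation)) {
    out$annotation <- annotation$annotation[match(out$tc_id, annotation$tc_id)]
  }
  num <- c("r_value", profile_experiments(profiles))
  for (cl in num) out[[cl]] <- format_num(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Re-read an exported profile CSV
#'
#' Inverse of [export_profiles()] for the numeric content: returns a
#' `combined_profiles` table (rank order) with the reporters attribute
#' rebuilt from the reporter columns.
#'
#' @param path Path written by [export_profiles()].
#' @return A `combined_profiles` data frame.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  rep_cols <- grep("^reporters_", names(df), value = TRUE)
  platforms <- sub("^reporters_", "", rep_cols)
  keys <- setdiff(names(df), c("tc_id", "r_value", "annotation", rep_cols))
  out <- data.frame(tc_id = df$tc_id, r_value = as.numeric(df$r_value),
                    stringsAsFactors = FALSE)
  for (e in keys) out[[e]] <- as.numeric(df[[e]])
  reporters <- lapply(seq_len(nrow(df)), function(i) {
    stats::setNames(lapply(rep_cols, function(cl) {
      r <- df[[cl]][i]
      if (nzchar(r)) strsplit(r, ";", fixed = TRUE)[[1]] else character()
    }), platforms)
  })
  names(reporters) <- df$tc_id
  attr(out, "reporters") <- reporters
  attr(out, "platforms") <- platforms
  class(out) <- c("combined_profiles", "data.frame")
  out
}
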