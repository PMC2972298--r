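#' Integrated EST / microarray expression analysis
#'
#' Runs the full analysis in memory: three-state library filter, Stekel
#' log-likelihood ratio R, reporter join against the expression matrices,
#' Ward clustering of the combined profiles, dendrogram cuts, and (when an
#' annotation is supplied) per-cluster GO summaries.
#'
#' When `config$k` is set, only that cut is produced; otherwise every cut
#' from 2 to 8 (capped at the profile count) is produced, mirroring the
#' usual exploratory workflow. The GO summary is computed at `config$k`, or
#' at k = 4 when k is unset.
#'
#' @param catalog A `library_catalog`.
#' @param compositions List of `tc_composition`.
#' @param selection A `library_selection`.
#' @param reporter_map A `reporter_map`.
#' @param matrices List of `expression_matrix`.
#' @param config A `run_config`.
#' @param go Optional `go_annotation`.
#' @param go_top_n Terms per cluster in the GO summary.
#' @return An `estarray_analysis` object: list with `ranking` (R results in
#'   rank order), `profiles`, `dropped`, `features`, `dendrogram`, `cuts`
#'   (list of `cluster_assignment` by k), `size_table`, `go_summary`,
#'   `go_k`, `counts` (stage counts) and `config`.
#' @export
integrate_profiles <- function(catalog, compositions, selection, reporter_map,
                               matrices, config, go = NULL, go_top_n = 5) {
  n_input <- length(compositions)
  retained <- filter_tcs(compositions, selection)
  rres <- compute_r_all(retained, selection, catalog)
  joined <- join_profiles(retained, rres, reporter_map, matrices, config)
  profiles <- joined$profiles
  dropped <- joined$dropped
  stopifnot(nrow(profiles) + nrow(dropped) == length(retained))

  features <- build_feature_matrix(profiles, config)
  dendrogram <- ward_cluster(features)
  n <- nrow(profiles)
  if (!is.null(config$k) && config$k > n) {
    stop_data("k = ", config$k, " exceeds the number of joined profiles (", n, ")")
  }
  ks <- if (is.null(config$k)) 2:8 else config$k
  ks <- ks[ks <= n]
  cuts <- lapply(ks, function(k) cut_dendrogram(dendrogram, k))
  names(cuts) <- as.character(ks)
  size_table <- do.call(rbind, lapply(cuts, function(a) {
    c(a$sizes, rep(NA_integer_, max(ks) - a$k))
  }))
  if (!is.null(size_table)) {
    dimnames(size_table) <- list(paste0("k", ks), paste0("cluster", seq_len(max(ks))))
  }

  go_k <- if (is.null(config$k)) 4L else config$k
  go_k <- min(go_k, n)
  go_summary <- NULL
  if (!is.null(go)) {
    cut_go <- cuts[[as.character(go_k)]]
    if (is.null(cut_go)) cut_go <- cut_dendrogram(dendrogram, go_k)
    go_summary <- summarize_clusters(cut_go, go, top_n = go_top_n)
  }

  drop_by_reason <- table(factor(dropped$reason, levels = c("NO_REPORTER", "MISSING_VALUE")))
  counts <- list(n_input_tcs = n_input,
                 n_retained = length(retained),
                 n_joined = nrow(profiles),
                 n_dropped = nrow(dropped),
                 n_dropped_by_reason = stats::setNames(as.integer(drop_by_reason),
                                                       names(drop_by_reason)),
                 n_clustered = nrow(profiles))

  structure(list(ranking = rank_by_r(rres), profiles = profiles, dropped = dropped,
                 features = features, dendrogram = dendrogram, cuts = cuts,
                 size_table = size_table, go_summary = go_summary, go_k = go_k,
                 counts = counts, config = config),
            class = "estarray_analysis")
}

#' Stage counts of an analysis
#'
#' @param x An `estarray_analysis`.
#' @return Named list: `n_input_tcs`, `n_retained`, `n_joined`, `n_dropped`,
#'   `n_dropped_by_reason`, `n_clustered`.
#' @export
stage_counts <- function(x) {
  stopifnot(inherits(x, "estarray_analysis"))
  x$counts
}

#' @export
print.estarray_analysis <- function(x, ...) {
  cat("Integrated EST/microarray expression analysis\n")
  cat(sprintf("  TCs: %d input, %d retained by library filter, %d joined, %d dropped\n",
              x$counts$n_input_tcs, x$counts$n_retained, x$counts$n_joined,
              x$counts$n_dropped))
  cat(sprintf("  experiments: %s\n", paste(profile_experiments(x$profiles), collapse = ", ")))
  cat(sprintf("  cuts: k = %s\n", paste(names(x$cuts), collapse = ", ")))
  top <- utils::head(x$ranking, 3)
  cat("  top TCs by R:", paste(sprintf("%s (%.2f)", top$tc_id, top$r_value),
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.estarray_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$size_table)) {
    cat("\nCluster sizes per cut:\n")
    print(object$size_table, na.print = "")
  }
  if (!is.null(object$go_summary)) {
    cat(sprintf("\nTop GO categories per cluster (k = %d):\n", object$go_k))
    print(object$go_summary)
  }
  invisible(object)
}

#' Plot the dendrogram of an analysis
#'
#' @param x An `estarray_analysis`.
#' @param k Draw the cut line for this cluster count (default: the GO cut).
#' @param ... Passed to `plot.hclust`.
#' @export
plot.estarray_analysis <- function(x, k = x$go_k, ...) {
  h <- stats::as.hclust(x$dendrogram)
  plot(h, labels = FALSE, main = "Ward clustering of combined profiles",
       xlab = "", sub = "", ...)
  if (!is.null(k) && k > 1 && k <= length(h$height)) {
    n <- length(h$height) + 1
    cut_h <- mean(h$height[c(n - k, n - k + 1)])
    graphics::abline(h = cut_h, col = "red", lty = 2)
  }
  invisible(x)
}

#' Run the full pipeline on files
#'
#' File-level orchestration: reads all inputs, runs [integrate_profiles()],
#' and writes the result bundle to `outdir`: `profiles.csv` (rank order),
#' `dendrogram.tsv` and `dendrogram.nwk`, `labels_k<k>.tsv` per cut,
#' `cluster_sizes.tsv`, `go_summary.tsv` (when annotation given),
#' `coordinates.csv` (first three experiments, labels of the GO cut; only
#' when at least three experiments are configured) and `run.log` with the
#' stage counts. On any stage error the partial outputs are removed and the
#' error is re-raised with the stage name.
#'
#' @param catalog_file,compositions_file,selection_file,reporter_map_file
#'   Input TSV paths (see the corresponding readers).
#' @param matrix_files Named list: `matrix_id` -> list(path, platform).
#' @param config_file Run-config YAML path.
#' @param outdir Output directory.
#' @param go_file Optional GO annotation TSV.
#' @return The `estarray_analysis`, invisibly, with a `files` attribute.
#' @export
run_pipeline <- function(catalog_file, compositions_file, selection_file,
                         reporter_map_file, matrix_files, config_file, outdir,
                         go_file = NULL) {
  config <- read_run_config(config_file)
  catalog <- read_library_catalog(catalog_file)
  compositions <- read_tc_compositions(compositions_file, catalog)
  selection <- read_library_selection(selection_file, catalog)
  map <- read_reporter_map(reporter_map_file)
  matrices <- lapply(names(matrix_files), function(id) {
    read_expression_matrix(matrix_files[[id]]$path, id, matrix_files[[id]]$platform)
  })
  go <- if (!is.null(go_file)) read_go_annotation(go_file) else NULL

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(f) { written <<- c(written, f); f }
  res <- tryCatch({
    analysis <- integrate_profiles(catalog, compositions, selection, map,
                                   matrices, config, go = go)
    export_profiles(analysis$profiles, note(file.path(outdir, "profiles.csv")))
    write_dendrogram(analysis$dendrogram, note(file.path(outdir, "dendrogram.tsv")))
    write_dendrogram_newick(analysis$dendrogram, note(file.path(outdir, "dendrogram.nwk")))
    for (kk in names(analysis$cuts)) {
      write_cluster_labels(analysis$cuts[[kk]],
                           note(file.path(outdir, sprintf("labels_k%s.tsv", kk))))
    }
    st <- analysis$size_table
    st_df <- data.frame(k = rownames(st), st, check.names = FALSE,
                        stringsAsFactors = FALSE)
    utils::write.table(st_df, note(file.path(outdir, "cluster_sizes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    if (!is.null(analysis$go_summary)) {
      write_go_summary(analysis$go_summary, note(file.path(outdir, "go_summary.tsv")))
    }
    exps <- profile_experiments(analysis$profiles)
    if (length(exps) >= 3) {
      cut_go <- analysis$cuts[[as.character(analysis$go_k)]]
      if (is.null(cut_go)) cut_go <- cut_dendrogram(analysis$dendrogram, analysis$go_k)
      export_coordinates(analysis$profiles, cut_go, exps[1:3],
                         note(file.path(outdir, "coordinates.csv")))
    }
    cn <- analysis$counts
    log_lines <- c(
      sprintf("n_input_tcs\t%d", cn$n_input_tcs),
      sprintf("n_retained\t%d", cn$n_retained),
      sprintf("n_joined\t%d", cn$n_joined),
      sprintf("n_dropped\t%d", cn$n_dropped),
      sprintf("n_dropped_%s\t%d", names(cn$n_dropped_by_reason),
              cn$n_dropped_by_reason),
      sprintf("n_clustered\t%d", cn$n_clustered),
      sprintf("dropped\t%s\t%s", analysis$dropped$tc_id, analysis$dropped$reason))
    writeLines(log_lines, note(file.path(outdir, "run.log")))
    analysis
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  attr(res, "files") <- written
  invisible(res)
}
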