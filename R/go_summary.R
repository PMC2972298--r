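#' Normalize GO identifiers
#'
#' Accepts `"GO:0005524"`, `"0005524"` or the bare-number style `"5524"`
#' and normalizes to the zero-padded `"GO:0005524"` form. Idempotent.
#'
#' @param go_id Character vector of GO ids in any accepted form.
#' @return Character vector of normalized ids.
#' @export
normalize_go_id <- function(go_id) {
  num <- sub("^GO:", "", go_id)
  if (any(!grepl("^[0-9]+$", num))) {
    stop_data("non-numeric GO id: ", go_id[!grepl("^[0-9]+$", num)][1])
  }
  sprintf("GO:%07d", as.integer(num))
}

#' Read a GO annotation table
#'
#' TSV with columns `tc_id`, `go_id`, `namespace`, `name`. GO ids are
#' normalized (see [normalize_go_id()]); duplicate (tc, go) rows collapse to
#' one (set semantics). A TC may carry zero terms (it is simply absent).
#'
#' @param path Path to the TSV.
#' @return A `go_annotation`: data frame with columns `tc_id`, `go_id`,
#'   `namespace`, `name`, unique on (tc_id, go_id).
#' @export
read_go_annotation <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("tc_id", "go_id", "namespace", "name")
  if (!all(need %in% names(df))) {
    stop_data(path, " must have columns: ", paste(need, collapse = ", "))
  }
  num <- sub("^GO:", "", df$go_id)
  bad <- which(!grepl("^[0-9]+$", num))
  if (length(bad)) stop_data(path, ": non-numeric go_id on data row ", bad[1])
  valid_ns <- c("molecular_function", "biological_process", "cellular_component", "unknown")
  df$namespace[!df$namespace %in% valid_ns] <- "unknown"
  df$go_id <- normalize_go_id(df$go_id)
  df <- df[!duplicated(df[, c("tc_id", "go_id")]), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("go_annotation", "data.frame")
  df
}

#' Write a GO annotation table
#' @param annotation A `go_annotation`.
#' @param path Output path.
#' @export
write_go_annotation <- function(annotation, path) {
  write_tsv_raw(as.data.frame(annotation), path)
  invisible(path)
}

#' Per-cluster GO category summary
#'
#' For each cluster, counts the member TCs annotated with each GO term and
#' ranks terms by count (descending, ties by go_id ascending). This is
#' descriptive frequency counting of direct annotations -- no enrichment
#' test and no ancestor propagation along the GO graph.
#'
#' @param assignment A `cluster_assignment`.
#' @param annotation A `go_annotation`.
#' @param top_n Number of top terms per cluster (default 5).
#' @return Data frame with columns `cluster`, `rank`, `go_id`, `name`,
#'   `count`, `fraction` (of cluster size); clusters without any annotated
#'   member are listed in the `empty_clusters` attribute.
#' @export
summarize_clusters <- function(assignment, annotation, top_n = 5) {
  if (top_n < 1) stop_config("top_n must be >= 1")
  empty <- integer()
  rows <- lapply(seq_len(assignment$k), function(cl) {
    members <- names(assignment$labels)[assignment$labels == cl]
    ann <- annotation[annotation$tc_id %in% members, , drop = FALSE]
    if (nrow(ann) == 0) {
      empty <<- c(empty, cl)
      return(NULL)
    }
    counts <- stats::aggregate(list(count = ann$tc_id),
                               by = list(go_id = ann$go_id), FUN = length)
    counts$name <- ann$name[match(counts$go_id, ann$go_id)]
    counts <- counts[order(-counts$count, counts$go_id), , drop = FALSE]
    counts <- utils::head(counts, top_n)
    data.frame(cluster = cl, rank = seq_len(nrow(counts)),
               go_id = counts$go_id, name = counts$name, count = counts$count,
               fraction = counts$count / length(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = integer(), rank = integer(), go_id = character(),
                      name = character(), count = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "empty_clusters") <- empty
  out
}

#' Write a GO cluster summary to TSV
#' @param summary_df Output of [summarize_clusters()].
#' @param path Output path.
#' @export
write_go_summary <- function(summary_df, path) {
  df <- as.data.frame(summary_df)
  df$fraction <- format_num(df$fraction)
  write_tsv_raw(df, path)
  invisible(path)
}
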