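#' Build the clustering feature matrix
#'
#' Columns are the likelihood ratio R (optional, first) followed by the
#' configured experiment columns. When `standardize` is on, each column is
#' z-scored with the sample (n-1) standard deviation; a constant column is
#' mapped to all zeros with a warning. By default standardization is on
#' whenever R is mixed with expression columns (the scales differ by orders
#' of magnitude) and off otherwise.
#'
#' @param profiles A `combined_profiles` data frame.
#' @param config A `run_config`.
#' @return Numeric matrix, rownames = tc ids, columns `R` (optional) then
#'   experiment keys.
#' @export
build_feature_matrix <- function(profiles, config) {
  if (nrow(profiles) < 2) stop_data("clustering needs at least 2 profiles")
  keys <- profile_experiments(profiles)
  mat <- as.matrix(profiles[, keys, drop = FALSE])
  if (config$include_r_in_features) {
    mat <- cbind(R = profiles$r_value, mat)
  }
  rownames(mat) <- profiles$tc_id
  standardize <- config$standardize
  if (is.null(standardize)) {
    standardize <- config$include_r_in_features && length(keys) > 0
  }
  if (standardize) {
    for (j in seq_len(ncol(mat))) {
      s <- stats::sd(mat[, j])
      if (s == 0) {
        warning("constant feature column '", colnames(mat)[j], "' mapped to zeros")
        mat[, j] <- 0
      } else {
        mat[, j] <- (mat[, j] - mean(mat[, j])) / s
      }
    }
  }
  mat
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances (the Ward-D2 convention: the squared merge heights
#' accumulate twice the increase in within-cluster sum of squares). The
#' merge sequence is deterministic and its heights are nondecreasing.
#'
#' @param features Numeric matrix from [build_feature_matrix()]; rows >= 2,
#'   no missing values.
#' @return A `ward_dendrogram` (an `hclust` object with labels = tc ids).
#' @export
ward_cluster <- function(features) {
  if (nrow(features) < 2) stop_data("clustering needs at least 2 rows")
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_data("non-finite feature value at row '", rownames(features)[bad[1, 1]],
              "', column '", colnames(features)[bad[1, 2]], "'")
  }
  h <- stats::hclust(stats::dist(features, method = "euclidean"), method = "ward.D2")
  h$labels <- rownames(features)
  class(h) <- c("ward_dendrogram", "hclust")
  h
}

#' Merge table of a dendrogram
#'
#' @param dendrogram A `ward_dendrogram`.
#' @return Data frame with one row per merge: `left`, `right` (negative =
#'   leaf index, positive = earlier merge), `height`, `size` (leaves under
#'   the merged node).
#' @export
merge_table <- function(dendrogram) {
  n <- length(dendrogram$labels)
  size <- integer(n - 1)
  node_size <- function(v) ifelse(v < 0, 1L, size[v])
  for (i in seq_len(n - 1)) {
    size[i] <- node_size(dendrogram$merge[i, 1]) + node_size(dendrogram$merge[i, 2])
  }
  data.frame(left = dendrogram$merge[, 1], right = dendrogram$merge[, 2],
             height = dendrogram$height, size = size)
}

#' Write a dendrogram as a merge-list TSV
#' @param dendrogram A `ward_dendrogram`.
#' @param path Output path.
#' @export
write_dendrogram <- function(dendrogram, path) {
  mt <- merge_table(dendrogram)
  mt$height <- format_num(mt$height)
  df <- data.frame(left = mt$left, right = mt$right, height = mt$height,
                   size = mt$size, stringsAsFactors = FALSE)
  leaves <- paste(dendrogram$labels, collapse = ";")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#leaves\t", leaves), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a merge-list TSV dendrogram
#' @param path Path written by [write_dendrogram()].
#' @return A `ward_dendrogram`.
#' @export
read_dendrogram <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "#leaves\t")) stop_data(path, ": missing #leaves header")
  labels <- strsplit(sub("^#leaves\t", "", lines[1]), ";", fixed = TRUE)[[1]]
  df <- utils::read.delim(text = lines[-1], sep = "\t", comment.char = "",
                          stringsAsFactors = FALSE)
  h <- list(merge = cbind(df$left, df$right), height = df$height,
            labels = labels, method = "ward.D2", dist.method = "euclidean")
  # recompute the plotting order of leaves from the merge tree
  ord <- function(v) if (v < 0) -v else c(ord(h$merge[v, 1]), ord(h$merge[v, 2]))
  h$order <- ord(nrow(h$merge))
  class(h) <- c("ward_dendrogram", "hclust")
  h
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths are derived from the merge heights so external tree
#' viewers reproduce the dendrogram geometry.
#'
#' @param dendrogram A `ward_dendrogram`.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges. Cluster labels 1..k are assigned in order of
#' each cluster's first leaf in dendrogram leaf order, so the labelling is a
#' pure function of the tree.
#'
#' @param dendrogram A `ward_dendrogram`.
#' @param k Number of clusters, 1 <= k <= number of leaves.
#' @return A `cluster_assignment`: list with `k`, `labels` (named integer
#'   vector tc_id -> 1..k) and `sizes` (integer vector of length k).
#' @export
cut_dendrogram <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n || k != floor(k)) {
    stop_data("k must be an integer in 1..", n, " (got ", k, ")")
  }
  raw <- stats::cutree(stats::as.hclust(dendrogram), k = k)
  # relabel by first appearance along the dendrogram leaf order
  leaf_seq <- raw[dendrogram$order]
  relabel <- stats::setNames(seq_len(k), unique(leaf_seq))
  labels <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
  sizes <- as.integer(tabulate(labels, nbins = k))
  structure(list(k = as.integer(k), labels = labels, sizes = sizes),
            class = "cluster_assignment")
}

#' Write cluster labels to TSV
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @export
write_cluster_labels <- function(assignment, path) {
  write_tsv_raw(data.frame(tc_id = names(assignment$labels),
                           cluster = unname(assignment$labels),
                           stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read cluster labels from TSV
#' @param path Path written by [write_cluster_labels()].
#' @return A `cluster_assignment`.
#' @export
read_cluster_labels <- function(path) {
  df <- read_tsv_raw(path)
  labels <- stats::setNames(as.integer(df$cluster), df$tc_id)
  k <- max(labels)
  structure(list(k = k, labels = labels,
                 sizes = as.integer(tabulate(labels, nbins = k))),
            class = "cluster_assignment")
}

#' Export 3D coordinates for external scatter viewers
#'
#' Projects the profiles onto three chosen experiment columns and attaches
#' the cluster label, one row per TC.
#'
#' @param profiles A `combined_profiles` data frame.
#' @param assignment A `cluster_assignment` covering the profiles.
#' @param axes Character vector of three distinct experiment keys.
#' @param path Output CSV path.
#' @export
export_coordinates <- function(profiles, assignment, axes, path) {
  if (length(axes) != 3 || anyDuplicated(axes)) {
    stop_config("axes must be three distinct experiment ids")
  }
  missing_axis <- setdiff(axes, profile_experiments(profiles))
  if (length(missing_axis)) stop_config("unknown axis experiment: ", missing_axis[1])
  out <- data.frame(tc_id = profiles$tc_id,
                    x = format_num(profiles[[axes[1]]]),
                    y = format_num(profiles[[axes[2]]]),
                    z = format_num(profiles[[axes[3]]]),
                    cluster = unname(assignment$labels[profiles$tc_id]),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
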