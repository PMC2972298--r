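#' Logarithmic likelihood ratio R for one TC
#'
#' The Stekel et al. (2000) single-gene log-likelihood ratio measures how
#' unevenly a TC's ESTs distribute across cDNA libraries relative to the
#' library sizes. Over the used library set U (libraries in state MUST or
#' MAY with a positive size), with x_i the TC's EST count in library i,
#' N_i the library size and f = sum(x_i) / sum(N_i):
#'
#'   R = sum over i in U of x_i * ln( x_i / (N_i * f) )
#'
#' with the convention 0 * ln 0 = 0. R is in nats, nonnegative up to
#' floating error, and exactly 0 when counts are proportional to library
#' sizes or only one library is used. MUST_NOT libraries contribute nothing.
#' Higher R means more condition-specific expression.
#'
#' @param tc A `tc_composition`.
#' @param selection A `library_selection`.
#' @param catalog The `library_catalog` providing the library sizes.
#' @return A one-row data frame with columns `tc_id`, `r_value`,
#'   `n_libraries_used`, `total_counts_used`.
#' @export
compute_r <- function(tc, selection, catalog) {
  states <- as.character(selection)
  used <- names(selection)[states %in% c("MUST", "MAY")]
  if (length(used) == 0) stop_data("no MUST or MAY libraries: R is undefined")
  sizes <- stats::setNames(catalog$total_ests, catalog$id)[used]
  if (any(sizes == 0)) {
    warning("dropping ", sum(sizes == 0), " used librar",
            if (sum(sizes == 0) == 1) "y" else "ies", " with total_ests = 0")
    used <- used[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  if (length(used) == 0) stop_data("all used libraries have total_ests = 0")
  x <- stats::setNames(rep(0, length(used)), used)
  hits <- intersect(names(tc$counts), used)
  x[hits] <- tc$counts[hits]
  total_x <- sum(x)
  if (total_x == 0) {
    warning("TC ", tc$tc_id, " has no ESTs in the used libraries; R = 0")
    r <- 0
  } else {
    f <- total_x / sum(sizes)
    pos <- x > 0
    r <- sum(x[pos] * log(x[pos] / (sizes[pos] * f)))
    # clamp tiny negative floating error; R is >= 0 analytically
    if (r < 0 && r > -1e-12) r <- 0
  }
  data.frame(tc_id = tc$tc_id, r_value = r,
             n_libraries_used = length(used),
             total_counts_used = as.integer(total_x),
             stringsAsFactors = FALSE)
}

#' Compute R for a list of TCs
#'
#' @param tcs List of `tc_composition`.
#' @inheritParams compute_r
#' @return Data frame with one row per TC (input order), columns as in
#'   [compute_r()].
#' @export
compute_r_all <- function(tcs, selection, catalog) {
  out <- do.call(rbind, lapply(tcs, compute_r, selection = selection, catalog = catalog))
  if (is.null(out)) {
    out <- data.frame(tc_id = character(), r_value = numeric(),
                      n_libraries_used = integer(), total_counts_used = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Rank TCs by R
#'
#' Descending by `r_value`; ties broken by `tc_id` ascending, so the order
#' is total and deterministic.
#'
#' @param results Data frame as returned by [compute_r_all()].
#' @return The same data frame, reordered.
#' @export
rank_by_r <- function(results) {
  results[order(-results$r_value, results$tc_id), , drop = FALSE]
}
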