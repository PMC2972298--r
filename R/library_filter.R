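#' Filter TCs by a three-state library selection
#'
#' A TC is retained iff it has at least one EST from the MUST group (OR
#' semantics across MUST libraries) and zero ESTs from every MUST_NOT
#' library. MAY libraries never affect membership. With an empty MUST group
#' the MUST clause is vacuously true (the filter reduces to the MUST_NOT
#' exclusion); a warning is emitted because that case is usually a
#' misconfigured selection.
#'
#' @param tcs List of `tc_composition`.
#' @param selection A `library_selection`.
#' @return The retained subset of `tcs`, input order preserved.
#' @export
filter_tcs <- function(tcs, selection) {
  states <- as.character(selection)
  must <- names(selection)[states == "MUST"]
  must_not <- names(selection)[states == "MUST_NOT"]
  if (length(must) == 0) {
    warning("empty MUST group: the MUST clause is vacuously true")
  }
  keep <- vapply(tcs, function(tc) {
    cc <- tc$counts
    must_ok <- length(must) == 0 || sum(cc[names(cc) %in% must]) >= 1
    not_ok <- sum(cc[names(cc) %in% must_not]) == 0
    must_ok && not_ok
  }, logical(1))
  tcs[keep]
}
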