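# Classed conditions so the CLI can map failures to exit codes:
#   estarray_config_error -> 2, estarray_data_error -> 3, anything else -> 4.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("estarray_config_error", "estarray_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("estarray_data_error", "estarray_error")))
}

# TSV conventions shared by all readers: tab-separated, UTF-8, header row,
# and crucially no comment character -- DFCI-style library ids begin with '#'.
read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

# Deterministic numeric formatting for file output (byte-identical reruns).
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
}
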