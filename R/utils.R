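#' @useDynLib nightsong, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

SONG_CATEGORIES <- c("whistle", "trill", "buzz", "other")

# Classed conditions so callers/tests can distinguish malformed files
# (format) from files that parse but violate domain invariants (integrity).
abort_ns <- function(msg, class) {
  stop(structure(
    class = c(class, "nightsong_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
stop_format    <- function(msg) abort_ns(msg, "nightsong_format_error")
stop_integrity <- function(msg) abort_ns(msg, "nightsong_integrity_error")
stop_input     <- function(msg) abort_ns(msg, "nightsong_input_error")

# Delimiter auto-detection from the header line: tab wins over comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_format(sprintf("'%s' is empty", path))
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, required, what) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format(sprintf("%s '%s': missing column(s): %s",
                        what, path, paste(missing, collapse = ", ")))
  }
  df
}

write_delim_out <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stage-specific RNG seeds derived from one master seed so that individual
# pipeline stages are reproducible in isolation. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(sim = 11L, cv = 23L, loo = 37L, perm = 53L, misc = 71L)
  off <- offs[[stage]] %||% 97L
  as.integer((as.numeric(seed) * 101 + off) %% 2147483647)
}
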