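#' Construct a song sequence
#'
#' A song sequence is one male's ordered record of nocturnal songs, each
#' labelled with a song type and the song category that type belongs to
#' (whistle, trill, buzz, or other). It is the raw material for repertoire
#' measures and for the transition-network orderliness metrics.
#'
#' @param male_id single identifier.
#' @param song_type character vector of song-type labels, in singing order.
#' @param category character vector, same length, each one of
#'   \code{"whistle"}, \code{"trill"}, \code{"buzz"}, \code{"other"}.
#'   Category must be a fixed attribute of song type: a type may never carry
#'   two different categories.
#' @return An object of class \code{song_sequence}.
#' @export
song_sequence <- function(male_id, song_type, category) {
  if (length(song_type) < 1L) stop_input("song sequence must contain at least one song")
  if (length(song_type) != length(category)) {
    stop_input("song_type and category must have equal length")
  }
  song_type <- as.character(song_type)
  category <- as.character(category)
  bad <- setdiff(unique(category), SONG_CATEGORIES)
  if (length(bad) > 0L) {
    stop_integrity(sprintf("unknown song category label(s): %s (male %s)",
                           paste(bad, collapse = ", "), male_id))
  }
  ncat <- vapply(split(category, song_type), function(z) length(unique(z)), 1L)
  if (any(ncat > 1L)) {
    stop_integrity(sprintf(
      "song type(s) %s carry more than one category (male %s)",
      paste(names(ncat)[ncat > 1L], collapse = ", "), male_id))
  }
  structure(list(male_id = male_id, song_type = song_type, category = category),
            class = "song_sequence")
}

#' @export
length.song_sequence <- function(x) length(x$song_type)

#' @export
print.song_sequence <- function(x, ...) {
  cat(sprintf("<song_sequence> male %s: %d songs, %d types\n",
              x$male_id, length(x), length(unique(x$song_type))))
  invisible(x)
}

#' Read labelled song sequences from a delimited text file
#'
#' Expects columns \code{male_id}, \code{position}, \code{song_type},
#' \code{category} (comma- or tab-separated, auto-detected from the header).
#' Positions must run 1..L per male with no gaps, and category must be
#' consistent per song type across the whole corpus.
#'
#' @param path path to the file.
#' @return Named list of \code{\link{song_sequence}} objects, one per male,
#'   in order of first appearance.
#' @export
read_sequences <- function(path) {
  df <- read_delim_checked(path, c("male_id", "position", "song_type", "category"),
                           "song sequence file")
  df$male_id <- as.character(df$male_id)
  df$position <- as.integer(df$position)

  # category consistency is a corpus-wide invariant, not per male
  ncat <- vapply(split(df$category, df$song_type),
                 function(z) length(unique(z)), 1L)
  if (any(ncat > 1L)) {
    stop_integrity(sprintf("song type(s) %s appear with more than one category",
                           paste(names(ncat)[ncat > 1L], collapse = ", ")))
  }

  males <- unique(df$male_id)
  out <- lapply(males, function(m) {
    sub <- df[df$male_id == m, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    expect <- seq_len(nrow(sub))
    if (!identical(sub$position, expect)) {
      at <- which(sub$position != expect)[1L]
      stop_integrity(sprintf(
        "male %s: positions are not consecutive (expected %d, found %d)",
        m, expect[at], sub$position[at]))
    }
    song_sequence(m, sub$song_type, sub$category)
  })
  names(out) <- males
  out
}

#' Repertoire and category measures for one male
#'
#' Counts the distinct song types (repertoire size), the distinct types per
#' category (whistle/trill/buzz repertoire sizes) and the number of songs per
#' category irrespective of type (occurrences), over the first \code{window}
#' songs of the sequence. Field studies of nightingale song conventionally use
#' 533 consecutive songs (about one hour of singing), which saturates the
#' repertoire accumulation curve.
#'
#' If the sequence is shorter than \code{window} the full sequence is used,
#' the realised window length is recorded, and a warning is emitted.
#'
#' @param seq a \code{\link{song_sequence}}.
#' @param window number of consecutive songs to analyse (default 533).
#' @return One-row data frame of class \code{repertoire_summary}.
#' @export
compute_repertoire <- function(seq, window = 533L) {
  stopifnot(inherits(seq, "song_sequence"))
  L <- length(seq)
  if (L < 1L) stop_input("empty song sequence")
  if (L < window) {
    warning(sprintf("male %s: sequence length %d < window %d; using full sequence",
                    seq$male_id, L, window))
    window <- L
  }
  idx <- seq_len(window)
  ty <- seq$song_type[idx]
  ca <- seq$category[idx]
  n_types <- function(cat) length(unique(ty[ca == cat]))
  n_songs <- function(cat) sum(ca == cat)
  out <- data.frame(
    male_id = seq$male_id,
    repertoire_size = length(unique(ty)),
    whistle_repertoire = n_types("whistle"),
    whistle_occurrence = n_songs("whistle"),
    trill_repertoire = n_types("trill"),
    trill_occurrence = n_songs("trill"),
    buzz_repertoire = n_types("buzz"),
    buzz_occurrence = n_songs("buzz"),
    window_length = window,
    stringsAsFactors = FALSE
  )
  class(out) <- c("repertoire_summary", "data.frame")
  out
}

#' Repertoire accumulation curve
#'
#' Entry k is the number of distinct song types among the first k songs;
#' non-decreasing, ending at the full repertoire size.
#'
#' @param seq a \code{\link{song_sequence}}.
#' @return Integer vector of length \code{length(seq)}.
#' @export
accumulation_curve <- function(seq) {
  stopifnot(inherits(seq, "song_sequence"))
  if (length(seq) < 1L) stop_input("empty song sequence")
  cumsum(!duplicated(seq$song_type))
}

#' Descriptive statistics of song measures across males
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (CV = SD / mean) per measure. CV is flagged undefined (NA)
#' when the mean is zero, never silently reported as 0. Statistics are kept
#' at full precision; see \code{\link{format_measure_table}} for report-time
#' rounding.
#'
#' @param values data frame of per-male measure values (rows = males,
#'   numeric columns = measures); at least two males.
#' @return Data frame with columns measure, mean, sd, cv, cv_defined.
#' @export
describe_measures <- function(values) {
  values <- as.data.frame(values)
  num <- vapply(values, is.numeric, TRUE)
  values <- values[, num, drop = FALSE]
  if (nrow(values) < 2L) {
    abort_ns("describe_measures requires at least 2 males", "nightsong_statistics_error")
  }
  mu <- vapply(values, mean, 0)
  sd_ <- vapply(values, stats::sd, 0)
  defined <- mu != 0
  cv <- ifelse(defined, sd_ / mu, NA_real_)
  data.frame(measure = names(values), mean = unname(mu), sd = unname(sd_),
             cv = unname(cv), cv_defined = unname(defined),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Round a measure-statistics table for presentation
#'
#' @param stats output of \code{\link{describe_measures}}.
#' @param digits decimal places (default 2, the conventional presentation).
#' @return Data frame with rounded mean, sd and cv columns.
#' @export
format_measure_table <- function(stats, digits = 2L) {
  stats$mean <- round(stats$mean, digits)
  stats$sd <- round(stats$sd, digits)
  stats$cv <- round(stats$cv, digits)
  stats
}
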