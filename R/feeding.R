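#' Parse an RFID antenna registration log
#'
#' Reads a delimited text log with columns \code{male_id}, \code{timestamp}
#' (ISO-8601 to 1-second resolution, \code{"YYYY-MM-DD HH:MM:SS"} or with a
#' \code{T} separator) and \code{kind} (\code{arrival} or \code{departure}).
#' Duplicate identical rows are removed and events are sorted per male by
#' timestamp. All timestamps are interpreted in UTC.
#'
#' @param path path to the log file.
#' @return Data frame of class \code{antenna_events} with columns
#'   \code{male_id}, \code{timestamp} (POSIXct), \code{kind}.
#' @export
read_rfid_log <- function(path) {
  df <- read_delim_checked(path, c("male_id", "timestamp", "kind"), "RFID log")
  df$male_id <- as.character(df$male_id)
  df$kind <- as.character(df$kind)
  raw <- gsub("T", " ", as.character(df$timestamp), fixed = TRUE)
  ts <- as.POSIXct(raw, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(ts)) {
    line <- which(is.na(ts))[1L]
    stop_format(sprintf("RFID log '%s': unparseable timestamp '%s' at data line %d",
                        path, raw[line], line))
  }
  bad <- setdiff(unique(df$kind), c("arrival", "departure"))
  if (length(bad) > 0L) {
    stop_format(sprintf("RFID log '%s': unknown event kind(s): %s",
                        path, paste(bad, collapse = ", ")))
  }
  df$timestamp <- ts
  df <- df[!duplicated(df[, c("male_id", "timestamp", "kind")]), , drop = FALSE]
  df <- df[order(df$male_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("antenna_events", "data.frame")
  df
}

#' Collapse antenna registrations into nest visits
#'
#' A single approach to the antenna typically produces several registrations
#' within a few seconds. Consecutive registrations of one male separated by
#' less than \code{min_gap} seconds are merged into a single visit spanning
#' the first to the last registration; a gap of \code{min_gap} or more starts
#' a new visit. An isolated registration forms a zero-duration visit.
#'
#' @param events an \code{antenna_events} data frame (or any data frame with
#'   \code{male_id} and POSIXct \code{timestamp}).
#' @param min_gap merge threshold in seconds (default 60).
#' @return Data frame of class \code{visit_table}: \code{male_id},
#'   \code{start}, \code{end}.
#' @export
events_to_visits <- function(events, min_gap = 60) {
  stopifnot(is.data.frame(events), all(c("male_id", "timestamp") %in% names(events)))
  events <- events[order(events$male_id, events$timestamp), , drop = FALSE]
  pieces <- lapply(split(events$timestamp, events$male_id), function(ts) {
    gaps <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "secs"))
    grp <- cumsum(c(TRUE, gaps >= min_gap))
    data.frame(start = as.POSIXct(tapply(as.numeric(ts), grp, min),
                                  origin = "1970-01-01", tz = "UTC"),
               end = as.POSIXct(tapply(as.numeric(ts), grp, max),
                                origin = "1970-01-01", tz = "UTC"))
  })
  out <- do.call(rbind, pieces)
  out <- data.frame(male_id = rep(names(pieces), vapply(pieces, nrow, 1L)),
                    start = out$start, end = out$end,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$male_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("visit_table", "data.frame")
  out
}

tod_seconds <- function(t) {
  as.numeric(difftime(t, trunc(t, "days"), units = "secs"))
}

parse_hms <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  p <- c(p, 0L, 0L)[1:3]
  p[1L] * 3600 + p[2L] * 60 + p[3L]
}

#' Session feeding rates from nest visits
#'
#' For every male and recording day two session windows are evaluated:
#' morning, from the first visit of the day (before \code{morning_end}) until
#' \code{morning_end}; and evening, from \code{evening_start} until the last
#' visit of the day. The rate is the number of visits whose start time falls
#' in the window, divided by the window duration in hours. The morning window
#' is half-open at \code{morning_end}; the evening window is closed at its
#' last visit. Days with a zero-duration window or no qualifying visits yield
#' no session rate (rather than a deflating zero).
#'
#' @param visits a \code{visit_table}.
#' @param morning_end end of the morning window, \code{"HH:MM"} (default 10:00).
#' @param evening_start start of the evening window (default 18:00).
#' @return Data frame of class \code{session_rates}: \code{male_id},
#'   \code{date}, \code{session}, \code{window_start}, \code{window_end},
#'   \code{visit_count}, \code{rate} (visits per hour).
#' @export
session_rates <- function(visits, morning_end = "10:00", evening_start = "18:00") {
  stopifnot(is.data.frame(visits), all(c("male_id", "start") %in% names(visits)))
  m_end <- parse_hms(morning_end)
  e_start <- parse_hms(evening_start)
  rows <- list()
  day <- as.Date(visits$start, tz = "UTC")
  for (key in split(seq_len(nrow(visits)), list(visits$male_id, as.character(day)), drop = TRUE)) {
    st <- visits$start[key]
    tod <- tod_seconds(st)
    m <- visits$male_id[key][1L]
    d <- day[key][1L]
    # morning: [first visit, morning_end)
    morn <- tod < m_end
    if (any(morn)) {
      w0 <- min(tod[morn])
      dur <- (m_end - w0) / 3600
      if (dur > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          male_id = m, date = d, session = "morning",
          window_start = w0, window_end = m_end,
          visit_count = sum(morn), rate = sum(morn) / dur,
          stringsAsFactors = FALSE)
      }
    }
    # evening: [evening_start, last visit]
    eve <- tod >= e_start
    if (any(eve)) {
      w1 <- max(tod[eve])
      dur <- (w1 - e_start) / 3600
      if (dur > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          male_id = m, date = d, session = "evening",
          window_start = e_start, window_end = w1,
          visit_count = sum(eve), rate = sum(eve) / dur,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(male_id = character(), date = as.Date(character()),
               session = character(), window_start = numeric(),
               window_end = numeric(), visit_count = integer(),
               rate = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$male_id, out$date, out$session), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("session_rates", "data.frame")
  out
}

#' Per-male median feeding effort
#'
#' The composite feeding-effort measure is the median over all of a male's
#' session rates (standard midpoint convention for even counts).
#'
#' @param rates a \code{session_rates} data frame.
#' @return Data frame of class \code{feeding_summary}: \code{male_id},
#'   \code{median_rate}, \code{n_sessions}.
#' @export
summarize_feeding <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("male_id", "rate") %in% names(rates)))
  if (nrow(rates) == 0L) stop_input("no session rates to summarize")
  by <- split(rates$rate, rates$male_id)
  out <- data.frame(male_id = names(by),
                    median_rate = vapply(by, stats::median, 0),
                    n_sessions = vapply(by, length, 1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("feeding_summary", "data.frame")
  out
}

#' One-way ANOVA of session feeding rates between males
#'
#' Fixed-effects analysis of variance computed directly from the sums of
#' squares (between-male vs within-male session rates); the p-value comes
#' from the F distribution. A significant F indicates that feeding rates are
#' repeatable within males relative to the variation between males.
#'
#' @param rates a \code{session_rates} data frame (needs \code{male_id} and
#'   \code{rate}); at least two males and at least one male with two sessions.
#' @return List of class \code{anova_result}: \code{f_statistic},
#'   \code{df_between}, \code{df_within}, \code{p_value}, plus the three sums
#'   of squares.
#' @export
feeding_anova <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("male_id", "rate") %in% names(rates)))
  y <- rates$rate
  g <- as.character(rates$male_id)
  k <- length(unique(g))
  n <- length(y)
  if (k < 2L) stop_input("ANOVA requires at least 2 males")
  if (n - k < 1L) stop_input("ANOVA requires at least one male with >= 2 sessions")
  grand <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  ss_total <- sum((y - grand)^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ss_within == 0) {
    warning("within-male sum of squares is 0: F is infinite, p reported as 0")
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(f_statistic = f, df_between = df_b, df_within = df_w,
                 p_value = p, ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_total),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}
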