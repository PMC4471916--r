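rfid_file <- function(rows) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

ts <- function(x) as.POSIXct(x, tz = "UTC")

test_that("read_rfid_log parses, de-duplicates and rejects bad input", {
  rows <- data.frame(male_id = "m01",
                     timestamp = c("2011-06-01 08:00:00", "2011-06-01 08:00:03",
                                   "2011-06-01 08:10:00", "2011-06-01 19:00:00"),
                     kind = c("arrival", "departure", "arrival", "arrival"))
  ev <- read_rfid_log(rfid_file(rows))
  expect_equal(nrow(ev), 4L)
  expect_s3_class(ev$timestamp, "POSIXct")

  dup <- rbind(rows, rows[1, ])
  expect_equal(nrow(read_rfid_log(rfid_file(dup))), 4L)

  bad <- rows; bad$timestamp[2] <- "2011-06-01 25:61:00"
  err <- tryCatch(read_rfid_log(rfid_file(bad)), error = identity)
  expect_s3_class(err, "nightsong_format_error")
  expect_match(conditionMessage(err), "line")
})

test_that("events_to_visits merges registrations below the gap threshold", {
  t0 <- ts("2011-06-01 08:00:00")
  ev <- data.frame(male_id = "m01", timestamp = t0 + c(0, 3, 200),
                   kind = "arrival", stringsAsFactors = FALSE)
  v <- events_to_visits(ev, min_gap = 60)
  expect_equal(nrow(v), 2L)
  expect_equal(v$start[1], t0)
  expect_equal(v$end[1], t0 + 3)

  single <- events_to_visits(ev[1, ], min_gap = 60)
  expect_equal(nrow(single), 1L)
  expect_equal(single$start, single$end)

  # idempotence: re-collapsing the visit start times reproduces the visits
  again <- events_to_visits(
    data.frame(male_id = v$male_id, timestamp = v$start), min_gap = 60)
  expect_equal(again$start, v$start)

  # order invariance
  shuf <- ev[c(3, 1, 2), ]
  expect_equal(events_to_visits(shuf, min_gap = 60)$start, v$start)
})

test_that("session rates follow the window conventions", {
  day <- "2011-06-01 "
  # 10 visit starts uniformly over [08:00, 10:00), first exactly at 08:00
  starts <- ts(paste0(day, sprintf("%02d:%02d:00", 8 + (0:9) %/% 5, (0:9) %% 5 * 12)))
  v <- data.frame(male_id = "m01", start = starts, end = starts)
  r <- session_rates(v)
  expect_equal(nrow(r), 1L)
  expect_equal(r$session, "morning")
  expect_equal(r$rate, 10 / 2)

  # evening window is closed at the last visit
  ev_starts <- ts(paste0(day, c("18:30:00", "19:00:00", "20:00:00")))
  ve <- data.frame(male_id = "m01", start = ev_starts, end = ev_starts)
  re <- session_rates(ve)
  expect_equal(re$session, "evening")
  expect_equal(re$rate, 3 / 2)

  # a visit at exactly 18:00 alone gives a zero-duration evening window
  vz <- data.frame(male_id = "m01", start = ts(paste0(day, "18:00:00")),
                   end = ts(paste0(day, "18:00:00")))
  expect_equal(nrow(session_rates(vz)), 0L)

  # visits at/after morning_end are not morning visits
  vm <- data.frame(male_id = "m01", start = ts(paste0(day, "10:00:00")),
                   end = ts(paste0(day, "10:00:00")))
  expect_equal(nrow(session_rates(vm)), 0L)
})

test_that("per-male medians use the standard conventions", {
  r <- data.frame(male_id = c("a", "a", "b", "b", "b"),
                  rate = c(8, 12, 5, 11, 30))
  s <- summarize_feeding(r)
  expect_equal(s$median_rate[s$male_id == "a"], 10)
  expect_equal(s$median_rate[s$male_id == "b"], 11)
  expect_equal(s$n_sessions, c(2L, 3L))
  expect_error(summarize_feeding(r[0, ]), class = "nightsong_input_error")

  # sort-based median oracle on simulated males
  set.seed(14)
  sim <- data.frame(male_id = rep(sprintf("m%02d", 1:20), each = 9),
                    rate = rexp(180, 1 / 10))
  got <- summarize_feeding(sim)
  oracle <- vapply(split(sim$rate, sim$male_id), function(v) {
    sv <- sort(v)
    n <- length(sv)
    if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  }, 0)
  expect_equal(got$median_rate, unname(oracle[got$male_id]))
})

test_that("one-way ANOVA matches hand computation and closes the SS identity", {
  flat <- data.frame(male_id = rep(c("a", "b"), each = 2), rate = c(1, 3, 1, 3))
  expect_equal(feeding_anova(flat)$f_statistic, 0)

  r <- data.frame(male_id = rep(c("a", "b"), each = 3), rate = c(1, 2, 3, 4, 5, 6))
  a <- feeding_anova(r)
  expect_equal(a$f_statistic, 13.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  # cross-check against R's own ANOVA as an independent routine
  ref <- anova(lm(rate ~ male_id, data = r))
  expect_equal(a$f_statistic, ref$`F value`[1])
  expect_equal(a$p_value, ref$`Pr(>F)`[1])

  set.seed(3)
  for (i in 1:20) {
    rr <- data.frame(male_id = sample(letters[1:6], 60, TRUE), rate = rnorm(60))
    aa <- feeding_anova(rr)
    expect_equal(aa$ss_between + aa$ss_within, aa$ss_total,
                 tolerance = 1e-9)
  }

  ident <- data.frame(male_id = rep(c("a", "b"), each = 2), rate = c(1, 1, 5, 5))
  expect_warning(az <- feeding_anova(ident), "within")
  expect_equal(az$p_value, 0)

  expect_error(feeding_anova(data.frame(male_id = "a", rate = 1)),
               class = "nightsong_input_error")
})

test_that("between-male intensity variance produces a large F", {
  set.seed(8)
  lam <- exp(rnorm(12, log(10), 0.4))
  rr <- data.frame(male_id = rep(sprintf("m%02d", 1:12), each = 8),
                   rate = rpois(96, rep(lam * 4, each = 8)) / 4)
  a <- feeding_anova(rr)
  expect_gt(a$f_statistic, 1)
  expect_lt(a$p_value, 0.01)
})
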