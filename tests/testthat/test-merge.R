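utc <- function(s) as.POSIXct(s, tz = "UTC")

mini_tables <- function(seg_times, obs_times, obs_behaviour) {
  seg <- simulate_segment("Stand", seed = 1)
  n <- length(seg_times)
  list(
    fixes = tibble::tibble(bird_id = "b1", time = utc(seg_times),
                           lat = 53.48, lon = 6.2, alt_m = 1,
                           speed_ms = 0.1),
    segments = tibble::tibble(bird_id = "b1", start_time = utc(seg_times),
                              rate = 20, duration = 3,
                              x = rep(list(seg$x), n),
                              y = rep(list(seg$y), n),
                              z = rep(list(seg$z), n)),
    observations = tibble::tibble(
      bird_id = "b1", start_time = utc(obs_times),
      behaviour = obs_behaviour,
      sub_behaviour = vapply(obs_behaviour, function(b)
        behaviour_vocabulary()$sub_behaviour[
          behaviour_vocabulary()$behaviour == b][1], "")))
}

test_that("a segment inside one observation interval gets its behaviour", {
  tb <- mini_tables("2009-07-01 10:01:00",
                    c("2009-07-01 10:00:00", "2009-07-01 10:02:00"),
                    c("Forage", "Stand"))
  out <- label_records(tb$fixes, tb$segments, tb$observations)
  expect_equal(out$behaviour, "Forage")
  expect_false(out$ambiguous)
})

test_that("a change within the delay window makes the record ambiguous", {
  # segment [t0, t0+3]; change logged 4 s after t0: with up to 10 s
  # recording delay the change may in truth have fallen inside the segment
  tb <- mini_tables("2009-07-01 10:01:00",
                    c("2009-07-01 10:00:00", "2009-07-01 10:01:04"),
                    c("Forage", "Stand"))
  out <- label_records(tb$fixes, tb$segments, tb$observations)
  expect_true(out$ambiguous)
  # with no recording delay the same record is clean
  out0 <- label_records(tb$fixes, tb$segments, tb$observations,
                        max_delay_s = 0)
  expect_false(out0$ambiguous)
  expect_equal(out0$behaviour, "Forage")
})

test_that("segments outside any observation session stay unlabeled", {
  tb <- mini_tables("2009-07-01 12:00:00", "2009-07-01 10:00:00", "Forage")
  out <- label_records(tb$fixes, tb$segments, tb$observations)
  expect_true(is.na(out$behaviour))
})

test_that("zero-delay labeling recovers the generator truth exactly", {
  st <- simulate_study(study_config(n_birds = 1, n_days = 1,
                                    fix_interval_s = 300), seed = 4)
  out <- label_records(st$fixes, st$segments, st$observations,
                       max_delay_s = 0)
  labeled <- !is.na(out$behaviour)
  expect_gt(sum(labeled), 0)
  truth <- st$truth$behaviour[match(out$start_time[labeled],
                                    st$truth$time)]
  expect_equal(out$behaviour[labeled], truth)
})

test_that("filtering removes ambiguous, unlabeled and malformed records", {
  st <- simulate_study(study_config(n_birds = 1, n_days = 1), seed = 6)
  out <- label_records(st$fixes, st$segments, st$observations)
  out$ambiguous[] <- FALSE
  out$ambiguous[1:3] <- TRUE
  out$behaviour[1:3] <- "Stand"
  out$sub_behaviour[1:3] <- "Stand"
  out$x[[4]] <- out$x[[4]][1:59]   # malformed: 59 samples
  kept <- filter_records(out)
  rep <- attr(kept, "filter_report")
  expect_equal(rep$n[rep$reason == "ambiguous"], 3)
  expect_equal(rep$n[rep$reason == "malformed segment"], 1)
  expect_equal(nrow(kept), nrow(out) - sum(rep$n))
  expect_false(any(is.na(kept$behaviour)))
  # idempotence
  kept2 <- filter_records(kept)
  expect_equal(nrow(kept2), nrow(kept))
  expect_equal(sum(attr(kept2, "filter_report")$n), 0)
})

test_that("headers-only files read as empty collections", {
  d <- withr::local_tempdir()
  writeLines("bird_id,time_iso8601,lat,lon,alt_m,speed_ms",
             file.path(d, "fixes.csv"))
  writeLines(paste0("bird_id,start_time_iso8601,axis,",
                    paste0("s", 0:59, collapse = ",")),
             file.path(d, "segments.csv"))
  writeLines("bird_id,start_time_iso8601,behaviour,sub_behaviour",
             file.path(d, "observations.csv"))
  st <- read_study(d)
  expect_equal(nrow(st$fixes), 0)
  expect_equal(nrow(st$segments), 0)
  expect_equal(nrow(st$observations), 0)
})

test_that("empty speed fields parse as missing, not zero", {
  d <- withr::local_tempdir()
  writeLines(c("bird_id,time_iso8601,lat,lon,alt_m,speed_ms",
               "b1,2009-07-01T10:00:00Z,53.5,6.2,1.0,",
               "b1,2009-07-01T10:10:00Z,53.5,6.2,1.0,0.4"),
             file.path(d, "fixes.csv"))
  writeLines(paste0("bird_id,start_time_iso8601,axis,",
                    paste0("s", 0:59, collapse = ",")),
             file.path(d, "segments.csv"))
  writeLines("bird_id,start_time_iso8601,behaviour,sub_behaviour",
             file.path(d, "observations.csv"))
  st <- read_study(d)
  expect_true(is.na(st$fixes$speed_ms[1]))
  expect_equal(st$fixes$speed_ms[2], 0.4)
})

test_that("malformed rows and unknown labels are rejected with context", {
  d <- withr::local_tempdir()
  writeLines(c("bird_id,time_iso8601,lat,lon,alt_m,speed_ms",
               "b1,2009-07-01T10:00:00Z,53.5,six,1.0,"),
             file.path(d, "fixes.csv"))
  expect_error(read_study(d), "non-numeric")
  writeLines(c("bird_id,time_iso8601,lat,lon,alt_m,speed_ms"),
             file.path(d, "fixes.csv"))
  writeLines(paste0("bird_id,start_time_iso8601,axis,",
                    paste0("s", 0:59, collapse = ",")),
             file.path(d, "segments.csv"))
  writeLines(c("bird_id,start_time_iso8601,behaviour,sub_behaviour",
               "b1,2009-07-01T10:00:00Z,Forage,Moonwalk"),
             file.path(d, "observations.csv"))
  expect_error(read_study(d), "vocabulary")
})
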