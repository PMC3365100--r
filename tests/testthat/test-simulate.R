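test_that("zero-amplitude segment is the constant static gravity vector", {
  p <- signal_defaults()[signal_defaults()$behaviour == "Stand", ]
  p$noise_sd <- 0
  p$pitch_sd <- 0
  seg <- simulate_segment("Stand", p, seed = 1)
  expect_equal(nrow(seg), 60)
  expect_equal(seg$x, rep(sin(-20 * pi / 180), 60), tolerance = 1e-12)
  expect_equal(seg$y, rep(0, 60))
  expect_equal(seg$z, rep(cos(-20 * pi / 180), 60), tolerance = 1e-12)
})

test_that("segment simulation is deterministic given a seed", {
  a <- simulate_segment("Sit", seed = 1)
  b <- simulate_segment("Sit", seed = 1)
  expect_identical(a, b)
  expect_false(identical(simulate_segment("Sit", seed = 2), a))
})

test_that("fly segments carry their configured heave frequency", {
  # extractor as oracle: fdpsZ within one spectral bin (1/3 Hz) of 6 Hz
  for (s in 1:5) {
    seg <- simulate_segment("Fly", seed = s)
    sp <- spectral_features(seg$z - mean(seg$z))
    expect_lt(abs(sp$fdps - 6), 1 / 3 + 1e-12)
  }
})

test_that("unknown behaviour labels and bad configs are rejected", {
  expect_error(simulate_segment("Moonwalk"), "unknown behaviour")
  expect_error(study_config(transition = matrix(c(0.7, 0.2, 0.5, 0.5), 2,
                                                byrow = TRUE),
                            behaviours = c("Fly", "Sit"),
                            stationary = c(0.5, 0.5)),
               "sum to 1")
})

test_that("Markov behaviour frequencies approach the stationary law", {
  cfg <- study_config(n_birds = 1, n_days = 70, fix_interval_s = 600,
                      behaviours = c("Forage", "Stand"),
                      stationary = c(0.5, 0.5),
                      transition = matrix(0.5, 2, 2))
  seq_beh <- simulate_behaviour_sequence(cfg, 10000, seed = 7)
  freq <- table(seq_beh) / length(seq_beh)
  expect_lt(abs(freq[["Forage"]] - 0.5), 0.02)
})

test_that("fix count follows duration and interval", {
  cfg <- study_config(n_birds = 1, n_days = 31, fix_interval_s = 600)
  st <- simulate_study(cfg, seed = 3)
  expect_equal(nrow(st$fixes), 4464)
  expect_equal(nrow(st$segments), 4464)
})

test_that("study invariants hold: vocabulary, bbox, ordering, pairing", {
  st <- simulate_study(study_config(n_birds = 2, n_days = 1), seed = 5)
  expect_true(all(st$truth$behaviour %in% main_behaviours()))
  lons <- range(unlist(lapply(st$habitat$geometry, function(g) g[, "lon"])))
  lats <- range(unlist(lapply(st$habitat$geometry, function(g) g[, "lat"])))
  expect_true(all(st$fixes$lon >= lons[1] & st$fixes$lon <= lons[2]))
  expect_true(all(st$fixes$lat >= lats[1] & st$fixes$lat <= lats[2]))
  for (b in unique(st$fixes$bird_id)) {
    tt <- st$fixes$time[st$fixes$bird_id == b]
    expect_true(all(diff(as.numeric(tt)) > 0))
  }
  expect_equal(nrow(st$fixes), nrow(st$segments))
  expect_equal(st$fixes$time, st$segments$start_time)
})

test_that("writing a study is deterministic and byte-identical per seed", {
  cfg <- study_config(n_birds = 3, n_days = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg, seed = 11), d1)
  write_study(simulate_study(cfg, seed = 11), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  nests <- read.csv(file.path(d1, "nests.csv"))
  expect_equal(nrow(nests), 3)
})

test_that("write -> read round trip reproduces the study", {
  st <- simulate_study(study_config(n_birds = 1, n_days = 1), seed = 2)
  d <- withr::local_tempdir()
  write_study(st, d)
  rt <- read_study(d)
  expect_equal(rt$fixes, st$fixes, tolerance = 1e-12)
  expect_equal(rt$observations, st$observations)
  expect_equal(rt$truth, st$truth)
  expect_equal(rt$nests, st$nests, tolerance = 1e-12)
  expect_equal(rt$habitat$class, st$habitat$class)
  expect_equal(rt$habitat$geometry, st$habitat$geometry)
  expect_equal(length(rt$segments$x), length(st$segments$x))
  expect_equal(rt$segments$x[[5]], st$segments$x[[5]], tolerance = 1e-12)
})
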