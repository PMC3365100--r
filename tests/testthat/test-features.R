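test_that("static + dynamic reconstructs the raw signal exactly", {
  set.seed(1)
  for (method in c("segment-mean", "running-mean")) {
    x <- rnorm(60); y <- rnorm(60); z <- rnorm(60) + 1
    sd_ <- static_dynamic(x, y, z, method = method)
    expect_equal(sd_$static$x + sd_$dynamic$x, x, tolerance = 1e-12)
    expect_equal(sd_$static$y + sd_$dynamic$y, y, tolerance = 1e-12)
    expect_equal(sd_$static$z + sd_$dynamic$z, z, tolerance = 1e-12)
  }
  expect_error(static_dynamic(rnorm(60), rnorm(60), rnorm(60),
                              method = "running-mean", window_s = -1),
               "window_s")
})

test_that("segment-mean static equals the analytic mean of whole cycles", {
  t <- (0:59) / 20
  x <- 0.1 + 0.5 * sin(2 * pi * 2 * t)   # 2 Hz: 6 whole cycles in 3 s
  sd_ <- static_dynamic(x, rep(0, 60), rep(1, 60))
  expect_equal(sd_$static$x[1], 0.1, tolerance = 1e-9)
})

test_that("posture angles match the trigonometric oracle", {
  a <- posture_angles(c(0, 0, 1))
  expect_equal(unname(a), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(posture_angles(c(-0.5, 0, sqrt(3) / 2))[["pitchX"]], -30,
               tolerance = 1e-9)
  # scale invariance: only the direction matters
  v <- c(0, 0.4, 0.917)
  expect_equal(posture_angles(v), posture_angles(3.7 * v),
               tolerance = 1e-9)
  expect_equal(posture_angles(v)[["rollY"]],
               asin(0.4 / sqrt(sum(v^2))) * 180 / pi, tolerance = 1e-9)
  expect_error(posture_angles(c(0, 0, 0)), "degenerate")
})

test_that("dynamic body acceleration summaries follow their definitions", {
  zeros <- tibble::tibble(x = rep(0, 60), y = rep(0, 60), z = rep(0, 60))
  expect_true(all(dynamic_body_acceleration(zeros) == 0))

  sq <- zeros
  sq$y <- rep(c(0.2, -0.2), 30)
  dba <- dynamic_body_acceleration(sq)
  expect_equal(dba[["odbaY"]], 0.2)
  expect_equal(dba[["mdbaY"]], 0.2)
  expect_equal(dba[["odba"]], 0.2)

  t <- (0:59) / 20
  sine <- zeros
  sine$x <- 0.5 * sin(2 * pi * 1 * t)   # 3 whole cycles, 20 samples each
  dba <- dynamic_body_acceleration(sine)
  expect_lt(abs(dba[["odbaX"]] - 2 * 0.5 / pi) / (2 * 0.5 / pi), 0.02)
  expect_equal(dba[["odba"]], dba[["odbaX"]] + dba[["odbaY"]] +
                 dba[["odbaZ"]], tolerance = 1e-12)
  expect_lte(dba[["odbaX"]], dba[["mdbaX"]])
})

test_that("spectral features recover bin-aligned frequencies and power", {
  t <- (0:59) / 20
  v <- 0.3 * sin(2 * pi * 5 * t)        # k = 15 exactly
  sp <- spectral_features(v)
  expect_equal(sp$fdps, 5)
  sp2 <- spectral_features(2 * v)
  expect_equal(sp2$dps / sp$dps, 4, tolerance = 1e-9)
  # amplitude a in a single bin: PSD = a^2 / (2 * df)
  expect_equal(sp$dps, 0.3^2 / (2 * (20 / 60)), tolerance = 1e-9)
})

test_that("the periodogram integrates to the series variance (Parseval)", {
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(60, sd = runif(1, 0.01, 2))
    sp <- spectral_features(v)
    pvar <- mean((v - mean(v))^2)
    expect_equal(sum(sp$psd$psd) * 20 / 60, pvar, tolerance = 1e-9)
  }
})

test_that("fdps ties break to the lower frequency, degenerate flagged", {
  t <- (0:59) / 20
  v <- sin(2 * pi * 2 * t) + sin(2 * pi * 7 * t)  # equal power in 2 bins
  sp <- spectral_features(v)
  expect_equal(sp$fdps, 2)
  spz <- spectral_features(rep(0, 60))
  expect_true(spz$degenerate)
  expect_equal(spz$dps, 0)
  expect_equal(spz$fdps, 20 / 60)
})

test_that("scale equivariance: odba/mdba scale by |c|, dps by c^2", {
  seg <- simulate_segment("Forage", seed = 9)
  dyn <- static_dynamic(seg$x, seg$y, seg$z)$dynamic
  a <- dynamic_body_acceleration(dyn)
  scaled <- tibble::tibble(x = -3 * dyn$x, y = -3 * dyn$y, z = -3 * dyn$z)
  b <- dynamic_body_acceleration(scaled)
  expect_equal(unname(b), unname(a) * 3, tolerance = 1e-12)
  expect_equal(spectral_features(-3 * dyn$z)$dps,
               9 * spectral_features(dyn$z)$dps, tolerance = 1e-9)
})

test_that("extract_features composes the full 16-predictor vector", {
  const <- tibble::tibble(x = list(rep(0, 60)), y = list(rep(0, 60)),
                          z = list(rep(1, 60)), speed_ms = 0)
  f <- extract_features(const)
  expect_equal(f$odba, 0)
  expect_equal(f$speed, 0)
  expect_equal(f$pitchX, 0)
  expect_true(all(c("speed", "pitchX", "pitchZ", "rollY", "mdbaX", "mdbaY",
                    "mdbaZ", "odbaX", "odbaY", "odbaZ", "odba", "dpsX",
                    "dpsY", "dpsZ", "fdpsX", "fdpsY", "fdpsZ") %in%
                    names(f)))

  # missing speed propagates; acceleration features stay present
  seg <- simulate_segment("Walk", seed = 3)
  f2 <- extract_features(tibble::tibble(x = list(seg$x), y = list(seg$y),
                                        z = list(seg$z),
                                        speed_ms = NA_real_))
  expect_true(is.na(f2$speed))
  expect_false(anyNA(f2[setdiff(names(f2), c("speed", "speed_ms"))]))
})

test_that("fly segments have larger heave dps than forage segments", {
  for (s in 1:5) {
    fly <- simulate_segment("Fly", seed = s)
    forage <- simulate_segment("Forage", seed = s + 100)
    dps <- function(seg) {
      dyn <- static_dynamic(seg$x, seg$y, seg$z)$dynamic
      spectral_features(dyn$z)$dps
    }
    expect_gt(dps(fly), dps(forage))
  }
})
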