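test_that("budget proportions follow the counting definition", {
  cls <- tibble::tibble(
    bird_id = "b1",
    phase = rep("day", 10),
    habitat = rep("territory", 10),
    behaviour = c(rep("Forage", 6), rep("Stand", 4)))
  b <- compute_budget(cls)
  expect_equal(b$proportion[b$behaviour == "Forage"], 0.6)
  expect_equal(b$proportion[b$behaviour == "Stand"], 0.4)

  all_forage <- dplyr::mutate(cls, behaviour = "Forage")
  b2 <- compute_budget(all_forage)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$proportion, 1)
})

test_that("per-phase proportions sum to one over habitat x behaviour", {
  set.seed(4)
  cls <- tibble::tibble(
    bird_id = sample(c("b1", "b2"), 200, replace = TRUE),
    phase = sample(c("day", "night"), 200, replace = TRUE),
    habitat = sample(c("territory", "mudflats", "salt marsh"), 200,
                     replace = TRUE),
    behaviour = sample(c("Forage", "Stand", "Fly"), 200, replace = TRUE))
  b <- compute_budget(cls)
  sums <- dplyr::summarise(dplyr::group_by(b, bird_id, phase),
                           s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("adding a fix changes only its own cell and the phase total", {
  cls <- tibble::tibble(bird_id = "b1", phase = c("day", "day"),
                        habitat = c("territory", "mudflats"),
                        behaviour = c("Forage", "Stand"))
  b1 <- compute_budget(cls)
  b2 <- compute_budget(dplyr::bind_rows(
    cls, tibble::tibble(bird_id = "b1", phase = "day",
                        habitat = "mudflats", behaviour = "Stand")))
  expect_equal(b2$count[b2$behaviour == "Stand"], 2)
  expect_equal(b2$count[b2$behaviour == "Forage"], 1)
  expect_equal(b2$proportion[b2$behaviour == "Stand"], 2 / 3)
})

test_that("an empty deployment classifies to an empty table", {
  tr <- reference_accel_tree()
  empty_fix <- tibble::tibble(bird_id = character(),
                              time = as.POSIXct(character(), tz = "UTC"),
                              lat = numeric(), lon = numeric(),
                              alt_m = numeric(), speed_ms = numeric())
  empty_seg <- tibble::tibble(bird_id = character(),
                              start_time = as.POSIXct(character(),
                                                      tz = "UTC"),
                              rate = numeric(), duration = numeric(),
                              x = list(), y = list(), z = list())
  out <- classify_deployment(tr, empty_fix, empty_seg)
  expect_equal(nrow(out), 0)
  expect_true("behaviour" %in% names(out))
})

test_that("classification of a clean deployment recovers the truth", {
  feats <- simulate_labeled_features(
    n_per_class = 40, behaviours = c("Fly", "Forage", "Stand"), seed = 31)
  fit <- fit_behaviour_model(feats, model_spec("SA8", seed = 1))

  dep_tbl <- simulate_labeled_features(
    n_per_class = 50, behaviours = c("Fly", "Forage", "Stand"), seed = 32)
  dep_tbl2 <- simulate_labeled_features(
    n_per_class = 50, behaviours = c("Fly", "Forage", "Stand"), seed = 32)
  expect_identical(dep_tbl, dep_tbl2)   # generator determinism

  pred <- predict(fit, dep_tbl)
  acc <- mean(pred == dep_tbl$behaviour)
  expect_gt(acc, 0.9)
  expect_identical(pred, predict(fit, dep_tbl))
})

test_that("the deployment pipeline produces a coherent budget", {
  st <- simulate_study(study_config(n_birds = 1, n_days = 2,
                                    fix_interval_s = 1200), seed = 41)
  feats <- simulate_labeled_features(
    n_per_class = 40,
    behaviours = c("Fly", "Forage", "Body care", "Stand", "Sit"),
    seed = 42)
  fit <- fit_behaviour_model(feats, model_spec("SA8", seed = 1))
  res <- deployment_budget(fit, st)
  expect_equal(nrow(res$classified), nrow(st$fixes))
  expect_true(all(res$classified$phase %in% c("day", "night")))
  expect_true(all(res$classified$habitat %in%
                    c("territory", "salt marsh", "mudflats",
                      "unclassified")))
  sums <- dplyr::summarise(dplyr::group_by(res$budget, phase),
                           s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_s3_class(autoplot(res$budget), "ggplot")
})
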