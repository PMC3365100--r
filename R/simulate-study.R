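# A complete synthetic field campaign: several tagged birds, a fix every
# `fix_interval_s` seconds with a 3 s acceleration segment directly after
# each fix, visual-observation logs, nests, and a two-class habitat map
# (terrestrial salt marsh to the north, intertidal mudflats to the south).
# Behaviour follows a first-order Markov chain whose stationary
# distribution is known exactly, so recovered time budgets can be checked
# against it.

#' Configuration for a synthetic tracking study
#'
#' @param n_birds Number of tagged birds.
#' @param n_days Deployment duration in days.
#' @param fix_interval_s Seconds between GPS fixes.
#' @param start Deployment start (UTC), `POSIXct` or ISO-8601 string.
#' @param behaviours Behaviours included in the Markov chain; must be main
#'   behaviour labels.
#' @param transition Row-stochastic transition matrix over `behaviours`.
#'   The default is the independence chain (every row equals
#'   `stationary`), whose stationary distribution is exactly `stationary`
#'   and which mixes fast enough for time budgets over a deployment to
#'   track the stationary law closely; the self-transition probability of
#'   behaviour `b` is then `stationary[b]` (a ~17 min mean foraging bout
#'   at 10-min fixes). Pass a stickier matrix (e.g.
#'   `0.8 * diag(k) + 0.2 * outer(rep(1, k), stationary)`) for longer
#'   bouts, at the cost of wider sampling fluctuations in recovered
#'   budgets.
#' @param stationary Stationary behaviour frequencies used to build the
#'   default transition matrix. Defaults emulate a breeding shorebird in
#'   July: mostly foraging and roosting, very little flight.
#' @param signal_params Per-behaviour signal parameters
#'   (see [signal_defaults()]).
#' @param missing_speed_rate Fraction of fixes whose GPS speed is missing.
#' @param speed_noise_sd Std. dev. (m/s) of the GPS speed measurement
#'   error. Instantaneous GPS speed is too inaccurate to resolve slow
#'   terrestrial movement, so the reported speed is the true ground speed
#'   plus Gaussian noise, truncated at zero; the true speed still drives
#'   the movement model.
#' @param speed_glitch_rate Probability of a gross speed outlier
#'   (uniform on 0-5 m/s), emulating GPS dropouts and multipath errors.
#' @param recording_delay_s Maximum uniform lag (s) added to logged
#'   observation start times, emulating the handheld-computer recording
#'   delay. 0 disables the lag.
#' @param gps_noise_m Std. dev. (m) of additive position noise.
#' @return A `study_config` list.
#' @export
study_config <- function(n_birds = 3,
                         n_days = 31,
                         fix_interval_s = 600,
                         start = "2009-07-01T00:00:00Z",
                         behaviours = c("Fly", "Forage", "Body care",
                                        "Stand", "Sit"),
                         stationary = c(0.02, 0.40, 0.13, 0.25, 0.20),
                         transition = NULL,
                         signal_params = signal_defaults(),
                         missing_speed_rate = 0.01,
                         speed_noise_sd = 0.3,
                         speed_glitch_rate = 0.08,
                         recording_delay_s = 0,
                         gps_noise_m = 3) {
  assert_behaviour(behaviours)
  stopifnot(n_birds >= 1, n_days > 0, fix_interval_s > 0,
            length(stationary) == length(behaviours))
  stationary <- stationary / sum(stationary)
  if (is.null(transition)) {
    k <- length(behaviours)
    transition <- matrix(stationary, k, k, byrow = TRUE)
  }
  transition <- as.matrix(transition)
  if (nrow(transition) != length(behaviours) ||
      ncol(transition) != length(behaviours) ||
      any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  dimnames(transition) <- list(behaviours, behaviours)
  if (is.character(start)) {
    start <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  }
  structure(list(n_birds = n_birds, n_days = n_days,
                 fix_interval_s = fix_interval_s, start = start,
                 behaviours = behaviours, stationary = stationary,
                 transition = transition, signal_params = signal_params,
                 missing_speed_rate = missing_speed_rate,
                 speed_noise_sd = speed_noise_sd,
                 speed_glitch_rate = speed_glitch_rate,
                 recording_delay_s = recording_delay_s,
                 gps_noise_m = gps_noise_m),
            class = "study_config")
}

# Default landscape: a small coastal strip around 53.47 N, 6.23 E. The
# northern rectangle is terrestrial (salt marsh, nests), the southern one
# intertidal (mudflats).
default_habitat_map <- function() {
  terr <- cbind(lon = c(6.15, 6.31, 6.31, 6.15, 6.15),
                lat = c(53.475, 53.475, 53.50, 53.50, 53.475))
  tidal <- cbind(lon = c(6.15, 6.31, 6.31, 6.15, 6.15),
                 lat = c(53.44, 53.44, 53.475, 53.475, 53.44))
  tibble::tibble(class = c("terrestrial", "intertidal"),
                 geometry = list(terr, tidal))
}

.default_sub <- function(behaviour) {
  v <- .vocab()
  unname(vapply(behaviour, function(b)
    v$sub_behaviour[v$behaviour == b][1], ""))
}

#' Simulate a complete synthetic tracking study
#'
#' Draws a behaviour sequence per bird from the configured Markov chain,
#' simulates per-fix ground speed within the behaviour's speed range,
#' moves birds by a correlated random walk (step length = speed x fix
#' interval) reflected at the habitat-map boundary, simulates one
#' acceleration segment per fix, and writes an observation log entry at
#' every behaviour change (optionally lagged by a uniform recording delay).
#' Stationary behaviours are pulled back towards the nest so that roosting
#' happens on the terrestrial marsh.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the study is fully reproducible from it.
#' @return A `synthetic_study` list with tibbles `fixes`, `segments`,
#'   `observations`, `truth`, `nests` and the `habitat` polygon table.
#' @export
#' @examples
#' st <- simulate_study(study_config(n_birds = 1, n_days = 1), seed = 1)
#' nrow(st$fixes)
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  run_with_seed(seed, {
    habitat <- default_habitat_map()
    n_fix <- floor(config$n_days * 86400 / config$fix_interval_s)
    sp <- config$signal_params
    m_per_deg_lat <- 111320

    birds <- sprintf("bird%03d", seq_len(config$n_birds))
    nests <- tibble::tibble(
      bird_id = birds,
      lat = 53.478 + stats::runif(config$n_birds, 0.0005, 0.004),
      lon = 6.18 + stats::runif(config$n_birds, 0, 0.08))

    per_bird <- lapply(seq_len(config$n_birds), function(b) {
      beh <- simulate_behaviour_sequence(config, n_fix)
      times <- config$start + (seq_len(n_fix) - 1) * config$fix_interval_s

      prm <- sp[match(beh, sp$behaviour), ]
      speed <- stats::runif(n_fix, prm$speed_min, prm$speed_max)

      lat <- numeric(n_fix); lon <- numeric(n_fix)
      lat[1] <- nests$lat[b]; lon[1] <- nests$lon[b]
      heading <- stats::runif(1, 0, 2 * pi)
      moving <- prm$speed_max > 2 | prm$speed_min >= 0.2
      for (i in seq_len(n_fix - 1)) {
        if (moving[i]) {
          heading <- heading + stats::rnorm(1, 0, 0.6)
          step_m <- speed[i] * config$fix_interval_s
          # cap displacement so birds stay within the small study area
          step_m <- min(step_m, 1500)
          dlat <- step_m * cos(heading) / m_per_deg_lat
          dlon <- step_m * sin(heading) /
            (m_per_deg_lat * cos(lat[i] * pi / 180))
          lat[i + 1] <- lat[i] + dlat
          lon[i + 1] <- lon[i] + dlon
        } else {
          # roosting / stationary: drift back towards the nest
          lat[i + 1] <- lat[i] + 0.25 * (nests$lat[b] - lat[i])
          lon[i + 1] <- lon[i] + 0.25 * (nests$lon[b] - lon[i])
        }
        # reflect at the landscape bounding box
        lat[i + 1] <- reflect_into(lat[i + 1], 53.4405, 53.4995)
        lon[i + 1] <- reflect_into(lon[i + 1], 6.1505, 6.3095)
        if (lat[i + 1] > 53.4995 || lat[i + 1] < 53.4405) heading <- -heading
      }
      noise_deg <- config$gps_noise_m / m_per_deg_lat
      lat <- reflect_into(lat + stats::rnorm(n_fix, 0, noise_deg),
                          53.4405, 53.4995)
      lon <- reflect_into(lon + stats::rnorm(n_fix, 0, noise_deg),
                          6.1505, 6.3095)

      # reported GPS speed: true speed + measurement noise, floored at 0
      meas_speed <- pmax(0, speed +
                           stats::rnorm(n_fix, 0, config$speed_noise_sd))
      glitch <- stats::runif(n_fix) < config$speed_glitch_rate
      meas_speed[glitch] <- stats::runif(sum(glitch), 0, 5)
      meas_speed[stats::runif(n_fix) < config$missing_speed_rate] <-
        NA_real_
      fixes <- tibble::tibble(
        bird_id = birds[b], time = times, lat = lat, lon = lon,
        alt_m = round(stats::rnorm(n_fix, 2, 1), 1),
        speed_ms = meas_speed)

      segs <- lapply(seq_len(n_fix), function(i) {
        simulate_segment(beh[i], sp[sp$behaviour == beh[i], ])
      })
      segments <- tibble::tibble(
        bird_id = birds[b], start_time = times,
        rate = 20, duration = 3,
        x = lapply(segs, `[[`, "x"),
        y = lapply(segs, `[[`, "y"),
        z = lapply(segs, `[[`, "z"))

      chg <- c(TRUE, beh[-1] != beh[-n_fix])
      obs_time <- times[chg]
      if (config$recording_delay_s > 0) {
        obs_time <- obs_time +
          stats::runif(sum(chg), 0, config$recording_delay_s)
      }
      observations <- tibble::tibble(
        bird_id = birds[b], start_time = obs_time,
        behaviour = beh[chg], sub_behaviour = .default_sub(beh[chg]))

      truth <- tibble::tibble(bird_id = birds[b], time = times,
                              behaviour = beh)
      list(fixes = fixes, segments = segments, observations = observations,
           truth = truth)
    })

    structure(list(
      fixes = dplyr::bind_rows(lapply(per_bird, `[[`, "fixes")),
      segments = dplyr::bind_rows(lapply(per_bird, `[[`, "segments")),
      observations = dplyr::bind_rows(lapply(per_bird, `[[`, "observations")),
      truth = dplyr::bind_rows(lapply(per_bird, `[[`, "truth")),
      nests = nests, habitat = habitat, config = config),
      class = "synthetic_study")
  })
}

#' Draw a behaviour sequence from the configured Markov chain
#'
#' The chain starts in its stationary distribution and steps once per
#' GPS fix interval.
#'
#' @param config A [study_config()].
#' @param n_fix Number of fixes (chain length).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [simulate_study()]).
#' @return Character vector of behaviour labels, length `n_fix`.
#' @export
simulate_behaviour_sequence <- function(config, n_fix, seed = NULL) {
  stopifnot(inherits(config, "study_config"), n_fix >= 1)
  run_with_seed(seed, {
    beh <- character(n_fix)
    beh[1] <- sample(config$behaviours, 1, prob = config$stationary)
    for (i in seq_len(n_fix - 1)) {
      beh[i + 1] <- sample(config$behaviours, 1,
                           prob = config$transition[beh[i], ])
    }
    beh
  })
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(unique(x$fixes$bird_id)), " bird(s), ",
      nrow(x$fixes), " fixes, ", nrow(x$observations),
      " observation records\n", sep = "")
  invisible(x)
}
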