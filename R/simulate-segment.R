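# Synthetic 3 s / 20 Hz tri-axial acceleration segments. The signal model is
# deliberately simple: a static gravity component set by body pitch, one
# sinusoidal dynamic component per axis, optional short high-frequency
# bursts (prey handling / pecking), and white noise. It is the simplest
# family that reproduces the qualitative contrasts seen in field data:
# flight has large dynamic amplitude on all axes with a fast heave
# periodicity (flapping), foraging walks are slower and lower-amplitude
# with occasional bursts, body care shows small sway/heave movement with
# almost none on the surge axis, and standing vs sitting differ only in
# posture (pitch sign), not movement.

run_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default behaviour-specific signal parameters
#'
#' One row per main behaviour, giving the generative parameters of the
#' synthetic acceleration model and the ground-speed range. Per-axis
#' sinusoid amplitudes are multiplied by a per-segment intensity factor
#' drawn uniformly from `[scale_min, scale_max]`, reflecting how strongly
#' movement intensity varies between bouts of the same behaviour;
#' `burst_amp` sets the peak of the short 8 Hz transients; surge/sway
#' frequencies vary per segment by the fraction `freq_jitter_xy` while the
#' heave frequency stays fixed (flapping and body-bob periodicity is most
#' consistent dorso-ventrally). Amplitudes and
#' noise are in g, frequencies in Hz (all below the 10 Hz Nyquist limit of
#' 20 Hz sampling), pitch in degrees (negative = anterior tilted up, the
#' standing posture), speeds in m/s. `burst_rate` is the expected number of
#' short high-frequency bursts per 3 s segment.
#'
#' @return A tibble with columns `behaviour`, `pitch_deg`, `pitch_sd`
#'   (between-segment posture variability, deg), `amp_x`, `amp_y`,
#'   `amp_z`, `freq_x`, `freq_y`, `freq_z`, `burst_rate`, `noise_sd`,
#'   `speed_min`, `speed_max`.
#' @export
signal_defaults <- function() {
  tibble::tribble(
    ~behaviour,   ~pitch_deg, ~pitch_sd, ~amp_x, ~amp_y, ~amp_z, ~freq_x, ~freq_y, ~freq_z, ~freq_jitter_xy, ~scale_min, ~scale_max, ~burst_rate, ~burst_amp, ~noise_sd, ~speed_min, ~speed_max,
    "Fly",                 0,         4,   0.55,    0.5,    1.6,       4,       4,       6,             0.5,        0.8,       1.25,           0,          0,      0.05,        8.0,       15.0,
    "Forage",            -10,         4,    0.5,    0.4,    0.9,       2,       2,       2,             0.5,        0.5,        1.5,           1,        1.0,      0.04,        0.2,        1.2,
    "Body care",         -15,         4,   0.04,   0.15,   0.15,      3,  10 / 3,   8 / 3,             0.3,        0.7,        1.3,           0,          0,      0.05,        0.0,       0.15,
    "Stand",             -20,         4,      0,      0,      0,       0,       0,       0,               0,          1,          1,           0,          0,      0.02,        0.0,       0.15,
    "Sit",                 0,         4,      0,      0,      0,       0,       0,       0,               0,          1,          1,           0,          0,      0.02,        0.0,       0.15,
    "Walk",              -15,         4,   0.35,    0.2,   0.45,   5 / 3,   5 / 3,   5 / 3,             0.5,        0.6,        1.4,           0,          0,      0.04,        0.2,        1.2,
    "Handle",            -20,         4,   0.05,   0.08,   0.08,       3,       3,       3,             0.3,          1,          1,           2,        0.5,      0.03,        0.0,       0.15,
    "Aggression",        -15,         4,    0.2,    0.2,    0.2,  10 / 3,  10 / 3,  10 / 3,             0.3,        0.5,        1.5,         0.5,        0.5,      0.04,        0.0,        1.2
  )
}

validate_signal_params <- function(p) {
  stopifnot(is.data.frame(p))
  need <- c("behaviour", "pitch_deg", "pitch_sd", "amp_x", "amp_y", "amp_z",
            "freq_x", "freq_y", "freq_z", "freq_jitter_xy",
            "scale_min", "scale_max",
            "burst_rate", "burst_amp", "noise_sd", "speed_min",
            "speed_max")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0)
    stop("signal parameter columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  amp <- unlist(p[c("amp_x", "amp_y", "amp_z")])
  fr <- unlist(p[c("freq_x", "freq_y", "freq_z")])
  if (any(amp < 0) || any(p$noise_sd < 0) || any(p$burst_rate < 0) ||
      any(p$pitch_sd < 0) || any(p$burst_amp < 0) ||
      any(p$freq_jitter_xy < 0) || any(p$freq_jitter_xy >= 1) ||
      any(p$scale_min < 0) || any(p$scale_max < p$scale_min) ||
      any(p$speed_min < 0) || any(p$speed_max < p$speed_min))
    stop("amplitudes, noise, burst rate and speeds must be non-negative, ",
         "with speed_max >= speed_min", call. = FALSE)
  if (any(fr[amp > 0] <= 0) || any(fr > 10))
    stop("dominant frequencies must lie in (0, 10] Hz (Nyquist for 20 Hz)",
         call. = FALSE)
  invisible(p)
}

static_from_pitch <- function(pitch_deg) {
  sx <- sin(pitch_deg * pi / 180)
  c(x = sx, y = 0, z = sqrt(max(0, 1 - sx^2)))
}

#' Simulate one tri-axial acceleration segment
#'
#' Generates a 3 s segment at 20 Hz (60 samples per axis) for one behaviour:
#' static gravity implied by the behaviour's pitch, plus per-axis sinusoids,
#' optional bursts and Gaussian noise.
#'
#' @param behaviour A main behaviour label (see [main_behaviours()]).
#' @param params A one-row data frame of signal parameters for this
#'   behaviour; defaults to the matching row of [signal_defaults()].
#' @param seed Optional integer seed for reproducibility.
#' @param rate,duration Sampling rate (Hz) and duration (s).
#' @return A tibble with 60 rows and columns `t` (s), `x`, `y`, `z` (g).
#' @export
#' @examples
#' seg <- simulate_segment("Fly", seed = 1)
#' nrow(seg)
simulate_segment <- function(behaviour, params = NULL, seed = NULL,
                             rate = 20, duration = 3) {
  assert_behaviour(behaviour)
  if (is.null(params)) {
    params <- signal_defaults()[signal_defaults()$behaviour == behaviour, ]
  }
  validate_signal_params(params)
  run_with_seed(seed, {
    n <- rate * duration
    t <- (seq_len(n) - 1) / rate
    pitch <- params$pitch_deg + stats::rnorm(1, 0, params$pitch_sd)
    g0 <- static_from_pitch(pitch)
    # per-segment movement intensity: real locomotion bouts vary widely
    intensity <- stats::runif(1, params$scale_min, params$scale_max)
    amp <- intensity * c(params$amp_x, params$amp_y, params$amp_z)
    # surge/sway periodicity wanders between bouts; the heave (flapping
    # or body-bob) frequency is the consistent one
    jit <- stats::runif(2, 1 - params$freq_jitter_xy,
                        1 + params$freq_jitter_xy)
    frq <- c(params$freq_x * jit[1], params$freq_y * jit[2],
             params$freq_z)
    phase <- stats::runif(3, 0, 2 * pi)
    sig <- lapply(1:3, function(i) {
      g0[i] + amp[i] * sin(2 * pi * frq[i] * t + phase[i]) +
        stats::rnorm(n, 0, params$noise_sd)
    })
    n_burst <- stats::rpois(1, params$burst_rate)
    if (n_burst > 0) {
      for (b in seq_len(n_burst)) {
        # 0.3 s transient of fast, decaying shaking on all axes
        t0 <- stats::runif(1, 0, duration - 0.3)
        idx <- which(t >= t0 & t < t0 + 0.3)
        env <- exp(-8 * (t[idx] - t0))
        for (i in 1:3) {
          sig[[i]][idx] <- sig[[i]][idx] +
            params$burst_amp * env *
            sin(2 * pi * 8 * (t[idx] - t0) + phase[i])
        }
      }
    }
    tibble::tibble(t = t, x = sig[[1]], y = sig[[2]], z = sig[[3]])
  })
}

#' Simulate a balanced labeled feature set
#'
#' Draws `n_per_class` segments per behaviour, a ground speed from the
#' behaviour's speed range, extracts the full predictor set and attaches
#' the behaviour and its default sub-behaviour label. Useful for
#' calibration experiments where a balanced design is wanted rather than
#' a full study simulation.
#'
#' @param n_per_class Segments per behaviour.
#' @param behaviours Main behaviour labels to include.
#' @param params Signal parameter table (see [signal_defaults()]).
#' @param seed Integer seed.
#' @param missing_speed_rate Fraction of records with missing speed.
#' @param speed_noise_sd Std. dev. (m/s) of GPS speed measurement error
#'   added to the true ground speed (truncated at zero), emulating the
#'   poor accuracy of instantaneous GPS speed at low speeds.
#' @param speed_glitch_rate Probability that a fix's reported speed is a
#'   gross outlier (uniform on 0-5 m/s regardless of behaviour),
#'   emulating occasional GPS speed dropouts and multipath errors.
#' @return Tibble with `behaviour`, `sub_behaviour` and the feature
#'   columns of [extract_features()].
#' @export
simulate_labeled_features <- function(n_per_class = 300,
                                      behaviours = c("Fly", "Forage",
                                                     "Stand"),
                                      params = signal_defaults(),
                                      seed = 1,
                                      missing_speed_rate = 0,
                                      speed_noise_sd = 0.3,
                                      speed_glitch_rate = 0.08) {
  assert_behaviour(behaviours)
  run_with_seed(seed, {
    rows <- lapply(behaviours, function(b) {
      p <- params[params$behaviour == b, ]
      segs <- lapply(seq_len(n_per_class), function(i) simulate_segment(b, p))
      speed <- pmax(0, stats::runif(n_per_class, p$speed_min, p$speed_max) +
                      stats::rnorm(n_per_class, 0, speed_noise_sd))
      glitch <- stats::runif(n_per_class) < speed_glitch_rate
      speed[glitch] <- stats::runif(sum(glitch), 0, 5)
      speed[stats::runif(n_per_class) < missing_speed_rate] <- NA_real_
      tibble::tibble(behaviour = b, sub_behaviour = .default_sub(b),
                     speed_ms = speed,
                     x = lapply(segs, `[[`, "x"),
                     y = lapply(segs, `[[`, "y"),
                     z = lapply(segs, `[[`, "z"))
    })
    extract_features(dplyr::bind_rows(rows))
  })
}
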