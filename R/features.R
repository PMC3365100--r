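# The 16 predictors derived per GPS fix + 3 s acceleration segment:
#   speed                     3D GPS speed (m/s), passed through
#   pitchX, pitchZ, rollY     posture angles (deg) from static acceleration
#   mdbaX/Y/Z                 max |dynamic| per axis (g)
#   odbaX/Y/Z, odba           mean |dynamic| per axis and their sum (g)
#   dpsX/Y/Z                  dominant power spectral density (g^2/Hz)
#   fdpsX/Y/Z                 frequency at the dominant PSD (Hz)

#' Split a segment into static and dynamic acceleration
#'
#' The static (gravity/posture) component is the per-axis mean over the
#' whole segment by default, or a centred running mean; the dynamic
#' component is the remainder, so `static + dynamic` reconstructs the raw
#' signal exactly, sample-wise.
#'
#' @param x,y,z Numeric sample vectors (g), equal length.
#' @param method `"segment-mean"` (default) or `"running-mean"`.
#' @param window_s Running-mean window (s), used only for
#'   `method = "running-mean"`.
#' @param rate Sampling rate (Hz).
#' @return A list with `static` (tibble `x`, `y`, `z`, one row per sample)
#'   and `dynamic` (same shape). For the segment-mean method the static
#'   series is constant.
#' @export
static_dynamic <- function(x, y, z, method = c("segment-mean",
                                               "running-mean"),
                           window_s = 1, rate = 20) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n > 0)
  if (method == "segment-mean") {
    st <- lapply(list(x, y, z), function(v) rep(mean(v), n))
  } else {
    if (window_s <= 0 || window_s > n / rate)
      stop("window_s must be in (0, segment duration]", call. = FALSE)
    w <- max(1L, round(window_s * rate))
    st <- lapply(list(x, y, z), function(v) running_mean(v, w))
  }
  static <- tibble::tibble(x = st[[1]], y = st[[2]], z = st[[3]])
  dynamic <- tibble::tibble(x = x - st[[1]], y = y - st[[2]],
                            z = z - st[[3]])
  list(static = static, dynamic = dynamic)
}

# centred running mean, shrinking the window at the edges
running_mean <- function(v, w) {
  n <- length(v)
  half <- (w - 1) / 2
  cs <- cumsum(c(0, v))
  lo <- pmax(1, ceiling(seq_len(n) - half))
  hi <- pmin(n, floor(seq_len(n) + half))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Posture angles from a static acceleration vector
#'
#' Pitch and roll of the logger relative to gravity, computed from the
#' normalized static vector: `pitchX = asin(sx)`, `rollY = asin(sy)`,
#' `pitchZ = acos(sz)` — the tilt of the heave axis from the vertical
#' (degrees). A horizontal logger (static
#' pointing along +Z) gives all three angles 0. With the mounting
#' convention used here, an anterior-up (standing) posture tilts the surge
#' axis away from gravity and gives negative `pitchX`.
#'
#' @param static Numeric length-3 vector `(x, y, z)` of static
#'   acceleration (g); need not be unit length.
#' @return Named numeric vector `pitchX`, `pitchZ`, `rollY` (degrees).
#' @export
#' @examples
#' posture_angles(c(0, 0, 1))
#' posture_angles(c(-0.5, 0, sqrt(3) / 2))   # anterior up: pitchX = -30
posture_angles <- function(static) {
  stopifnot(length(static) == 3)
  nrm <- sqrt(sum(static^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("degenerate posture: static acceleration vector has zero norm",
         call. = FALSE)
  s <- static / nrm
  clamp <- function(v) pmin(1, pmax(-1, v))
  c(pitchX = asin(clamp(s[[1]])) * 180 / pi,
    pitchZ = acos(clamp(s[[3]])) * 180 / pi,
    rollY = asin(clamp(s[[2]])) * 180 / pi)
}

#' Dynamic body acceleration summaries
#'
#' Per-axis mean absolute dynamic acceleration (`odbaX/Y/Z`), their sum
#' (`odba`, overall dynamic body acceleration), and per-axis maximum
#' absolute dynamic acceleration (`mdbaX/Y/Z`).
#'
#' @param dynamic A data frame or list with numeric `x`, `y`, `z` dynamic
#'   series (g).
#' @return Named numeric vector `mdbaX`, `mdbaY`, `mdbaZ`, `odbaX`,
#'   `odbaY`, `odbaZ`, `odba`.
#' @export
dynamic_body_acceleration <- function(dynamic) {
  ax <- abs(dynamic$x); ay <- abs(dynamic$y); az <- abs(dynamic$z)
  od <- c(odbaX = mean(ax), odbaY = mean(ay), odbaZ = mean(az))
  c(mdbaX = max(ax), mdbaY = max(ay), mdbaZ = max(az), od,
    odba = sum(od))
}

#' Dominant power spectral density of a dynamic-acceleration series
#'
#' One-sided periodogram with a rectangular window on the frequency grid
#' `k * rate / n` for `k = 1..n/2` (DC excluded), normalized so that
#' `sum(PSD) * df` equals the population variance of the series
#' (Parseval). `dps` is the maximum PSD value and `fdps` the frequency at
#' which it occurs; when two bins tie, the lower frequency wins.
#'
#' @param v Numeric series (dynamic acceleration, g).
#' @param rate Sampling rate (Hz).
#' @return A list: `dps` (g^2/Hz), `fdps` (Hz), `psd` (tibble `freq`,
#'   `psd`), and `degenerate` (TRUE for an all-constant series, for which
#'   `dps = 0` and `fdps` is reported as the lowest bin).
#' @export
spectral_features <- function(v, rate = 20) {
  n <- length(v)
  stopifnot(n >= 4, n %% 2 == 0)
  df <- rate / n
  X <- fft(v)
  k <- seq_len(n / 2)
  p <- Mod(X[k + 1])^2 / (n^2 * df)
  p[k < n / 2] <- 2 * p[k < n / 2]    # fold negative frequencies in
  freq <- k * df
  degenerate <- max(p) <= 0
  # ties (within numerical precision) break to the lower frequency
  imax <- if (degenerate) 1L else
    which(p >= max(p) * (1 - 1e-9))[1]
  list(dps = p[imax], fdps = freq[imax],
       psd = tibble::tibble(freq = freq, psd = p),
       degenerate = degenerate)
}

feature_names <- function() {
  c("speed", "pitchX", "pitchZ", "rollY", "mdbaX", "mdbaY", "mdbaZ",
    "odbaX", "odbaY", "odbaZ", "odba", "dpsX", "dpsY", "dpsZ",
    "fdpsX", "fdpsY", "fdpsZ")
}

extract_one <- function(x, y, z, speed = NA_real_, rate = 20,
                        method = "segment-mean", window_s = 1) {
  sd_ <- static_dynamic(x, y, z, method = method, window_s = window_s,
                        rate = rate)
  st <- vapply(sd_$static, mean, numeric(1))
  ang <- posture_angles(st)
  dba <- dynamic_body_acceleration(sd_$dynamic)
  spx <- spectral_features(sd_$dynamic$x, rate)
  spy <- spectral_features(sd_$dynamic$y, rate)
  spz <- spectral_features(sd_$dynamic$z, rate)
  tibble::tibble(
    speed = speed,
    pitchX = ang[["pitchX"]], pitchZ = ang[["pitchZ"]],
    rollY = ang[["rollY"]],
    mdbaX = dba[["mdbaX"]], mdbaY = dba[["mdbaY"]], mdbaZ = dba[["mdbaZ"]],
    odbaX = dba[["odbaX"]], odbaY = dba[["odbaY"]], odbaZ = dba[["odbaZ"]],
    odba = dba[["odba"]],
    dpsX = spx$dps, dpsY = spy$dps, dpsZ = spz$dps,
    fdpsX = spx$fdps, fdpsY = spy$fdps, fdpsZ = spz$fdps)
}

#' Extract the 16 predictors for every record
#'
#' Computes posture, dynamic-body-acceleration and dominant-power-spectrum
#' predictors per segment and carries the GPS speed through. A missing
#' speed stays missing; all acceleration-derived predictors are always
#' present.
#'
#' @param records A tibble with list-columns `x`, `y`, `z` (one 60-sample
#'   series each per row), a `speed_ms` column (optional, may contain
#'   `NA`), and any identifying columns, e.g. the output of
#'   [label_records()] or the `segments` table of a study joined to its
#'   fixes.
#' @param method,window_s Static/dynamic separation method, see
#'   [static_dynamic()].
#' @return `records` without the sample list-columns, with the 17 feature
#'   columns (`speed` plus 16 acceleration-derived) appended.
#' @export
#' @examples
#' seg <- simulate_segment("Forage", seed = 2)
#' rec <- tibble::tibble(x = list(seg$x), y = list(seg$y), z = list(seg$z),
#'                       speed_ms = 0.8)
#' extract_features(rec)$odbaX
extract_features <- function(records, method = c("segment-mean",
                                                 "running-mean"),
                             window_s = 1) {
  method <- match.arg(method)
  stopifnot(all(c("x", "y", "z") %in% names(records)))
  speed <- if ("speed_ms" %in% names(records)) records$speed_ms else
    rep(NA_real_, nrow(records))
  rate <- if ("rate" %in% names(records)) records$rate else
    rep(20, nrow(records))
  feats <- purrr::pmap(
    list(records$x, records$y, records$z, speed, rate),
    function(x, y, z, sp, r) extract_one(x, y, z, sp, r, method = method,
                                         window_s = window_s))
  keep <- records[setdiff(names(records), c("x", "y", "z", "t"))]
  dplyr::bind_cols(keep, dplyr::bind_rows(feats))
}
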