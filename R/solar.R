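# Sunrise/sunset from the NOAA general solar position equations
# (low-accuracy ephemeris, good to well under a minute at temperate
# latitudes), used to split fixes into day and night at the fixed study
# reference coordinates.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# solar declination (deg) and equation of time (min) at Julian century T
solar_position <- function(T) {
  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C <- sin(deg2rad(M)) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * T) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 -
    T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(lambda))))
  y <- tan(deg2rad(eps / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) -
      1.25 * e^2 * sin(2 * deg2rad(M)))
  list(decl = decl, eot = eot)
}

#' Sunrise and sunset (UTC) for a calendar date
#'
#' NOAA solar-position algorithm with the standard refraction-corrected
#' zenith of 90.833 degrees. Iterates the hour-angle solution a few times
#' so declination and the equation of time are evaluated at the event
#' time rather than at noon.
#'
#' @param date A `Date` (or ISO date string), the UTC calendar date.
#' @param lat,lon Coordinates in decimal degrees (WGS84).
#' @return Tibble with `date`, `sunrise`, `sunset` (`POSIXct` UTC).
#'   Errors at latitudes with polar day or night on the requested date.
#' @export
#' @examples
#' sun_times("2009-07-15", lat = 53.47, lon = 6.23)
sun_times <- function(date, lat = 53.47, lon = 6.23) {
  date <- as.Date(date)
  out <- lapply(as.list(date), function(d) {
    jd0 <- as.numeric(d) + 2440587.5   # midnight UTC Julian day
    event_utc <- function(rise) {
      t_min <- 720                     # start at solar noon
      for (iter in 1:4) {
        T <- (jd0 + t_min / 1440 - 2451545) / 36525
        sp <- solar_position(T)
        cosH <- (cos(deg2rad(90.833)) /
                   (cos(deg2rad(lat)) * cos(deg2rad(sp$decl))) -
                   tan(deg2rad(lat)) * tan(deg2rad(sp$decl)))
        if (cosH > 1 || cosH < -1)
          stop("sun does not rise/set at latitude ", lat,
               " on ", format(d), " (polar day or night)", call. = FALSE)
        H <- rad2deg(acos(cosH))
        noon <- 720 - 4 * lon - sp$eot
        t_min <- if (rise) noon - 4 * H else noon + 4 * H
      }
      as.POSIXct(as.numeric(d) * 86400 + t_min * 60,
                 origin = "1970-01-01", tz = "UTC")
    }
    tibble::tibble(date = d, sunrise = event_utc(TRUE),
                   sunset = event_utc(FALSE))
  })
  dplyr::bind_rows(out)
}

#' Diel phase of UTC timestamps
#'
#' `"day"` iff `sunrise <= time < sunset` on the timestamp's UTC calendar
#' date at the reference coordinates (a fixed study site, not the per-fix
#' position); otherwise `"night"`. A fix exactly at sunrise is day,
#' exactly at sunset is night.
#'
#' @param time `POSIXct` UTC timestamps.
#' @param lat,lon Reference coordinates; defaults are the study site on
#'   the Wadden Sea coast (53.47 N, 6.23 E).
#' @return Character vector, `"day"` or `"night"`.
#' @export
#' @examples
#' diel_phase(as.POSIXct("2009-07-15 12:00:00", tz = "UTC"))
diel_phase <- function(time, lat = 53.47, lon = 6.23) {
  stopifnot(inherits(time, "POSIXct"))
  dates <- as.Date(time, tz = "UTC")
  ud <- unique(dates)
  st <- sun_times(ud, lat = lat, lon = lon)
  i <- match(dates, st$date)
  ifelse(time >= st$sunrise[i] & time < st$sunset[i], "day", "night")
}
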