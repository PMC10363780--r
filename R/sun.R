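# Sunrise/sunset from the NOAA solar-geometry equations (Julian-century
# series for the solar declination and the equation of time, zenith
# 90.833 degrees for refraction + solar radius). Accurate to well under a
# minute at mid latitudes, ample for anchoring rest phases sampled at
# 5-min resolution.

.julian_day <- function(date) {
  y <- as.integer(strftime(date, "%Y", tz = "UTC"))
  m <- as.integer(strftime(date, "%m", tz = "UTC"))
  d <- as.integer(strftime(date, "%d", tz = "UTC"))
  shift <- m <= 2
  y[shift] <- y[shift] - 1L; m[shift] <- m[shift] + 12L
  a <- y %/% 100L
  b <- 2L - a + a %/% 4L
  floor(365.25 * (y + 4716)) + floor(30.6001 * (m + 1)) + d + b - 1524.5
}

# declination (radians) and equation of time (minutes) at Julian century T
.sun_eqs <- function(T) {
  d2r <- pi / 180
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C <- sin(M * d2r) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * T) +
    sin(3 * M * d2r) * 0.000289
  omega <- 125.04 - 1934.136 * T
  app_long <- L0 + C - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(app_long * d2r))
  yv <- tan(eps * d2r / 2)^2
  eqtime <- 4 / d2r * (yv * sin(2 * L0 * d2r) - 2 * e * sin(M * d2r) +
                         4 * e * yv * sin(M * d2r) * cos(2 * L0 * d2r) -
                         0.5 * yv^2 * sin(4 * L0 * d2r) -
                         1.25 * e^2 * sin(2 * M * d2r))
  list(decl = decl, eqtime = eqtime)
}

#' Sunrise and sunset times
#'
#' NOAA solar-position equations with iterative refinement at the event
#' time; zenith 90.833 degrees (atmospheric refraction plus the solar
#' radius).
#'
#' @param lat,lon Degrees (north/east positive); `|lat|` must be below the
#'   polar circles.
#' @param date A `Date` vector.
#' @return Data frame with `date`, `sunrise` and `sunset` as POSIXct UTC.
#' @export
sun_times <- function(lat, lon, date) {
  if (abs(lat) >= 66)
    stop("latitudes at/beyond the polar circles are unsupported")
  d2r <- pi / 180
  jd <- .julian_day(date)
  event_utc <- function(rising) {
    minutes <- rep(720, length(date))
    for (k in 1:3) {
      T <- (jd + minutes / 1440 - 2451545) / 36525
      se <- .sun_eqs(T)
      cosha <- cos(90.833 * d2r) / (cos(lat * d2r) * cos(se$decl)) -
        tan(lat * d2r) * tan(se$decl)
      if (any(abs(cosha) > 1))
        stop("sun does not rise/set on some requested dates (polar day/night)")
      ha <- acos(cosha) / d2r
      minutes <- 720 - 4 * (lon + (if (rising) ha else -ha)) - se$eqtime
    }
    as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + minutes * 60,
               origin = "1970-01-01", tz = "UTC")
  }
  data.frame(date = date, sunrise = event_utc(TRUE), sunset = event_utc(FALSE))
}
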