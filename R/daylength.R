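# Seasonal covariate: sunrise-to-sunset duration from a NOAA-style solar
# position calculation. At 60 N the annual swing is roughly 6 h to 19 h of
# daylight, which is why the agreement models control for it.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Solar declination and related quantities per the NOAA solar calculator
# (Meeus-based low-precision series, adequate to well under 0.01 degrees).
noaa_declination <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  C <- sin(deg2rad(M)) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * T) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + 21.448 / 60) / 60 -
    (T * (46.815 + T * (0.00059 - T * 0.001813))) / 3600
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))  # radians
}

#' Day length (sunrise to sunset) in minutes
#'
#' Computes daylight duration for a calendar date and location from solar
#' declination and the sunrise hour angle, using the standard -0.833 degree
#' altitude for the solar limb plus atmospheric refraction. During polar day
#' the value clamps to 1440, during polar night to 0.
#'
#' @param date `Date` vector (or coercible).
#' @param latitude degrees north (default Helsinki, 60.17).
#' @param longitude degrees east (default Helsinki, 24.94); only used to pick
#'   the local solar-noon instant at which declination is evaluated.
#' @return numeric vector of minutes in `[0, 1440]`.
#' @export
#' @examples
#' day_length(as.Date("2019-06-21"))  # Helsinki midsummer, ~ 18.9 h
day_length <- function(date, latitude = 60.17, longitude = 24.94) {
  date <- as.Date(date)
  # Julian day at local solar noon
  jd <- as.numeric(date) + 2440587.5 + 0.5 - longitude / 360
  delta <- noaa_declination(jd)
  phi <- deg2rad(latitude)
  cos_ha <- (cos(deg2rad(90.833)) - sin(phi) * sin(delta)) /
    (cos(phi) * cos(delta))
  ha <- acos(pmin(1, pmax(-1, cos_ha)))
  out <- 8 * rad2deg(ha)  # 1 degree of hour angle = 8 min of daylight (x2)
  out[cos_ha >= 1] <- 0
  out[cos_ha <= -1] <- 1440
  out
}
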