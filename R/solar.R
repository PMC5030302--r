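#' Solar and sky configuration
#'
#' Location, date and clear-sky parameters for the diurnal light course.
#' Defaults are a tropical lowland rice site: latitude 14 N, day of year
#' 181 (30 June), atmospheric transmittance 0.5.  Irradiance is split into
#' a direct beam and an isotropic diffuse component with a simple
#' clear-sky two-component model (see [incident_ppfd()]).
#'
#' @param latitude degrees, positive north.
#' @param day_of_year 1--365.
#' @param transmittance atmospheric transmittance on (0, 1].
#' @param solar_constant PAR photon-flux solar constant,
#'   micromol m^-2 s^-1 (2600 is the conventional 400--700 nm conversion).
#' @param diffuse_coefficient fraction of the flux removed from the beam
#'   that reappears as diffuse sky light (Campbell--Norman style, 0.3).
#' @return A list of class `solar_config`.
#' @export
solar_config <- function(latitude = 14, day_of_year = 181,
                         transmittance = 0.5, solar_constant = 2600,
                         diffuse_coefficient = 0.3) {
  if (transmittance <= 0 || transmittance > 1) stop("transmittance must be in (0, 1]")
  if (solar_constant <= 0) stop("solar_constant must be positive")
  if (abs(latitude) > 90) stop("latitude must be in [-90, 90]")
  structure(list(latitude = latitude, day_of_year = day_of_year,
                 transmittance = transmittance,
                 solar_constant = solar_constant,
                 diffuse_coefficient = diffuse_coefficient),
            class = "solar_config")
}

#' Solar elevation and azimuth
#'
#' Standard declination / hour-angle astronomy with local solar time (no
#' equation-of-time or longitude correction): declination
#' `23.45 * sin(360 * (284 + d) / 365)` degrees and
#' `sin(beta) = sin(phi) sin(delta) + cos(phi) cos(delta) cos(H)` with hour
#' angle `H = 15 * (hour - 12)` degrees.
#'
#' @param cfg a [solar_config].
#' @param hour local solar time in hours, in \[0, 24).
#' @return Named vector `c(elevation, azimuth)` in degrees; azimuth 0 = N,
#'   clockwise (90 = E).
#' @export
solar_position <- function(cfg, hour) {
  stopifnot(inherits(cfg, "solar_config"), hour >= 0, hour < 24)
  d2r <- pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + cfg$day_of_year) / 365) * d2r
  phi <- cfg$latitude * d2r
  H <- 15 * (hour - 12) * d2r
  sinb <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  elev <- asin(pmin(1, pmax(-1, sinb))) / d2r
  east <- -cos(decl) * sin(H)
  north <- sin(decl) * cos(phi) - cos(decl) * sin(phi) * cos(H)
  az <- (atan2(east, north) / d2r) %% 360
  c(elevation = elev, azimuth = az)
}

#' Direct and diffuse PPFD for a solar elevation
#'
#' Clear-sky two-component model: with air mass `1/sin(beta)`,
#' `direct_normal = S0 * tau^(1/sin(beta))` and
#' `diffuse_horizontal = k_d * S0 * (1 - tau^(1/sin(beta))) * sin(beta)`.
#' Below the horizon both components are zero.
#'
#' @param cfg a [solar_config].
#' @param elevation solar elevation in degrees, in \[-90, 90\].
#' @return Named vector `c(direct_normal, diffuse_horizontal)` in
#'   micromol m^-2 s^-1.  `direct_normal` is the flux on a surface normal
#'   to the beam; the flux on a horizontal surface is
#'   `direct_normal * sin(beta) + diffuse_horizontal`.
#' @export
incident_ppfd <- function(cfg, elevation) {
  stopifnot(inherits(cfg, "solar_config"), abs(elevation) <= 90)
  if (elevation <= 0) {
    return(c(direct_normal = 0, diffuse_horizontal = 0))
  }
  sinb <- sin(elevation * pi / 180)
  tb <- cfg$transmittance^(1 / sinb)
  c(direct_normal = cfg$solar_constant * tb,
    diffuse_horizontal = cfg$diffuse_coefficient * cfg$solar_constant *
      (1 - tb) * sinb)
}

#' Photon travel direction for a solar position
#'
#' Unit vector of photon travel (from the sun toward the ground) in the
#' package's frame: x = east, y = north, z = up.
#'
#' @param elevation,azimuth solar position in degrees (azimuth 0 = N,
#'   clockwise), as returned by [solar_position()].
#' @return Length-3 unit vector with negative z for a sun above the
#'   horizon.
#' @export
sun_photon_direction <- function(elevation, azimuth) {
  d2r <- pi / 180
  -c(cos(elevation * d2r) * sin(azimuth * d2r),
     cos(elevation * d2r) * cos(azimuth * d2r),
     sin(elevation * d2r))
}
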