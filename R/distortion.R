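#' Wind specification
#'
#' Describes the steady wind used to distort a canopy: the compass direction
#' the wind blows FROM (0 = north, 90 = east) and the solid-body rotation
#' magnitude it induces.  Plants lean downwind: an easterly wind
#' (azimuth 90) tilts plants toward the west.
#'
#' @param azimuth degrees in \[0, 360), compass direction the wind comes
#'   from, or one of `"N"`, `"E"`, `"S"`, `"W"`.
#' @param angle solid-body rotation magnitude in degrees, in \[0, 90).
#' @return A list of class `wind_spec`.
#' @export
wind_spec <- function(azimuth, angle) {
  if (is.character(azimuth)) {
    azimuth <- c(N = 0, E = 90, S = 180, W = 270)[[toupper(azimuth)]]
  }
  azimuth <- azimuth %% 360
  if (angle < 0 || angle >= 90) stop("angle must be in [0, 90) degrees")
  structure(list(azimuth = azimuth, angle = angle), class = "wind_spec")
}

# Horizontal unit vector pointing downwind (direction plants lean toward).
downwind_vector <- function(azimuth_deg) {
  a <- azimuth_deg * pi / 180
  -c(sin(a), cos(a), 0)
}

#' Rigidly tilt a canopy (or single plant) downwind
#'
#' Applies a solid-body rotation of `wind$angle` degrees to every plant
#' about a horizontal axis through that plant's own base point at z = 0,
#' with the axis perpendicular to the wind azimuth, so each plant leans
#' downwind while its ground contact is preserved.  A rigid motion: face
#' areas and all pairwise distances are unchanged.
#'
#' @param x a `canopy_scene` or a [triangle_mesh] (rotated about the
#'   origin).
#' @param wind a [wind_spec].
#' @return Object of the same class as `x`, distorted.
#' @export
solid_body_rotate <- function(x, wind) {
  UseMethod("solid_body_rotate")
}

lean_rotation <- function(wind) {
  d <- downwind_vector(wind$azimuth)
  axis <- c(-d[2L], d[1L], 0)  # z-hat x d: rotating z toward d
  rotation_matrix(axis, wind$angle * pi / 180)
}

#' @export
solid_body_rotate.triangle_mesh <- function(x, wind) {
  stopifnot(inherits(wind, "wind_spec"))
  if (wind$angle == 0) return(x)
  transform_mesh(x, R = lean_rotation(wind))
}

#' @export
solid_body_rotate.canopy_scene <- function(x, wind) {
  stopifnot(inherits(wind, "wind_spec"))
  if (wind$angle == 0) return(x)
  R <- lean_rotation(wind)
  x$plants <- Map(function(p, i) {
    transform_mesh(p, R = R, pivot = c(x$positions[i, 1L],
                                       x$positions[i, 2L], 0))
  }, x$plants, seq_along(x$plants))
  x$wind <- wind
  x
}

#' Top-of-canopy horizontal displacement for a given tilt
#'
#' The horizontal displacement of the topmost vertex under a solid-body
#' rotation by `angle` about a horizontal axis through the base:
#' `height * sin(angle)`, reported in centimetres.  For the default 0.73 m
#' plant, 6 degrees gives 7.6 cm and 10 degrees gives 12.7 cm.
#'
#' @param mesh a [triangle_mesh] rooted at z = 0.
#' @param angle tilt in degrees, in \[0, 90).
#' @return Displacement in cm.
#' @export
tip_displacement <- function(mesh, angle) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  if (angle < 0 || angle >= 90) stop("angle must be in [0, 90) degrees")
  100 * max(mesh$vertices[, 3L]) * sin(angle * pi / 180)
}

#' Family of distorted scenes over a sweep of tilt angles
#'
#' Each returned scene is derived from the SAME undistorted input (the
#' distortion is not cumulative), as in a gust sweep from 0 to 10 degrees
#' in 1-degree increments.
#'
#' @param scene a `canopy_scene`.
#' @param wind_azimuth compass direction the wind is from (degrees or
#'   `"N"/"E"/"S"/"W"`).
#' @param angles strictly increasing tilt angles in degrees, each in
#'   \[0, 90).
#' @return A list of `canopy_scene`, one per angle.
#' @export
distortion_series <- function(scene, wind_azimuth, angles) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  lapply(angles, function(a) solid_body_rotate(scene, wind_spec(wind_azimuth, a)))
}
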