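#' Non-rectangular hyperbola parameters for one canopy layer
#'
#' The light response used to convert PPFD to net carbon uptake is a
#' non-rectangular hyperbola with quantum use efficiency `phi`, convexity
#' `theta`, capacity `pmax` and dark respiration `Rd = alpha * pmax`.
#' The canopy is parameterised in three layers with `pmax` 32 (top),
#' 21 (middle) and 5 (bottom) micromol CO2 m^-2 s^-1 and shared
#' `phi = 0.052`, `theta = 0.845`, `alpha = 0.1`.
#'
#' @param pmax maximum gross photosynthetic capacity,
#'   micromol CO2 m^-2 s^-1.
#' @param phi quantum use efficiency, mol CO2 per mol photons.
#' @param theta convexity, in (0, 1).
#' @param alpha ratio of dark respiration to `pmax`.
#' @return A list of class `nrh_params` with the derived `rd`.
#' @export
nrh_params <- function(pmax, phi = 0.052, theta = 0.845, alpha = 0.1) {
  if (pmax <= 0 || phi <= 0 || theta <= 0 || theta >= 1 || alpha < 0) {
    stop("invalid non-rectangular hyperbola parameters")
  }
  structure(list(phi = phi, theta = theta, pmax = pmax, alpha = alpha,
                 rd = alpha * pmax),
            class = "nrh_params")
}

#' Default per-layer parameter table
#'
#' @return Named list of [nrh_params] for layers `top`, `middle`, `bottom`
#'   (layer indices 1, 2, 3).
#' @export
nrh_layers <- function() {
  list(top = nrh_params(32), middle = nrh_params(21), bottom = nrh_params(5))
}

#' Net photosynthesis from the non-rectangular hyperbola
#'
#' Net CO2 uptake at irradiance `L`: the smaller root of
#' `theta F^2 - F (phi L + (1 + alpha) pmax) + phi L (1 + alpha) pmax = 0`
#' minus dark respiration `alpha * pmax`.  At `L = 0` this is `-Rd`; as
#' `L -> Inf` it approaches `pmax`.
#'
#' @param L PPFD, micromol photons m^-2 s^-1 (vectorised).
#' @param params an [nrh_params].
#' @return Net assimilation, micromol CO2 m^-2 s^-1.
#' @export
nrh <- function(L, params) {
  stopifnot(inherits(params, "nrh_params"), all(L >= 0))
  a <- params$phi * L + (1 + params$alpha) * params$pmax
  disc <- a^2 - 4 * params$theta * params$phi * L * (1 + params$alpha) * params$pmax
  gross <- (a - sqrt(pmax(disc, 0))) / (2 * params$theta)
  gross - params$alpha * params$pmax
}

#' Assign canopy faces to depth layers
#'
#' Splits the z-range from the ground to the highest face center into
#' `n_layers` equal-depth bands and assigns each face to the band holding
#' its center; a center exactly on a boundary goes to the upper layer.
#' Layer 1 is the top of the canopy.
#'
#' @param scene a `canopy_scene` or [triangle_mesh].
#' @param n_layers number of layers (default 3).
#' @return A list of class `layer_assignment`: `layer` (integer per face,
#'   1 = top), `boundaries` (z at layer bottoms, descending) and `height`.
#' @export
assign_layers <- function(scene, n_layers = 3L) {
  mesh <- if (inherits(scene, "canopy_scene")) scene_mesh(scene) else scene
  stopifnot(inherits(mesh, "triangle_mesh"))
  z <- mesh$center[, 3L]
  height <- max(z)
  if (height <= 0) stop("canopy height must be positive")
  depth <- height / n_layers
  band <- pmin(floor(z / depth), n_layers - 1L)  # 0 bottom .. n-1 top
  layer <- as.integer(n_layers - band)
  structure(list(layer = layer,
                 boundaries = height - depth * seq_len(n_layers),
                 height = height, n_layers = as.integer(n_layers)),
            class = "layer_assignment")
}

# Trapezoidal time integral of y(t) over the sub-window [lo, hi] of a
# light-series grid; t in hours, integral in (units of y) * seconds.
integrate_window <- function(times, y, window) {
  idx <- which(times >= window[1L] - 1e-9 & times <= window[2L] + 1e-9)
  if (length(idx) < 2L) stop("series does not cover the integration window")
  if (times[idx[1L]] > window[1L] + 1e-6 ||
      times[idx[length(idx)]] < window[2L] - 1e-6) {
    stop("series does not cover the integration window")
  }
  t_sec <- times[idx] * 3600
  if (is.null(dim(y))) {
    pracma::trapz(t_sec, y[idx])
  } else {
    apply(y[, idx, drop = FALSE], 1L, function(r) pracma::trapz(t_sec, r))
  }
}

#' Daily carbon assimilation of single triangles
#'
#' Integrates the non-rectangular hyperbola over each face's diurnal PPFD
#' course (trapezoidal rule on the series grid, dt in seconds) and
#' multiplies by the face area: `P_i = S_i * int F(L_i(t)) dt` in
#' micromol CO2 per triangle per day.  The default 5--22 h window accrues
#' dark respiration outside daylight.
#'
#' @param series a `light_series`.
#' @param params an [nrh_params] (applied to all requested faces), or a
#'   list of [nrh_params] indexed by `layer`.
#' @param layer optional integer vector (per face) of layer indices into
#'   `params` when `params` is a list.
#' @param window integration window in hours, default `c(5, 22)`.
#' @param faces indices of faces to integrate (default all).
#' @return Numeric vector `P_i`, micromol CO2 d^-1 per face.
#' @export
daily_carbon_triangle <- function(series, params, layer = NULL,
                                  window = c(5, 22), faces = NULL) {
  stopifnot(inherits(series, "light_series"))
  if (is.null(faces)) faces <- seq_len(nrow(series$ppfd))
  if (inherits(params, "nrh_params")) {
    params <- list(params)
    layer <- rep(1L, length(faces))
  } else if (is.null(layer)) {
    stop("layer indices required when params is a per-layer list")
  }
  rate <- matrix(0, length(faces), ncol(series$ppfd))
  for (k in seq_along(params)) {
    sel <- which(layer == k)
    if (length(sel) == 0L) next
    rate[sel, ] <- nrh(series$ppfd[faces[sel], , drop = FALSE], params[[k]])
  }
  area <- series$face_area[faces]
  area * integrate_window(series$times, rate, window)
}

#' Canopy daily carbon gain per unit leaf area
#'
#' `C = sum(P_i) / sum(S_i) / 1e6`, in mol CO2 m^-2 leaf d^-1.
#'
#' @param P per-face daily carbon, micromol CO2 d^-1 (from
#'   [daily_carbon_triangle()]).
#' @param S per-face one-sided areas, m^2.
#' @return C in mol CO2 m^-2 d^-1.
#' @export
canopy_carbon_per_area <- function(P, S) {
  if (length(P) != length(S)) stop("P and S must have the same length")
  if (sum(S) <= 0) stop("total leaf area must be positive")
  sum(P) / sum(S) / 1e6
}

#' Total canopy light interception per unit leaf area (TLLA)
#'
#' Area-weighted daily photon dose:
#' `TLLA = sum_i S_i int L_i(t) dt / sum_i S_i / 1e6` in
#' mol photons m^-2 leaf d^-1, integrated over the 5.5--18.5 h window by
#' default.
#'
#' @param series a `light_series`.
#' @param window hours, default `c(5.5, 18.5)`.
#' @param faces indices of faces to include (default all).
#' @return TLLA, mol photons m^-2 d^-1.
#' @export
total_light_per_area <- function(series, window = c(5.5, 18.5),
                                 faces = NULL) {
  stopifnot(inherits(series, "light_series"))
  if (is.null(faces)) faces <- seq_len(nrow(series$ppfd))
  S <- series$face_area[faces]
  dose <- integrate_window(series$times, series$ppfd[faces, , drop = FALSE],
                           window)
  sum(S * dose) / sum(S) / 1e6
}
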