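#' Leaf optical properties
#'
#' Two-sided Lambertian leaf optics: a photon hitting a leaf is reflected
#' with probability `reflectance`, transmitted through the lamina with
#' probability `transmittance`, and absorbed otherwise.  Defaults are the
#' 7.5% scattering / 7.5% transmittance used throughout the canopy
#' experiments.
#'
#' @param reflectance leaf reflectance, in \[0, 1).
#' @param transmittance leaf transmittance, in \[0, 1).
#' @return A list of class `leaf_optics`.
#' @export
leaf_optics <- function(reflectance = 0.075, transmittance = 0.075) {
  if (reflectance < 0 || transmittance < 0 ||
      reflectance + transmittance >= 1) {
    stop("need reflectance, transmittance >= 0 and their sum < 1")
  }
  structure(list(reflectance = reflectance, transmittance = transmittance,
                 absorbed = 1 - reflectance - transmittance),
            class = "leaf_optics")
}

#' Monte Carlo sampling configuration
#'
#' @param rays_per_m2 rays launched through the box top per square metre,
#'   for each of the direct and diffuse components.  The default (5e6,
#'   i.e. 2e5 rays per component on the standard 0.2 m x 0.2 m box) is the
#'   full-resolution setting; scaled-down studies and tests pass smaller
#'   budgets explicitly.
#' @param max_bounces scattering events allowed before a photon is
#'   terminated as absorbed; 3 captures > 99.7% of scattered energy at the
#'   default leaf optics.
#' @param n_batches independent ray batches used to form Monte Carlo
#'   standard errors.
#' @param seed integer seed for the tracer's own deterministic RNG.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(rays_per_m2 = 5e6, max_bounces = 3L,
                         n_batches = 8L, seed = 1L) {
  if (rays_per_m2 <= 0) stop("rays_per_m2 must be positive")
  if (max_bounces < 0) stop("max_bounces must be >= 0")
  structure(list(rays_per_m2 = rays_per_m2,
                 max_bounces = as.integer(max_bounces),
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "trace_config")
}

#' Trace one time point
#'
#' Launches direct-beam rays (parallel to `sun_direction`) and
#' cosine-weighted diffuse sky rays through the top of the scene's periodic
#' box and follows them through absorption, Lambertian reflection and
#' transmission.  Rays leaving a lateral box face re-enter from the
#' opposite face; the ground absorbs; the top face lets photons escape.
#' Each face accumulates INCIDENT photon flux per unit leaf area, counted
#' on both sides, so an unobstructed horizontal plate receives
#' `direct_normal * sin(beta) + diffuse_horizontal`.
#'
#' @param scene a `canopy_scene`.
#' @param sun_direction unit 3-vector of photon travel (pointing down for a
#'   sun above the horizon); see `incident_ppfd()` for the matching fluxes.
#' @param direct_normal,diffuse_horizontal PPFD components,
#'   micromol m^-2 s^-1.
#' @param optics a [leaf_optics].
#' @param cfg a [trace_config].
#' @param mesh optional pre-assembled scene mesh (from repeated calls);
#'   when supplied it must correspond to `scene`.
#' @return A list of class `trace_result`: `ppfd` (per-face incident PPFD),
#'   `se` (Monte Carlo standard error per face), `audit` (named incident /
#'   absorbed / escaped / ground totals averaged over batches,
#'   micromol s^-1), and `n_rays`.
#' @export
trace_timepoint <- function(scene, sun_direction, direct_normal,
                            diffuse_horizontal, optics = leaf_optics(),
                            cfg = trace_config(), mesh = NULL) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(optics, "leaf_optics"),
            inherits(cfg, "trace_config"))
  if (is.null(mesh)) mesh <- scene_mesh(scene)
  box <- scene$box
  area <- (box[["xmax"]] - box[["xmin"]]) * (box[["ymax"]] - box[["ymin"]])
  n_rays <- max(cfg$n_batches, ceiling(cfg$rays_per_m2 * area))
  ztop <- max(c(mesh$vertices[, 3L], 0.01)) + 1e-4
  sinb <- max(0, -sun_direction[3L] / sqrt(sum(sun_direction^2)))
  res <- .trace_cpp(
    mesh$vertices, mesh$faces - 1L,
    c(box[["xmin"]], box[["xmax"]], box[["ymin"]], box[["ymax"]], ztop),
    as.numeric(sun_direction),
    direct_horizontal = direct_normal * sinb,
    diffuse_horizontal = diffuse_horizontal,
    rho = optics$reflectance, tau = optics$transmittance,
    max_bounces = cfg$max_bounces, n_direct = n_rays, n_diffuse = n_rays,
    n_batches = cfg$n_batches, seed = as.double(cfg$seed) %% 2^31
  )
  B <- cfg$n_batches
  flux <- rowMeans(res$face_energy)           # micromol s^-1 per face
  ppfd <- flux / mesh$area
  se <- if (B > 1L) {
    apply(res$face_energy, 1L, stats::sd) / sqrt(B) / mesh$area
  } else {
    rep(NA_real_, length(flux))
  }
  audit <- c(incident = mean(res$incident), absorbed = mean(res$absorbed),
             escaped = mean(res$escaped), ground = mean(res$ground),
             intercepted = sum(flux))
  structure(list(ppfd = as.numeric(ppfd), se = as.numeric(se),
                 audit = audit, n_rays = n_rays,
                 batches = res$face_energy, face_area = mesh$area),
            class = "trace_result")
}

#' Photon-conservation audit of a trace
#'
#' Checks that launched flux is fully accounted for by absorption, escape
#' through the box top and ground interception.
#'
#' @param trace a `trace_result`.
#' @return A named vector with the audited totals (micromol s^-1) plus
#'   `closure`, the relative imbalance `(incident - absorbed - escaped -
#'   ground) / incident`.
#' @export
energy_audit <- function(trace) {
  stopifnot(inherits(trace, "trace_result"))
  a <- trace$audit
  closure <- if (a[["incident"]] > 0) {
    (a[["incident"]] - a[["absorbed"]] - a[["escaped"]] - a[["ground"]]) /
      a[["incident"]]
  } else 0
  c(a, closure = closure)
}

#' Diurnal per-triangle light course
#'
#' Evaluates [trace_timepoint()] on a uniform time grid, with the solar
#' position and clear-sky irradiance of each instant; night times are
#' filled with zeros without tracing.
#'
#' @param scene a `canopy_scene`.
#' @param solar a [solar_config].
#' @param optics a [leaf_optics].
#' @param cfg a [trace_config].
#' @param window `c(start, end)` hours of local solar time.
#' @param step time step in minutes.
#' @return A list of class `light_series`: `times` (hours), `ppfd` (faces x
#'   times matrix, micromol m^-2 s^-1), `face_area`, `face_center`,
#'   `plant_id`, and the configurations used.
#' @export
simulate_day <- function(scene, solar = solar_config(),
                         optics = leaf_optics(), cfg = trace_config(),
                         window = c(5, 22), step = 1) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (window[2L] <= window[1L]) stop("window end must exceed start")
  if (step <= 0) stop("step must be positive")
  times <- seq(window[1L], window[2L], by = step / 60)
  mesh <- scene_mesh(scene)
  m <- nrow(mesh$faces)
  ppfd <- matrix(0, m, length(times))
  for (j in seq_along(times)) {
    pos <- solar_position(solar, times[j])
    if (pos[["elevation"]] <= 0) next
    irr <- incident_ppfd(solar, pos[["elevation"]])
    cfg_t <- cfg
    cfg_t$seed <- (cfg$seed + 7919L * j) %% .Machine$integer.max
    tr <- trace_timepoint(scene, sun_photon_direction(pos[["elevation"]],
                                                      pos[["azimuth"]]),
                          irr[["direct_normal"]], irr[["diffuse_horizontal"]],
                          optics, cfg_t, mesh = mesh)
    ppfd[, j] <- tr$ppfd
  }
  structure(list(times = times, ppfd = ppfd, face_area = mesh$area,
                 face_center = mesh$center, plant_id = attr(mesh, "plant_id"),
                 solar = solar, optics = optics, trace = cfg),
            class = "light_series")
}

#' @export
print.light_series <- function(x, ...) {
  cat(sprintf(
    "<light_series> %d faces x %d times (%.2f-%.2f h)\n  peak PPFD %.0f umol m-2 s-1\n",
    nrow(x$ppfd), ncol(x$ppfd), min(x$times), max(x$times), max(x$ppfd)))
  invisible(x)
}

# Plain all-faces first-hit query through the BVH; the testing oracle
# recomputes this in R.
first_hit <- function(mesh, origins, dirs) {
  if (is.null(dim(origins))) origins <- matrix(origins, nrow = 1L)
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1L)
  .first_hit_cpp(mesh$vertices, mesh$faces - 1L, origins, dirs)
}
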