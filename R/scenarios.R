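#' Surface-area distribution of PPFD, by canopy layer
#'
#' For each layer, the fraction of that layer's leaf area receiving PPFD in
#' each half-open bin `[lo, hi)`.  Fractions sum to 1 per layer.
#'
#' @param ppfd per-face PPFD, micromol m^-2 s^-1.
#' @param areas per-face one-sided areas, m^2.
#' @param layers a `layer_assignment` (or integer vector per face).
#' @param bin_width bin width in micromol m^-2 s^-1.
#' @return A data.frame with `layer`, `bin_lo`, `bin_hi`, `fraction`.
#' @export
ppfd_area_distribution <- function(ppfd, areas, layers, bin_width = 100) {
  if (bin_width <= 0) stop("bin_width must be positive")
  layer <- if (inherits(layers, "layer_assignment")) layers$layer else layers
  stopifnot(length(ppfd) == length(areas), length(layer) == length(ppfd))
  n_bins <- max(1, ceiling((max(ppfd) + 1e-9) / bin_width))
  bin <- pmin(floor(ppfd / bin_width), n_bins - 1L)
  out <- list()
  for (m in sort(unique(layer))) {
    sel <- layer == m
    tot <- sum(areas[sel])
    frac <- vapply(seq_len(n_bins) - 1L, function(b) {
      sum(areas[sel][bin[sel] == b]) / tot
    }, 0)
    out[[length(out) + 1L]] <- data.frame(
      layer = m, bin_lo = (seq_len(n_bins) - 1L) * bin_width,
      bin_hi = seq_len(n_bins) * bin_width, fraction = frac)
  }
  do.call(rbind, out)
}

#' Percentage-point difference between two area distributions
#'
#' Per-bin signed difference `(f_distorted - f_undistorted) * 100` in
#' percentage points of leaf area; positive values mean the distorted
#' canopy has more area at that PPFD.  Distributions must share binning
#' (and layers, if present).
#'
#' @param f_distorted,f_undistorted data.frames from
#'   [ppfd_area_distribution()], or plain fraction vectors.
#' @return Same shape as the inputs with a `diff_pp` column (or vector).
#' @export
distribution_percent_difference <- function(f_distorted, f_undistorted) {
  if (is.data.frame(f_distorted)) {
    key <- c("layer", "bin_lo", "bin_hi")
    key <- key[key %in% names(f_distorted)]
    if (!isTRUE(all.equal(f_distorted[key], f_undistorted[key],
                          check.attributes = FALSE))) {
      stop("distributions have mismatched bins or layers")
    }
    out <- f_distorted[key]
    out$diff_pp <- (f_distorted$fraction - f_undistorted$fraction) * 100
    return(out)
  }
  if (length(f_distorted) != length(f_undistorted)) {
    stop("distributions have mismatched bins")
  }
  (f_distorted - f_undistorted) * 100
}

#' Min-max normalisation of a carbon-gain series
#'
#' Rescales a series across a displacement sweep to \[0, 1\]: 0 is the
#' least favourable configuration for carbon gain, 1 the most favourable.
#' A constant series is degenerate and reported as 0.5 with a flag.
#'
#' @param values numeric vector (>= 2 values) of carbon gain across the
#'   angle sweep for one face.
#' @return List with `normalized` (same length) and `degenerate` (logical).
#' @export
normalized_carbon <- function(values) {
  if (length(values) < 2L) stop("need at least two values to normalise")
  rng <- range(values)
  if (diff(rng) <= 0) {
    return(list(normalized = rep(0.5, length(values)), degenerate = TRUE))
  }
  list(normalized = (values - rng[1L]) / diff(rng), degenerate = FALSE)
}

#' Constant-wind scenario: whole-day light interception and carbon gain
#'
#' Runs the steady-displacement experiment: the undistorted stand plus the
#' stand tilted by `angle` degrees for each wind direction is ray-traced
#' over the day, and total light interception per unit leaf area (TLLA)
#' and daily carbon gain per unit leaf area (C) are computed on the central
#' plant with the per-layer light-response table.  `n_reps` independent
#' replicate day simulations give Monte Carlo standard errors.  Snapshot
#' PPFD surface-area distributions and leaf-angle distributions are
#' collected for each condition.
#'
#' @param scene an undistorted `canopy_scene`.
#' @param directions character/numeric vector of wind directions;
#'   `"none"` means undistorted.
#' @param angle tilt in degrees applied for every direction except
#'   `"none"`.
#' @param solar,optics,cfg configuration objects.
#' @param window simulated hours (default `c(5, 22)`, covering both the
#'   light and carbon integration windows).
#' @param step time step in minutes.
#' @param light_window TLLA integration window (hours).
#' @param carbon_window carbon integration window (hours).
#' @param snapshot_hours times at which PPFD distributions are recorded.
#' @param params per-layer [nrh_params] list (default [nrh_layers()]).
#' @param n_reps replicate day simulations for standard errors.
#' @param bin_width PPFD histogram bin width.
#' @param seed base seed; replicate and condition seeds derive from it.
#' @return A list of class `scenario_result` with elements `table`
#'   (direction, TLLA, TLLA_se, C, C_se), `distributions`, `leaf_angles`
#'   and `provenance`.
#' @export
run_constant <- function(scene, directions = c("none", "N", "E", "S", "W"),
                         angle = 6, solar = solar_config(),
                         optics = leaf_optics(), cfg = trace_config(),
                         window = c(5, 22), step = 1,
                         light_window = c(5.5, 18.5),
                         carbon_window = c(5, 22),
                         snapshot_hours = c(9, 12, 15),
                         params = nrh_layers(), n_reps = 3L,
                         bin_width = 100, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"))
  central <- central_plant_index(scene)
  rows <- list()
  dists <- list()
  angles_tab <- list()
  for (ci in seq_along(directions)) {
    dir <- directions[ci]
    scn <- if (identical(dir, "none")) scene else
      solid_body_rotate(scene, wind_spec(dir, angle))
    la <- assign_layers(scn)
    mesh <- scene_mesh(scn)
    on_central <- which(attr(mesh, "plant_id") == central)

    tlla_r <- c_r <- numeric(n_reps)
    snap <- NULL
    for (r in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$seed <- (seed + 104729L * ci + 1299709L * r) %% .Machine$integer.max
      series <- simulate_day(scn, solar, optics, cfg_r, window, step)
      tlla_r[r] <- total_light_per_area(series, light_window,
                                        faces = on_central)
      P <- daily_carbon_triangle(series, params,
                                 layer = la$layer[on_central],
                                 window = carbon_window, faces = on_central)
      c_r[r] <- canopy_carbon_per_area(P, series$face_area[on_central])
      snap_r <- lapply(snapshot_hours, function(h) {
        j <- which.min(abs(series$times - h))
        series$ppfd[on_central, j]
      })
      snap <- if (is.null(snap)) snap_r else
        Map(function(a, b) a + b, snap, snap_r)
    }
    snap <- lapply(snap, `/`, n_reps)

    rows[[ci]] <- data.frame(
      direction = as.character(dir), angle = ifelse(identical(dir, "none"), 0, angle),
      TLLA = mean(tlla_r), TLLA_se = stats::sd(tlla_r) / sqrt(n_reps),
      C = mean(c_r), C_se = stats::sd(c_r) / sqrt(n_reps))
    dists[[ci]] <- do.call(rbind, Map(function(h, p) {
      d <- ppfd_area_distribution(p, mesh$area[on_central],
                                  la$layer[on_central], bin_width)
      cbind(direction = as.character(dir), hour = h, d)
    }, snapshot_hours, snap))
    ang <- leaf_angle_from_vertical(mesh$normal[on_central, , drop = FALSE])
    angles_tab[[ci]] <- data.frame(direction = as.character(dir),
                                   layer = la$layer[on_central],
                                   angle_deg = ang,
                                   area = mesh$area[on_central])
  }
  structure(
    list(table = do.call(rbind, rows),
         distributions = do.call(rbind, dists),
         leaf_angles = do.call(rbind, angles_tab),
         provenance = list(seed = seed, n_reps = n_reps, step = step,
                           angle = angle, window = window,
                           light_window = light_window,
                           carbon_window = carbon_window,
                           rays_per_m2 = cfg$rays_per_m2)),
    class = "scenario_result"
  )
}

central_plant_index <- function(scene) {
  d2 <- scene$positions[, 1L]^2 + scene$positions[, 2L]^2
  which.min(d2)
}

# Seeded choice of measurement locations on the central plant: per layer,
# `n_per_layer` anchor faces, each pooled with its (n_adjacent - 1) nearest
# same-leaf neighbours by center distance.
select_locations <- function(scene, n_per_layer = 3L, n_adjacent = 5L,
                             seed = 1L) {
  central <- central_plant_index(scene)
  mesh <- scene_mesh(scene)
  on_central <- which(attr(mesh, "plant_id") == central)
  la <- assign_layers(scene)
  locs <- list()
  withr::with_seed(seed, {
    for (m in 1:3) {
      cand <- on_central[la$layer[on_central] == m]
      cand <- cand[vapply(cand, function(f) {
        sum(mesh$leaf_id == mesh$leaf_id[f]) >= n_adjacent
      }, TRUE)]
      if (length(cand) < n_per_layer) {
        stop("layer ", m, ": only ", length(cand), " faces on leaves with >= ",
             n_adjacent, " same-leaf faces on the central plant")
      }
      anchors <- sample(cand, n_per_layer)
      for (k in seq_len(n_per_layer)) {
        f <- anchors[k]
        mates <- which(mesh$leaf_id == mesh$leaf_id[f])
        d <- sqrt(rowSums(sweep(mesh$center[mates, , drop = FALSE], 2L,
                                mesh$center[f, ])^2))
        grp <- mates[order(d)][seq_len(n_adjacent)]
        locs[[length(locs) + 1L]] <-
          list(layer = m, anchor = f, faces = grp,
               label = sprintf("L%d.%d", m, k))
      }
    }
  })
  locs
}

#' Dynamic-wind scenario: gust sweep at fixed times of day
#'
#' Distorts the stand from the SAME undistorted state by each angle in
#' `angles`, ray-traces a single snapshot at each requested hour (the sweep
#' is assumed faster than any change in solar angle), and tracks nine leaf
#' locations on the central plant (three per canopy layer, each the mean of
#' `n_adjacent` adjacent same-leaf triangles; rigid motion preserves face
#' identity across angles).  Per location and time the result reports mean
#' PPFD, the matching net carbon rate from that layer's light response,
#' min-max normalised carbon gain (per face across the sweep, then averaged
#' over the location's faces; a constant series maps to 0.5 and is
#' flagged), and the percent difference in carbon rate relative to 0
#' degrees.
#'
#' @inheritParams run_constant
#' @param wind_azimuth compass direction of the wind (degrees or letter).
#' @param angles displacement sweep in degrees (default 0:10).
#' @param times hours of day to sample (default 9, 12, 15).
#' @param n_per_layer,n_adjacent location selection parameters.
#' @return A `scenario_result` whose `dynamic` element is a data.frame with
#'   one row per (hour, angle, location).
#' @export
run_dynamic <- function(scene, wind_azimuth = "E", angles = 0:10,
                        times = c(9, 12, 15), solar = solar_config(),
                        optics = leaf_optics(), cfg = trace_config(),
                        params = nrh_layers(), n_per_layer = 3L,
                        n_adjacent = 5L, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"))
  locs <- select_locations(scene, n_per_layer, n_adjacent, seed)
  scenes <- distortion_series(scene, wind_azimuth, angles)
  layer_names <- c("top", "middle", "bottom")

  rows <- list()
  for (ti in seq_along(times)) {
    pos <- solar_position(solar, times[ti])
    irr <- incident_ppfd(solar, pos[["elevation"]])
    sun <- sun_photon_direction(pos[["elevation"]], pos[["azimuth"]])
    # faces x angles PPFD for every tracked face
    tracked <- unlist(lapply(locs, `[[`, "faces"))
    ppfd_fa <- matrix(0, length(tracked), length(angles))
    for (ai in seq_along(angles)) {
      cfg_a <- cfg
      cfg_a$seed <- (seed + 15485863L * ti + 32452843L * ai) %%
        .Machine$integer.max
      tr <- trace_timepoint(scenes[[ai]], sun, irr[["direct_normal"]],
                            irr[["diffuse_horizontal"]], optics, cfg_a)
      ppfd_fa[, ai] <- tr$ppfd[tracked]
    }
    off <- 0L
    for (lc in locs) {
      nf <- length(lc$faces)
      block <- ppfd_fa[off + seq_len(nf), , drop = FALSE]
      off <- off + nf
      prm <- params[[lc$layer]]
      carbon_f <- nrh(block, prm)            # faces x angles
      norm_f <- t(apply(carbon_f, 1L, function(v) normalized_carbon(v)$normalized))
      degen <- apply(carbon_f, 1L, function(v) normalized_carbon(v)$degenerate)
      carbon_mean <- colMeans(carbon_f)
      ref <- carbon_mean[which(angles == 0)]
      pct <- if (length(ref) == 1L && abs(ref) > 1e-12) {
        (carbon_mean - ref) / abs(ref) * 100
      } else {
        ifelse(angles == 0, 0, NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hour = times[ti], angle = angles, location = lc$label,
        layer = layer_names[lc$layer], ppfd = colMeans(block),
        carbon = carbon_mean, carbon_norm = colMeans(norm_f),
        pct_diff = pct, degenerate = any(degen))
    }
  }
  structure(
    list(table = NULL, dynamic = do.call(rbind, rows),
         locations = locs,
         provenance = list(seed = seed, wind_azimuth = wind_azimuth,
                           angles = angles, times = times,
                           rays_per_m2 = cfg$rays_per_m2)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  if (!is.null(x$table)) {
    cat("Constant-wind summary (central plant):\n")
    print(x$table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$dynamic)) {
    cat(sprintf("Dynamic sweep: %d rows (%d hours x %d angles x %d locations)\n",
                nrow(x$dynamic), length(unique(x$dynamic$hour)),
                length(unique(x$dynamic$angle)),
                length(unique(x$dynamic$location))))
  }
  invisible(x)
}
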