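#' Recipe for a synthetic rice-like plant
#'
#' Parameterises the procedural plant generator.  The defaults describe a
#' vegetative-stage rice plant of the kind used throughout the package's
#' canopy experiments: 600 triangles in 10 tapered, drooping leaf blades,
#' canopy top at 0.73 m, erect leaves at the top of the plant grading to
#' near-horizontal leaves at the base, and 0.04 m^2 of one-sided leaf area
#' per plant (which yields a stand LAI of 4 on a 3x3 grid at 10 cm spacing).
#'
#' @param n_leaves number of leaf blades.
#' @param height canopy-top height in metres (the topmost vertex of the
#'   generated plant sits exactly here).
#' @param leaf_length_range metres, blade arc length for the lowest and the
#'   highest leaf; intermediate leaves interpolate quadratically so that
#'   mid-canopy blades stay compact.
#' @param leaf_width_range metres, pre-calibration maximum blade width for
#'   the lowest and highest leaf (uniform rescaling then enforces
#'   `target_leaf_area` exactly).
#' @param base_angle_range degrees from vertical at the blade base for the
#'   highest and lowest leaf (erect top, near-horizontal base).
#' @param droop_curvature 1/m, rate at which a blade's inclination from
#'   vertical increases along its length; the realised curvature grades from
#'   1.5x this value at the base to 0.67x at the top leaf.
#' @param triangles_per_leaf triangles per blade (even; strip triangulation).
#' @param target_leaf_area m^2 one-sided area per plant.
#' @param seed integer RNG seed for the shape jitter.
#'
#' @return A list of class `plant_recipe`.
#' @export
plant_recipe <- function(n_leaves = 10L,
                         height = 0.73,
                         leaf_length_range = c(0.22, 0.65),
                         leaf_width_range = c(0.010, 0.016),
                         base_angle_range = c(5, 75),
                         droop_curvature = 1.2,
                         triangles_per_leaf = 60L,
                         target_leaf_area = 0.04,
                         seed = 42L) {
  if (n_leaves < 1L) stop("n_leaves must be positive")
  if (triangles_per_leaf %% 2L != 0L || triangles_per_leaf < 2L) {
    stop("triangles_per_leaf must be a positive even number")
  }
  if (height <= 0 || target_leaf_area <= 0 || droop_curvature <= 0 ||
      any(leaf_length_range <= 0) || any(leaf_width_range <= 0)) {
    stop("recipe fields must be positive")
  }
  structure(
    list(n_leaves = as.integer(n_leaves), height = height,
         leaf_length_range = leaf_length_range,
         leaf_width_range = leaf_width_range,
         base_angle_range = base_angle_range,
         droop_curvature = droop_curvature,
         triangles_per_leaf = as.integer(triangles_per_leaf),
         target_leaf_area = target_leaf_area, seed = as.integer(seed)),
    class = "plant_recipe"
  )
}

# Centerline of one blade: inclination from vertical grows linearly with arc
# length, gamma(s) = gamma0 + c*s, capped at GAMMA_MAX so tips hang rather
# than curling under the ground.  Closed-form integral of (sin gamma, cos
# gamma) gives radial and vertical coordinates.
GAMMA_MAX <- 1.745  # radians, ~100 degrees

blade_centerline <- function(s, gamma0, curv) {
  s_star <- max(0, (GAMMA_MAX - gamma0) / curv)
  arc <- pmin(s, s_star)
  gam <- gamma0 + curv * arc
  radial <- (cos(gamma0) - cos(gam)) / curv
  zrel <- (sin(gam) - sin(gamma0)) / curv
  over <- s > s_star
  if (any(over)) {
    radial[over] <- radial[over] + (s[over] - s_star) * sin(GAMMA_MAX)
    zrel[over] <- zrel[over] + (s[over] - s_star) * cos(GAMMA_MAX)
  }
  cbind(radial, zrel)
}

# Blade half-width profile: widest mid-blade, narrow (but never degenerate)
# at base and tip.
blade_halfwidth <- function(s, len, width) {
  (width / 2) * (0.25 + 0.75 * sin(pi * pmin(1, s / len)))
}

#' Generate a synthetic rice-like plant mesh
#'
#' Builds `n_leaves` tapered blades as triangle strips along drooping
#' centerlines.  Leaves are placed at golden-angle azimuths with jitter;
#' blade length, base inclination and curvature grade with insertion rank so
#' the top of the plant is erect and the base planophile.  After assembly the
#' plant is scaled isotropically so its topmost vertex sits exactly at
#' `recipe$height` (isotropy preserves all leaf angles), then blade widths
#' are rescaled uniformly so the one-sided area equals
#' `recipe$target_leaf_area` exactly (width scaling leaves face normals
#' unchanged, see the package vignette).
#'
#' @param recipe a [plant_recipe].
#' @return A [triangle_mesh] with `recipe$n_leaves * recipe$triangles_per_leaf`
#'   faces, rooted at the origin.
#' @export
generate_plant <- function(recipe = plant_recipe()) {
  stopifnot(inherits(recipe, "plant_recipe"))
  n <- recipe$n_leaves
  withr::with_seed(recipe$seed, {
    rank <- if (n == 1L) 1 else (seq_len(n) - 1) / (n - 1)  # 0 base .. 1 top
    golden <- 137.50776405
    azim <- (golden * seq_len(n) + runif(n, -20, 20)) * pi / 180
    gamma0 <- (recipe$base_angle_range[1L] +
                 (recipe$base_angle_range[2L] - recipe$base_angle_range[1L]) *
                 (1 - rank)) * pi / 180
    gamma0 <- gamma0 * runif(n, 0.95, 1.05)
    len <- (recipe$leaf_length_range[1L] +
              diff(recipe$leaf_length_range) * rank^2) * runif(n, 0.95, 1.05)
    wid <- (recipe$leaf_width_range[1L] +
              diff(recipe$leaf_width_range) * rank) * runif(n, 0.9, 1.1)
    curv <- recipe$droop_curvature * (1.5 - 0.833 * rank)
    z0 <- 0.02 + 0.08 * rank * max(recipe$leaf_length_range)
  })

  n_seg <- recipe$triangles_per_leaf %/% 2L
  skel <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seq(0, len[i], length.out = n_seg + 1L)
    cl <- blade_centerline(s, gamma0[i], curv[i])
    d <- c(sin(azim[i]), cos(azim[i]))  # horizontal blade direction
    centers <- cbind(cl[, 1L] * d[1L], cl[, 1L] * d[2L], z0[i] + cl[, 2L])
    u <- c(cos(azim[i]), -sin(azim[i]), 0)  # lateral unit vector
    skel[[i]] <- list(centers = centers, u = u,
                      halfw = blade_halfwidth(s, len[i], wid[i]))
  }

  raw_top <- max(vapply(skel, function(l) max(l$centers[, 3L]), 0))
  k <- recipe$height / raw_top
  for (i in seq_len(n)) {
    skel[[i]]$centers <- skel[[i]]$centers * k
    skel[[i]]$halfw <- skel[[i]]$halfw * k
  }
  mesh <- assemble_blades(skel, n_seg)
  if (min(mesh$vertices[, 3L]) < -1e-9) {
    stop("infeasible recipe: blades extend below the ground plane")
  }

  # Width calibration: scaling the lateral offsets scales every face area
  # linearly and leaves normals unchanged.
  w_mult <- recipe$target_leaf_area / sum(mesh$area)
  mean_len <- mean(len) * k
  mean_wid <- mean(wid) * k * w_mult
  if (mean_wid > 0.5 * mean_len) {
    stop("infeasible recipe: target area needs blades wider than half ",
         "their length; increase n_leaves or leaf length")
  }
  for (i in seq_len(n)) skel[[i]]$halfw <- skel[[i]]$halfw * w_mult
  assemble_blades(skel, n_seg)
}

assemble_blades <- function(skel, n_seg) {
  verts <- list()
  faces <- list()
  leaf_id <- integer(0)
  off <- 0L
  for (i in seq_along(skel)) {
    sk <- skel[[i]]
    left <- sk$centers - outer(sk$halfw, sk$u)
    right <- sk$centers + outer(sk$halfw, sk$u)
    v <- matrix(0, 2L * (n_seg + 1L), 3L)
    v[seq(1L, by = 2L, length.out = n_seg + 1L), ] <- left
    v[seq(2L, by = 2L, length.out = n_seg + 1L), ] <- right
    f <- matrix(0L, 2L * n_seg, 3L)
    for (j in seq_len(n_seg)) {
      l0 <- 2L * j - 1L; r0 <- 2L * j; l1 <- 2L * j + 1L; r1 <- 2L * j + 2L
      f[2L * j - 1L, ] <- c(l0, r0, l1)
      f[2L * j, ] <- c(r0, r1, l1)
    }
    verts[[i]] <- v
    faces[[i]] <- f + off
    leaf_id <- c(leaf_id, rep.int(i, 2L * n_seg))
    off <- off + nrow(v)
  }
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces), leaf_id = leaf_id)
}

#' Assemble a canopy stand from duplicated plants
#'
#' Duplicates one plant onto a `rows` x `cols` grid at `spacing` metres,
#' giving each duplicate an independent uniform random yaw about its own
#' base.  The periodic ray-tracing box spans the centers of the outer
#' plants, so for the default 3x3 stand at 0.10 m spacing the box is
#' 0.20 m x 0.20 m centered on the central plant.  Plants are numbered
#' row-major.
#'
#' @param plant a [triangle_mesh], rooted at the origin.
#' @param rows,cols grid dimensions.
#' @param spacing plant spacing in metres.
#' @param seed integer RNG seed for the yaws.
#' @return An object of class `canopy_scene`: `plants` (list of positioned
#'   meshes), `positions`, `yaw_deg`, `grid`, `spacing`, `box`
#'   (xmin, xmax, ymin, ymax) and `seed`.
#' @export
build_canopy <- function(plant, rows = 3L, cols = 3L, spacing = 0.10,
                         seed = 42L) {
  stopifnot(inherits(plant, "triangle_mesh"))
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  if (spacing <= 0) stop("spacing must be positive")
  n <- rows * cols
  yaw <- withr::with_seed(seed, runif(n, 0, 360))
  xs <- (seq_len(cols) - (cols + 1) / 2) * spacing
  ys <- (seq_len(rows) - (rows + 1) / 2) * spacing
  pos <- cbind(x = rep(xs, times = rows), y = rep(rev(ys), each = cols))
  plants <- vector("list", n)
  for (i in seq_len(n)) {
    R <- rotation_matrix(c(0, 0, 1), yaw[i] * pi / 180)
    plants[[i]] <- transform_mesh(plant, R = R,
                                  translate = c(pos[i, 1L], pos[i, 2L], 0))
  }
  box <- c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
  structure(
    list(plants = plants, positions = pos, yaw_deg = yaw,
         grid = c(rows = rows, cols = cols), spacing = spacing,
         box = box, seed = as.integer(seed)),
    class = "canopy_scene"
  )
}

#' Wrap a bare mesh (or meshes) as a scene with an explicit box
#'
#' Used for ray-tracer validation scenes (plates, single plants) where the
#' periodic box is chosen by hand rather than derived from a grid.
#'
#' @param meshes a [triangle_mesh] or list of them.
#' @param box numeric (xmin, xmax, ymin, ymax).
#' @param spacing nominal spacing (m), used only for LAI-style summaries.
#' @return A `canopy_scene`.
#' @export
scene_from_meshes <- function(meshes, box, spacing = NA_real_) {
  if (inherits(meshes, "triangle_mesh")) meshes <- list(meshes)
  stopifnot(all(vapply(meshes, inherits, TRUE, "triangle_mesh")),
            length(box) == 4L, box[2L] > box[1L], box[4L] > box[3L])
  structure(
    list(plants = meshes,
         positions = matrix(0, length(meshes), 2L,
                            dimnames = list(NULL, c("x", "y"))),
         yaw_deg = rep(0, length(meshes)),
         grid = c(rows = 1L, cols = length(meshes)), spacing = spacing,
         box = setNames(as.numeric(box), c("xmin", "xmax", "ymin", "ymax")),
         seed = NA_integer_),
    class = "canopy_scene"
  )
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf(
    "<canopy_scene> %d plants (%dx%d grid, spacing %s m)\n  box [%.3f, %.3f] x [%.3f, %.3f] m, %d faces\n",
    length(x$plants), x$grid[["rows"]], x$grid[["cols"]],
    format(x$spacing), x$box[["xmin"]], x$box[["xmax"]], x$box[["ymin"]],
    x$box[["ymax"]], sum(vapply(x$plants, function(p) nrow(p$faces), 0L))))
  invisible(x)
}

# Merge all plants into one mesh; records which plant each face came from.
scene_mesh <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  nv <- vapply(scene$plants, function(p) nrow(p$vertices), 0L)
  off <- cumsum(c(0L, head(nv, -1L)))
  maxleaf <- vapply(scene$plants, function(p) max(0L, p$leaf_id), 0L)
  loff <- cumsum(c(0L, head(maxleaf, -1L)))
  verts <- do.call(rbind, lapply(scene$plants, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(p, o) p$faces + o, scene$plants, off))
  leaf <- unlist(Map(function(p, o) p$leaf_id + o, scene$plants, loff))
  mesh <- triangle_mesh(verts, faces, leaf_id = leaf)
  attr(mesh, "plant_id") <- rep(seq_along(scene$plants),
                                vapply(scene$plants, function(p) nrow(p$faces), 0L))
  mesh
}

#' Leaf area index of a stand
#'
#' One-sided leaf area of all plants divided by the plot footprint
#' `rows*spacing x cols*spacing` (each plant owns one grid cell).
#'
#' @param scene a `canopy_scene` built by [build_canopy()].
#' @return LAI (dimensionless).
#' @export
canopy_lai <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (!is.finite(scene$spacing) || scene$spacing <= 0) {
    stop("scene has no grid spacing; LAI undefined")
  }
  leaf_area <- sum(vapply(scene$plants, function(p) sum(p$area), 0))
  ground <- (scene$grid[["rows"]] * scene$spacing) *
    (scene$grid[["cols"]] * scene$spacing)
  leaf_area / ground
}
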