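# Fixtures and independent oracles shared across test files.

# Single horizontal square plate spanning [x0,x1] x [y0,y1] at height z.
make_plate <- function(z, x0 = -0.1, x1 = 0.1, y0 = -0.1, y1 = 0.1,
                       leaf_id = NULL) {
  triangle_mesh(rbind(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z), c(x0, y1, z)),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)), leaf_id = leaf_id)
}

unit_right_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(c(1L, 2L, 3L), 1L))
}

# Small, fast plant/canopy used where the full 600-triangle default is not
# the point of the test.
small_plant <- function(seed = 11L) {
  generate_plant(plant_recipe(n_leaves = 5L, triangles_per_leaf = 20L,
                              seed = seed))
}

small_canopy <- function(seed = 11L) {
  build_canopy(small_plant(seed), seed = seed)
}

fast_cfg <- function(seed = 1L, rays_per_m2 = 2e5, n_batches = 8L) {
  trace_config(rays_per_m2 = rays_per_m2, n_batches = n_batches, seed = seed)
}

# --- Independent oracles ----------------------------------------------------

# Long-hand triangle area: 0.5 * |AB x AC| computed element by element.
oracle_triangle_area <- function(a, b, c) {
  ab <- b - a
  ac <- c - a
  cx <- ab[2] * ac[3] - ab[3] * ac[2]
  cy <- ab[3] * ac[1] - ab[1] * ac[3]
  cz <- ab[1] * ac[2] - ab[2] * ac[1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Plain all-faces Moller-Trumbore first hit, written independently of the
# compiled BVH path.
oracle_first_hit <- function(mesh, origin, dir) {
  best_t <- Inf
  best_f <- 0L
  for (i in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[i, 1L], ]
    b <- mesh$vertices[mesh$faces[i, 2L], ]
    c <- mesh$vertices[mesh$faces[i, 3L], ]
    e1 <- b - a
    e2 <- c - a
    p <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-14) next
    s <- origin - a
    u <- sum(s * p) / det
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    v <- sum(dir * q) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) / det
    if (t > 1e-9 && t < best_t) {
      best_t <- t
      best_f <- i
    }
  }
  list(face = best_f, t = if (best_f > 0L) best_t else NA_real_)
}

# Independent evaluation of the light-response quadratic: solve
# theta*F^2 - F*(phi*L + (1+alpha)*pmax) + phi*L*(1+alpha)*pmax = 0 for the
# gross rate via polyroot, take the smaller real root, subtract alpha*pmax.
oracle_nrh <- function(L, phi, theta, pmax, alpha) {
  b <- phi * L + (1 + alpha) * pmax
  roots <- polyroot(c(phi * L * (1 + alpha) * pmax, -b, theta))
  min(Re(roots)) - alpha * pmax
}
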