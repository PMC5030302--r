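# Validation scenes use a 0.2 m x 0.2 m periodic box, matching the default
# canopy stand.

box02 <- c(-0.1, 0.1, -0.1, 0.1)
down <- c(0, 0, -1)

test_that("an empty scene sends every photon to the ground", {
  empty <- triangle_mesh(matrix(0, 0L, 3L), matrix(0L, 0L, 3L))
  scene <- scene_from_meshes(empty, box02)
  tr <- trace_timepoint(scene, down, 1000, 300, cfg = fast_cfg())
  expect_length(tr$ppfd, 0L)
  aud <- energy_audit(tr)
  expect_equal(aud[["ground"]], aud[["incident"]], tolerance = 1e-12)
  expect_equal(aud[["closure"]], 0, tolerance = 1e-12)
})

test_that("an unobstructed horizontal plate receives the incident flux", {
  scene <- scene_from_meshes(make_plate(0.3), box02)
  # overhead beam only: every ray hits, so the plate-wide mean is exact
  tr <- trace_timepoint(scene, down, 1300, 0, cfg = fast_cfg())
  plate_mean <- sum(tr$ppfd * tr$face_area) / sum(tr$face_area)
  expect_equal(plate_mean, 1300, tolerance = 1e-9)
  expect_true(all(abs(tr$ppfd - 1300) <= 3 * tr$se + 1e-6))

  # oblique beam + diffuse: plate receives direct_normal*sin(beta) + diffuse
  sun <- sun_photon_direction(35, 120)
  tr2 <- trace_timepoint(scene, sun, 1000, 250, cfg = fast_cfg(seed = 5))
  plate_mean2 <- sum(tr2$ppfd * tr2$face_area) / sum(tr2$face_area)
  expect_equal(plate_mean2, 1000 * sin(35 * pi / 180) + 250, tolerance = 1e-9)
})

test_that("plate interception is independent of its depth in the box", {
  sun <- sun_photon_direction(28, 200)  # low sun: deep plates need many wraps
  for (z in c(0.02, 0.35, 0.6)) {
    scene <- scene_from_meshes(make_plate(z), box02)
    tr <- trace_timepoint(scene, sun, 900, 0, cfg = fast_cfg(seed = 2))
    plate_mean <- sum(tr$ppfd * tr$face_area) / sum(tr$face_area)
    expect_equal(plate_mean, 900 * sin(28 * pi / 180), tolerance = 1e-9)
  }
})

test_that("periodic wrap makes the beam translation invariant in the box", {
  sun <- sun_photon_direction(40, 75)
  ppfd_at <- function(x0, y0) {
    plate <- make_plate(0.25, x0, x0 + 0.04, y0, y0 + 0.04)
    scene <- scene_from_meshes(plate, box02)
    tr <- trace_timepoint(scene, sun, 1200, 0,
                          cfg = fast_cfg(seed = 9, rays_per_m2 = 2e6))
    mu <- sum(tr$ppfd * tr$face_area) / sum(tr$face_area)
    se <- sqrt(sum((tr$se * tr$face_area)^2)) / sum(tr$face_area)
    c(mu, se)
  }
  center <- ppfd_at(-0.02, -0.02)
  corner <- ppfd_at(0.05, -0.09)  # hugs the box edge: beam must wrap
  expect_lt(abs(center[1L] - corner[1L]),
            3 * sqrt(center[2L]^2 + corner[2L]^2) + 1e-6)
  expect_equal(center[1L], 1200 * sin(40 * pi / 180), tolerance = 0.05)
})

test_that("two stacked plates reproduce the closed-form transmission", {
  upper <- make_plate(0.5)
  lower <- make_plate(0.2)
  scene <- scene_from_meshes(list(upper, lower), box02)

  # opaque upper plate: nothing reaches the lower one
  tr0 <- trace_timepoint(scene, down, 1300, 0, optics = leaf_optics(0, 0),
                         cfg = fast_cfg(seed = 3))
  expect_equal(tr0$ppfd[3:4], c(0, 0))
  aud <- energy_audit(tr0)
  expect_equal(aud[["absorbed"]], aud[["incident"]], tolerance = 1e-12)

  # scattering leaves: lower plate sees tau * I / (1 - rho^2) from the
  # infinite interreflection series (the periodic box loses nothing sideways)
  rho <- 0.075
  tau <- 0.075
  tr1 <- trace_timepoint(scene, down, 1300, 0, optics = leaf_optics(rho, tau),
                         cfg = fast_cfg(seed = 3, rays_per_m2 = 2e6))
  lower_mean <- sum(tr1$ppfd[3:4] * tr1$face_area[3:4]) /
    sum(tr1$face_area[3:4])
  lower_se <- sqrt(sum((tr1$se[3:4] * tr1$face_area[3:4])^2)) /
    sum(tr1$face_area[3:4])
  expect_lt(abs(lower_mean - tau * 1300 / (1 - rho^2)), 3 * lower_se + 0.5)
})

test_that("photon energy is conserved through a full canopy trace", {
  scene <- small_canopy()
  pos <- solar_position(solar_config(), 10)
  irr <- incident_ppfd(solar_config(), pos[["elevation"]])
  tr <- trace_timepoint(scene, sun_photon_direction(pos[[1L]], pos[[2L]]),
                        irr[[1L]], irr[[2L]], cfg = fast_cfg(seed = 8))
  aud <- energy_audit(tr)
  expect_lt(abs(aud[["closure"]]), 0.01)
  expect_true(all(tr$ppfd >= 0))
})

test_that("tracing is deterministic for a fixed seed", {
  scene <- small_canopy()
  sun <- sun_photon_direction(50, 90)
  a <- trace_timepoint(scene, sun, 1000, 300, cfg = fast_cfg(seed = 77))
  b <- trace_timepoint(scene, sun, 1000, 300, cfg = fast_cfg(seed = 77))
  expect_identical(a$ppfd, b$ppfd)
  c <- trace_timepoint(scene, sun, 1000, 300, cfg = fast_cfg(seed = 78))
  expect_false(identical(a$ppfd, c$ppfd))
})

test_that("an opaque cover above the canopy never brightens a face", {
  plant <- small_plant()
  open <- scene_from_meshes(plant, box02)
  half_plate <- make_plate(0.9, 0, 0.1, -0.1, 0.1)  # covers half the box
  covered <- scene_from_meshes(list(half_plate, plant), box02)
  sun <- sun_photon_direction(60, 180)
  cfg <- fast_cfg(seed = 12, rays_per_m2 = 1e6)
  a <- trace_timepoint(open, sun, 1000, 0, optics = leaf_optics(0, 0),
                       cfg = cfg)
  b <- trace_timepoint(covered, sun, 1000, 0, optics = leaf_optics(0, 0),
                       cfg = cfg)
  nplate <- 2L
  b_ppfd <- b$ppfd[-seq_len(nplate)]
  b_se <- b$se[-seq_len(nplate)]
  expect_true(all(b_ppfd <= a$ppfd + 3 * (a$se + b_se) + 1e-6))
})

test_that("the accelerated intersector agrees with an all-faces oracle", {
  plant <- generate_plant()
  set.seed(21)
  n <- 120L
  origins <- cbind(runif(n, -0.3, 0.3), runif(n, -0.3, 0.3),
                   runif(n, 0.2, 0.9))
  dirs <- matrix(rnorm(3L * n), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  got <- windcanopy:::first_hit(plant, origins, dirs)
  for (i in seq_len(n)) {
    want <- oracle_first_hit(plant, origins[i, ], dirs[i, ])
    expect_equal(got$face[i], want$face)
    if (want$face > 0L) expect_equal(got$t[i], want$t, tolerance = 1e-9)
  }
})

test_that("a day simulation has the documented grid and night handling", {
  scene <- scene_from_meshes(make_plate(0.3), box02)
  cfg <- fast_cfg(rays_per_m2 = 1e4)
  series <- simulate_day(scene, solar_config(), cfg = cfg,
                         window = c(5.5, 18.5), step = 1)
  expect_equal(length(series$times), 781L)
  expect_true(all(series$ppfd >= 0))
  # before sunrise (~5.59 h at 14 N on day 181) the series is zero
  pre_dawn <- series$times < 5.58
  expect_true(all(series$ppfd[, pre_dawn] == 0))

  night <- simulate_day(scene, solar_config(), cfg = cfg,
                        window = c(0, 4), step = 30)
  expect_true(all(night$ppfd == 0))
  expect_error(simulate_day(scene, window = c(8, 8)), "window")
})

test_that("coarsening the time grid changes daily interception by under 1%", {
  scene <- scene_from_meshes(generate_plant(), box02)
  cfg <- fast_cfg(seed = 6, rays_per_m2 = 3e5, n_batches = 4L)
  fine <- simulate_day(scene, cfg = cfg, window = c(10, 14), step = 1)
  coarse <- simulate_day(scene, cfg = cfg, window = c(10, 14), step = 10)
  tl_fine <- total_light_per_area(fine, window = c(10, 14))
  tl_coarse <- total_light_per_area(coarse, window = c(10, 14))
  expect_equal(tl_coarse, tl_fine, tolerance = 0.01)
})
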