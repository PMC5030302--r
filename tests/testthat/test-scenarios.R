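test_that("PPFD area distributions bin area fractions correctly", {
  # all faces at PPFD 100 with bin 50: single bin [100, 150)
  d <- ppfd_area_distribution(rep(100, 4L), rep(2e-4, 4L), rep(1L, 4L),
                              bin_width = 50)
  expect_equal(sum(d$fraction), 1)
  expect_equal(d$fraction[d$bin_lo == 100], 1)
  # two equal-area faces at 10 and 1000: 0.5 each
  d2 <- ppfd_area_distribution(c(10, 1000), c(1e-4, 1e-4), c(1L, 1L),
                               bin_width = 100)
  expect_equal(d2$fraction[d2$bin_lo == 0], 0.5)
  expect_equal(d2$fraction[d2$bin_lo == 1000], 0.5)
  # fractions sum to 1 per layer for arbitrary inputs
  set.seed(3)
  d3 <- ppfd_area_distribution(runif(60, 0, 2000), runif(60, 1e-5, 1e-3),
                               sample(1:3, 60, TRUE), bin_width = 100)
  sums <- tapply(d3$fraction, d3$layer, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("distribution differences are signed, zero-sum and antisymmetric", {
  set.seed(8)
  ppfd <- runif(40, 0, 1200)
  areas <- runif(40, 1e-5, 1e-3)
  layer <- rep(1L, 40L)
  fa <- ppfd_area_distribution(ppfd, areas, layer, 100)
  fb <- ppfd_area_distribution(rev(ppfd), areas, layer, 100)
  expect_equal(distribution_percent_difference(fa, fa)$diff_pp,
               rep(0, nrow(fa)))
  dab <- distribution_percent_difference(fa, fb)
  dba <- distribution_percent_difference(fb, fa)
  expect_equal(sum(dab$diff_pp), 0, tolerance = 1e-9)
  expect_equal(dab$diff_pp, -dba$diff_pp)
  fb_bad <- ppfd_area_distribution(ppfd, areas, layer, 200)
  expect_error(distribution_percent_difference(fa, fb_bad), "mismatch")
})

test_that("carbon-gain normalisation maps min to 0 and max to 1", {
  out <- normalized_carbon(c(2, 4, 6))
  expect_equal(out$normalized, c(0, 0.5, 1))
  expect_false(out$degenerate)
  set.seed(2)
  v <- rnorm(11)
  nz <- normalized_carbon(v)$normalized
  expect_equal(min(nz), 0)
  expect_equal(max(nz), 1)
  # constant series: degenerate convention 0.5 + flag
  flat <- normalized_carbon(rep(3, 5L))
  expect_true(flat$degenerate)
  expect_equal(flat$normalized, rep(0.5, 5L))
  expect_error(normalized_carbon(1), "two values")
})

test_that("a tiny constant-wind run yields the full summary table", {
  scene <- build_canopy(small_plant(), seed = 3L)
  res <- run_constant(scene, directions = c("none", "E"), angle = 6,
                      cfg = fast_cfg(rays_per_m2 = 5e4),
                      window = c(11, 13), step = 30,
                      light_window = c(11, 13), carbon_window = c(11, 13),
                      snapshot_hours = 12, n_reps = 2L, seed = 5L)
  expect_s3_class(res, "scenario_result")
  expect_equal(nrow(res$table), 2L)
  expect_true(all(c("TLLA", "TLLA_se", "C", "C_se") %in% names(res$table)))
  expect_true(all(is.finite(res$table$TLLA)))
  # distribution fractions sum to 1 per (direction, layer)
  sums <- tapply(res$distributions$fraction,
                 interaction(res$distributions$direction,
                             res$distributions$layer, drop = TRUE), sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
               tolerance = 1e-9)
  # leaf-angle table covers the central plant
  expect_equal(nrow(res$leaf_angles),
               2L * nrow(scene$plants[[5L]]$faces))
})

test_that("doubling the solar constant exactly doubles light interception", {
  scene <- scene_from_meshes(small_plant(), c(-0.1, 0.1, -0.1, 0.1))
  cfg <- fast_cfg(seed = 14, rays_per_m2 = 1e5)
  s1 <- simulate_day(scene, solar_config(solar_constant = 2600), cfg = cfg,
                     window = c(11.5, 12.5), step = 15)
  s2 <- simulate_day(scene, solar_config(solar_constant = 5200), cfg = cfg,
                     window = c(11.5, 12.5), step = 15)
  t1 <- total_light_per_area(s1, window = c(11.5, 12.5))
  t2 <- total_light_per_area(s2, window = c(11.5, 12.5))
  expect_equal(t2, 2 * t1, tolerance = 1e-9)
})

test_that("dynamic sweep location selection finds same-leaf neighbours", {
  scene <- build_canopy(generate_plant(), seed = 6L)
  locs <- windcanopy:::select_locations(scene, 3L, 5L, seed = 2L)
  expect_length(locs, 9L)
  mesh <- windcanopy:::scene_mesh(scene)
  for (lc in locs) {
    expect_length(lc$faces, 5L)
    expect_length(unique(mesh$leaf_id[lc$faces]), 1L)  # one leaf section
    expect_true(lc$anchor %in% lc$faces)
  }
  # deterministic for a fixed seed
  locs2 <- windcanopy:::select_locations(scene, 3L, 5L, seed = 2L)
  expect_identical(lapply(locs, `[[`, "faces"), lapply(locs2, `[[`, "faces"))
})

test_that("a small dynamic run produces a complete, well-formed table", {
  scene <- build_canopy(generate_plant(), seed = 6L)
  res <- run_dynamic(scene, angles = c(0, 5, 10), times = 12,
                     cfg = fast_cfg(rays_per_m2 = 5e4), seed = 2L)
  dyn <- res$dynamic
  expect_equal(nrow(dyn), 3L * 1L * 9L)
  expect_false(any(is.na(dyn$ppfd)))
  expect_true(all(dyn$pct_diff[dyn$angle == 0] == 0))
  expect_true(all(dyn$carbon_norm >= 0 & dyn$carbon_norm <= 1))
  expect_true(all(table(dyn$location) == 3L))
})
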