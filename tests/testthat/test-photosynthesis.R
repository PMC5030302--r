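test_that("the light response has the stated dark, saturating and mid-range values", {
  top <- nrh_params(32)
  expect_equal(nrh(0, top), -3.2)           # -Rd = -alpha * pmax
  expect_equal(signif(nrh(1e6, top), 3), 32.0)  # asymptote = pmax
  # independent quadratic-root evaluation at moderate light
  for (L in c(50, 200, 500, 1500)) {
    expect_equal(nrh(L, top), oracle_nrh(L, 0.052, 0.845, 32, 0.1),
                 tolerance = 1e-10)
  }
  mid <- nrh_params(21)
  expect_equal(nrh(0, mid), -2.1)
  expect_equal(nrh(500, mid), oracle_nrh(500, 0.052, 0.845, 21, 0.1),
               tolerance = 1e-10)
})

test_that("the light response is monotone, concave, bounded and has slope phi at the origin", {
  top <- nrh_params(32)
  L <- seq(0, 3000, by = 5)
  F <- nrh(L, top)
  expect_true(all(diff(F) > 0))
  expect_true(all(diff(diff(F)) < 1e-9))  # concave
  expect_true(all(F <= 32 + 1e-9))
  expect_true(all(F >= -3.2 - 1e-12))
  slope <- (nrh(1e-3, top) - nrh(0, top)) / 1e-3
  expect_equal(slope, 0.052, tolerance = 1e-3)
})

test_that("the theta -> 0 limit is the rectangular hyperbola", {
  p <- nrh_params(32, theta = 1e-8)
  L <- c(10, 100, 800, 2500)
  rect <- 0.052 * L * (1.1 * 32) / (0.052 * L + 1.1 * 32) - 0.1 * 32
  expect_equal(nrh(L, p), rect, tolerance = 1e-6)
})

test_that("layer assignment partitions faces into equal-depth thirds", {
  p <- generate_plant()
  la <- assign_layers(p)
  expect_length(la$layer, 600L)
  expect_true(all(la$layer %in% 1:3))
  expect_equal(sum(table(la$layer)), 600L)
  # centers land in their band; a boundary tie goes to the upper layer
  h <- la$height
  top_faces <- p$center[, 3L] > 2 * h / 3
  expect_true(all(la$layer[top_faces] == 1L))
  tie <- triangle_mesh(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2),  # tie at 2/3 h
                             c(0, 0, 3), c(1, 0, 3), c(0, 1, 3)),
                       rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  la2 <- assign_layers(tie)
  expect_equal(la2$layer, c(1L, 1L))
})

test_that("daily carbon of a constant-light face matches the closed form", {
  # synthetic series: one face, constant PPFD over 5-22 h
  times <- seq(5, 22, by = 1 / 60)
  mk <- function(L) {
    structure(list(times = times,
                   ppfd = matrix(L, 1L, length(times)),
                   face_area = 0.002), class = "light_series")
  }
  top <- nrh_params(32)
  # all-dark window: pure respiration
  expect_equal(daily_carbon_triangle(mk(0), top),
               0.002 * (-3.2) * 17 * 3600, tolerance = 1e-9)
  # constant light
  Lstar <- 700
  expect_equal(daily_carbon_triangle(mk(Lstar), top),
               0.002 * nrh(Lstar, top) * 17 * 3600, tolerance = 1e-9)
  expect_error(daily_carbon_triangle(mk(0), top, window = c(4, 22)), "cover")
})

test_that("trapezoidal carbon integration is stable under grid refinement", {
  # smooth synthetic diurnal light course
  f <- function(t) 1800 * pmax(0, sin(pi * (t - 6) / 12))^1.5
  series_at <- function(step) {
    t <- seq(5, 22, by = step / 60)
    structure(list(times = t, ppfd = matrix(f(t), 1L, length(t)),
                   face_area = 0.002), class = "light_series")
  }
  p1 <- daily_carbon_triangle(series_at(10), nrh_params(32))
  p2 <- daily_carbon_triangle(series_at(1), nrh_params(32))
  expect_equal(p1, p2, tolerance = 0.005)
})

test_that("canopy aggregates equal brute-force sums and are intensive", {
  set.seed(13)
  n <- 40L
  P <- rnorm(n, 500, 200)
  S <- runif(n, 1e-4, 4e-4)
  C <- canopy_carbon_per_area(P, S)
  expect_equal(C, sum(P) / sum(S) / 1e6, tolerance = 1e-15)
  expect_equal(C * sum(S) * 1e6, sum(P), tolerance = 1e-9)
  # one face, and duplicated faces, give the same intensity
  expect_equal(canopy_carbon_per_area(P[1L], S[1L]), P[1L] / S[1L] / 1e6)
  expect_equal(canopy_carbon_per_area(rep(P[1L], 2L), rep(S[1L], 2L)),
               canopy_carbon_per_area(P[1L], S[1L]))
  expect_error(canopy_carbon_per_area(P, S[-1L]), "length")
})

test_that("daily light interception matches constants and a brute-force double sum", {
  times <- seq(5, 22, by = 1 / 6)
  n <- 15L
  # constant field: TLLA = L * 13 h in mol
  const <- structure(list(times = times,
                          ppfd = matrix(1000, n, length(times)),
                          face_area = runif(n, 1e-4, 5e-4)),
                     class = "light_series")
  expect_equal(total_light_per_area(const), 1000 * 13 * 3600 / 1e6,
               tolerance = 1e-9)
  # all-dark series
  dark <- const
  dark$ppfd[] <- 0
  expect_equal(total_light_per_area(dark), 0)
  # random field vs an independent loop over (face, time)
  set.seed(29)
  rnd <- const
  rnd$ppfd <- matrix(runif(n * length(times), 0, 2000), n)
  got <- total_light_per_area(rnd, window = c(5.5, 18.5))
  idx <- which(times >= 5.5 & times <= 18.5)
  acc <- 0
  for (i in seq_len(n)) {
    integ <- 0
    for (j in idx[-length(idx)]) {
      integ <- integ + (rnd$ppfd[i, j] + rnd$ppfd[i, j + 1L]) / 2 *
        (times[j + 1L] - times[j]) * 3600
    }
    acc <- acc + rnd$face_area[i] * integ
  }
  expect_equal(got, acc / sum(rnd$face_area) / 1e6, tolerance = 1e-12)
})

test_that("aggregates are invariant to face relabelling and splitting", {
  times <- seq(5.5, 18.5, by = 0.25)
  n <- 10L
  set.seed(41)
  ppfd <- matrix(runif(n * length(times), 0, 1500), n)
  S <- runif(n, 1e-4, 4e-4)
  mk <- function(p, s) structure(list(times = times, ppfd = p, face_area = s),
                                 class = "light_series")
  base <- total_light_per_area(mk(ppfd, S))
  perm <- sample(n)
  expect_equal(total_light_per_area(mk(ppfd[perm, ], S[perm])), base,
               tolerance = 1e-12)
  # split face 1 into two halves with identical light course
  split_p <- rbind(ppfd[1L, ], ppfd)
  split_s <- c(S[1L] / 2, S[1L] / 2, S[-1L])
  expect_equal(total_light_per_area(mk(split_p, split_s)), base,
               tolerance = 1e-12)
})
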