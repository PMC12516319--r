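test_that("generators are bit-identical under a fixed seed", {
  m1 <- makeOrganoidMask(120, 30, 0.004, 2, boundary_noise_px = 1, seed = 6)
  m2 <- makeOrganoidMask(120, 30, 0.004, 2, boundary_noise_px = 1, seed = 6)
  expect_identical(maskPixels(m1$mask), maskPixels(m2$mask))

  t1 <- makeTracks(4, "brownian", seed = 9)
  t2 <- makeTracks(4, "brownian", seed = 9)
  expect_identical(t1$tracks, t2$tracks)
  expect_false(identical(t1$tracks,
                         makeTracks(4, "brownian", seed = 10)$tracks))

  l1 <- makeTimelapse(40, 0.01, c(1, 0), 5, 30, 1, 1, seed = 2)
  l2 <- makeTimelapse(40, 0.01, c(1, 0), 5, 30, 1, 1, seed = 2)
  expect_identical(l1$masks, l2$masks)

  sc <- capsuleScene(150, 40, 0, psz = 2, seed = 1)
  ax <- medialAxis(sc$mask)
  k1 <- makeMarkerImage(sc$mask, ax, list(list(midpoint = 0.5)), seed = 3)
  k2 <- makeMarkerImage(sc$mask, ax, list(list(midpoint = 0.5)), seed = 3)
  expect_identical(k1$image, k2$image)

  n1 <- makeNucleiPlane(sc$mask, 4, seed = 5)
  n2 <- makeNucleiPlane(sc$mask, 4, seed = 5)
  expect_identical(n1$image, n2$image)

  # generation does not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makeTracks(2, "brownian", seed = 1))
  expect_identical(runif(1), before)
})

test_that("capsule truth carries the closed-form length and straightness", {
  st <- makeOrganoidMask(200, 50, 0, 1, seed = 1)
  expect_equal(st$truth$length_um, 300)
  expect_equal(st$truth$straightness, 1)

  # near-semicircular centerline: chord/arc in closed form
  R <- 100; phi <- 0.95 * pi; a <- phi * R
  sem <- makeOrganoidMask(a, 25, 1 / R, 2, seed = 2)
  tipA <- c(0, 0) - 25 * c(1, 0)
  tipB <- c(R * sin(phi), R * (1 - cos(phi))) + 25 * c(cos(phi), sin(phi))
  expect_equal(sem$truth$straightness,
               sqrt(sum((tipB - tipA)^2)) / (a + 50))

  expect_error(makeOrganoidMask(200, 50, pi / 150, 1, seed = 1),
               "self-intersecting")
})

test_that("marker truth records boundaries and pole multiplicity", {
  sc <- capsuleScene(150, 40, 0, psz = 2, seed = 1)
  ax <- medialAxis(sc$mask)
  one <- makeMarkerImage(sc$mask, ax, list(list(midpoint = 0.6)), seed = 1)
  expect_equal(one$truth$boundaries, 0.6)
  expect_equal(one$truth$pole_count, 1L)
  two <- makeMarkerImage(sc$mask, ax,
                         list(list(midpoint = 0.2, direction = "falling"),
                              list(midpoint = 0.8)), seed = 1)
  expect_equal(two$truth$pole_count, 2L)
  expect_equal(two$truth$directions, c("falling", "rising"))
  flat <- makeMarkerImage(sc$mask, ax, list(), noise_sd = 0, seed = 1)
  expect_equal(flat$truth$pole_count, 0L)
  expect_equal(unique(flat$image[maskPixels(sc$mask)]), 0.05)
  expect_error(makeMarkerImage(sc$mask, ax, list(list(midpoint = 1.2)),
                               seed = 1), "midpoints")
})

test_that("nuclei planes respect separation and report their centres", {
  sc <- capsuleScene(150, 60, 0, psz = 1, seed = 77)
  np <- makeNucleiPlane(sc$mask, 6, min_separation_px = 20, seed = 4)
  expect_equal(np$truth$n_spots, 6L)
  d <- as.matrix(dist(np$truth$centers_px))
  expect_true(all(d[upper.tri(d)] >= 20))
  z <- makeNucleiPlane(sc$mask, 0, background_noise_sd = 0, seed = 1)
  expect_true(all(z$image == 10))
  expect_error(makeNucleiPlane(sc$mask, 50, min_separation_px = 60, seed = 1),
               "placement failed")
})

test_that("track generator honours its motion models", {
  bal <- makeTracks(2, "ballistic", v = 0.07, n_points = 6,
                    localization_noise_um = 0, seed = 1)
  expect_equal(meanSpeed(bal$tracks[bal$tracks$track_id == "tr001", ]), 0.07,
               tolerance = 1e-12)
  conf <- makeTracks(30, "confined", D = 0.05, confinement_radius = 3,
                     n_points = 60, localization_noise_um = 0, seed = 2)
  # stationary RMS radius close to the requested confinement radius
  tail_pts <- conf$tracks[conf$tracks$t > 400, ]
  expect_equal(sqrt(mean(tail_pts$x^2 + tail_pts$y^2 + tail_pts$z^2)), 3,
               tolerance = 0.2)
  expect_true(all(tapply(conf$tracks$t, conf$tracks$track_id,
                         function(v) all(diff(v) > 0))))
})

test_that("time-lapse generator keeps its stated growth and drift", {
  tl <- makeTimelapse(40, 0, c(0, 0), 6, 30, 1, 0, seed = 1)
  mo <- timelapseMotion(tl$masks, 1, 30)
  # zero drift: centroid moves less than half a pixel per frame
  steps <- sqrt(rowSums(diff(as.matrix(mo$centroid_track[, c("x", "y")]))^2))
  expect_true(all(steps <= 0.5))
  expect_equal(diff(range(mo$effective_radius_series$r_um)), 0,
               tolerance = 1e-6)
  expect_error(makeTimelapse(40, 10, c(0, 0), 25, 30, 1, 0, seed = 1),
               "field of view")
})

test_that("generated masks satisfy downstream preconditions", {
  set.seed(31)
  for (i in 1:4) {
    sc <- makeOrganoidMask(runif(1, 80, 220), runif(1, 25, 60),
                           runif(1, -1, 1) / 200, 2,
                           boundary_noise_px = sample(0:1, 1), seed = 900 + i)
    expect_true(validObject(sc$mask))
    ax <- medialAxis(sc$mask)
    expect_true(ax@length_um >= ax@chord_um && ax@chord_um > 0)
    sides <- splitContour(sc$mask, ax)
    expect_equal(dim(sides$side_A), c(101L, 2L))
  }
})
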