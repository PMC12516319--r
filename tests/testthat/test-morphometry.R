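test_that("medial-axis length matches the capsule closed form", {
  sc <- makeOrganoidMask(200, 50, 0, pixel_size_um = 1, seed = 1)
  ax <- medialAxis(sc$mask)
  expect_equal(ax@length_um, 300, tolerance = 0.03)
  expect_equal(straightness(ax), 1, tolerance = 0.01)
  expect_true(ax@length_um >= ax@chord_um)
})

test_that("medial-axis length is exact in declared pixel size and stable in resolution", {
  sc <- capsuleScene(200, 50, 0.005, psz = 1, seed = 9)
  L1 <- medialAxis(sc$mask)@length_um
  # same pixel mask declared at twice the calibration: exactly linear
  m2 <- OrganoidMask(maskPixels(sc$mask), 2)
  expect_equal(medialAxis(m2)@length_um, 2 * L1, tolerance = 1e-9)
  # same physical shape rendered at half the pixel size: within 1%
  fine <- makeOrganoidMask(200, 50, 0.005, pixel_size_um = 0.5, seed = 9)
  expect_equal(medialAxis(fine$mask)@length_um, L1, tolerance = 0.01)
})

test_that("a disk degenerates to a diameter-length axis", {
  dsk <- makeOrganoidMask(2, 100, 0, pixel_size_um = 1, seed = 3)
  expect_equal(medialAxis(dsk$mask)@length_um, 202, tolerance = 0.05)
})

test_that("straightness closed forms hold on analytic paths", {
  straight <- cbind(seq(0, 10, length.out = 50), 0)
  expect_equal(straightness(straight), 1)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(cos(th), sin(th))
  expect_equal(straightness(semi), 2 / pi, tolerance = 1e-4)
  arm <- cbind(c(seq(0, 1, length.out = 20), rep(1, 20)),
               c(rep(0, 20), seq(0, 1, length.out = 20)))
  expect_equal(straightness(arm), sqrt(2) / 2, tolerance = 1e-9)
  expect_error(straightness(cbind(c(1, 1), c(2, 2))), "zero-length")
})

test_that("semicircular-axis organoid recovers 2/pi straightness", {
  R <- 150; r <- 20
  sem <- makeOrganoidMask((pi - 2 * r / R) * R, r, 1 / R,
                          pixel_size_um = 1, seed = 5)
  ax <- medialAxis(sem$mask)
  expect_equal(straightness(ax), 2 / pi, tolerance = 0.02 / (2 / pi))
  expect_equal(straightness(ax, orientation = "arc-over-chord"),
               1 / straightness(ax))
})

test_that("elongation index matches closed forms and is scale invariant", {
  dsk <- makeOrganoidMask(2, 100, 0, pixel_size_um = 1, seed = 3)
  expect_lt(elongationIndex(dsk$mask), 0.02)
  cap <- makeOrganoidMask(200, 50, 0, pixel_size_um = 1, seed = 1)
  expect_equal(elongationIndex(cap$mask), capsuleEI(200, 50),
               tolerance = 0.01 / 0.314)
  # doubling every physical dimension leaves EI unchanged
  big <- makeOrganoidMask(400, 100, 0, pixel_size_um = 2, seed = 1)
  expect_equal(elongationIndex(big$mask), elongationIndex(cap$mask),
               tolerance = 0.01)
})

test_that("aspect ratio matches second-moment closed forms", {
  dsk <- capsuleScene(2, 100, 0, psz = 2, seed = 3)
  expect_equal(aspectRatio(dsk$mask), 1, tolerance = 0.02)
  n <- 200
  x <- matrix(rep(seq_len(300) - 1, each = n), n, 300)
  y <- matrix(rep(seq_len(n) - 1, 300), n, 300)
  ell <- ((x - 150) / 100)^2 + ((y - 100) / 50)^2 <= 1
  expect_equal(aspectRatio(OrganoidMask(ell, 1)), 2, tolerance = 0.02)
})

test_that("shape descriptors are rotation and scale invariant on random capsules", {
  set.seed(11)
  for (i in 1:4) {
    k <- runif(1, -1, 1) / 200
    rot <- runif(1, 15, 165)
    s1 <- capsuleScene(180, 45, k, psz = 2, seed = i)
    s2 <- capsuleScene(180, 45, k, psz = 2, seed = i, rotation = rot)
    expect_equal(elongationIndex(s2$mask), elongationIndex(s1$mask),
                 tolerance = 0.02)
    expect_equal(aspectRatio(s2$mask), aspectRatio(s1$mask),
                 tolerance = 0.02)
    expect_equal(straightness(medialAxis(s2$mask)),
                 straightness(medialAxis(s1$mask)), tolerance = 0.02)
  }
})

test_that("bent capsules recover analytic length and straightness", {
  set.seed(42)
  for (i in 1:6) {
    k <- runif(1, -1.3, 1.3) / 200
    s <- capsuleScene(200, 50, k, psz = 1, seed = 20 + i)
    ax <- medialAxis(s$mask)
    expect_equal(ax@length_um, s$truth$length_um, tolerance = 0.03)
    expect_equal(straightness(ax), s$truth$straightness, tolerance = 0.02)
  }
})

test_that("morphometry records assemble all descriptors", {
  sc <- capsuleScene(200, 50, 0, psz = 2, seed = 1)
  rec <- morphometry(sc$mask, organoid_id = "g1")
  expect_named(rec, c("organoid_id", "length_um", "straightness",
                      "elongation_index", "aspect_ratio", "area_um2",
                      "perimeter_um"))
  expect_equal(rec$area_um2, areaUm2(sc$mask))
  expect_true(rec$aspect_ratio >= 1 && rec$straightness <= 1)
})

test_that("time-lapse motion recovers translation and growth", {
  # static series
  tls <- makeTimelapse(50, 0, c(0, 0), n_frames = 5, frame_interval_min = 30,
                       pixel_size_um = 1, seed = 1)
  mo <- timelapseMotion(tls$masks, 1, 30)
  expect_equal(mo$total_displacement_um, 0, tolerance = 1e-9)
  expect_equal(mo$radial_growth_rate_um_per_min, 0, tolerance = 1e-9)
  expect_equal(diff(range(mo$effective_radius_series$r_um)), 0,
               tolerance = 1e-9)

  # 3-4-5 translation: 5 um centroid step per frame
  tlt <- makeTimelapse(40, 0, c(3, 4), n_frames = 6, frame_interval_min = 30,
                       pixel_size_um = 1, seed = 2)
  mot <- timelapseMotion(tlt$masks, 1, 30)
  expect_equal(mot$total_displacement_um, 5 * 5, tolerance = 0.02)

  expect_error(timelapseMotion(tls$masks[1:2], 1, 30), "3 frames")
})

test_that("radial growth rate is recovered under boundary noise", {
  tl <- makeTimelapse(r0_um = 50, radial_growth_um_per_min = 0.015,
                      drift_um_per_frame = c(1.5, -2), n_frames = 25,
                      frame_interval_min = 30, pixel_size_um = 1,
                      boundary_noise_px = 1, seed = 12)
  mo <- timelapseMotion(tl$masks, 1, 30)
  expect_equal(mo$radial_growth_rate_um_per_min, 0.015, tolerance = 0.05)
})
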