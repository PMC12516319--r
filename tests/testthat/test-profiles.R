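library(SummarizedExperiment)

test_that("contour splitting yields two equal-length capsule sides", {
  ps <- profileScene(seed = 3)
  sides <- splitContour(ps$scene$mask, ps$axis)
  lenA <- sum(sqrt(rowSums(diff(sides$side_A)^2)))
  lenB <- sum(sqrt(rowSums(diff(sides$side_B)^2)))
  expect_equal(lenA, lenB, tolerance = 0.01)
  expect_equal(nrow(sides$side_A), 101L)
  # both sides start and end exactly at the axis tips
  expect_equal(sides$side_A[1, ], unname(ps$axis@endpoints[1, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sides$side_B[101, ], unname(ps$axis@endpoints[2, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a rectangle splits into its two long edges", {
  m <- matrix(FALSE, 70, 220); m[11:60, 11:210] <- TRUE
  om <- OrganoidMask(m, 1)
  ax <- medialAxis(om)
  expect_equal(ax@length_um, 200, tolerance = 0.01)
  sides <- splitContour(om, ax)
  # each side spans a long edge plus two half short edges: 199 + 2*25
  expect_equal(sum(sqrt(rowSums(diff(sides$side_A)^2))), 249,
               tolerance = 0.02)
  # one side lies above, the other below the axis
  expect_gt(mean(sides$side_A[, 2]), mean(ps <- ax@points[, 2]))
  expect_lt(mean(sides$side_B[, 2]), mean(ps))
})

test_that("off-contour axis endpoints are rejected", {
  ps <- profileScene(seed = 3)
  bad <- ps$axis
  bad@points[1, ] <- bad@points[1, ] + c(5, 5)
  bad@endpoints[1, ] <- bad@points[1, ]
  expect_error(splitContour(ps$scene$mask, bad), "off the contour")
})

test_that("rectangle bins reproduce the analytic 2 x 50 tiling", {
  # sides constructed as the two long edges of a 200 x 50 rectangle
  xs <- seq(0, 200, length.out = 101)
  sides <- list(side_A = cbind(xs, 50), side_B = cbind(xs, 0))
  m <- matrix(FALSE, 61, 211); m[6:55, 6:205] <- TRUE
  om <- OrganoidMask(m, 1)
  axis_pts <- cbind(seq(0, 200, length.out = 201), 25)
  ax <- new("MedialAxisPath", points = axis_pts, length_um = 200,
            chord_um = 200, endpoints = axis_pts[c(1, 201), ])
  # rectangle pixel centres sit at x = 5..204; place the section lines
  # half a pixel off the centres so each 2 x 50 bin holds two columns
  sides <- list(side_A = cbind(xs + 4.5, 55), side_B = cbind(xs + 4.5, 5))
  ax@points <- ax@points + matrix(c(4.5, 5), 201, 2, byrow = TRUE)
  ax@endpoints <- ax@points[c(1, 201), ]
  bn <- makeBins(sides, om, ax)
  expect_equal(bn@bin_areas_um2, rep(100, 100), tolerance = 1e-9)
  counts <- tabulate(bn@assignment[!is.na(bn@assignment)], 100)
  expect_equal(counts, rep(100L, 100))
  expect_equal(bn@positions, (1:100 - 0.5) / 100, tolerance = 1e-9)
})

test_that("bins tile the mask and reverse exactly under side reversal", {
  set.seed(4)
  for (i in 1:3) {
    k <- runif(1, -1, 1) / 200
    ps <- profileScene(curvature = k, seed = 30 + i)
    bn <- ps$binning
    expect_equal(sum(bn@bin_areas_um2), areaUm2(ps$scene$mask),
                 tolerance = 0.03)
    expect_true(all(diff(bn@positions) > 0))
    # every foreground pixel is assigned
    expect_equal(sum(!is.na(bn@assignment)), sum(maskPixels(ps$scene$mask)))
  }
  ps <- profileScene(seed = 3)
  sides <- splitContour(ps$scene$mask, ps$axis)
  rev_sides <- list(
    side_A = sides$side_B[rev(seq_len(101)), ],
    side_B = sides$side_A[rev(seq_len(101)), ])
  bn1 <- ps$binning
  bn2 <- makeBins(rev_sides, ps$scene$mask, ps$axis)
  a1 <- bn1@assignment; a2 <- bn2@assignment
  keep <- !is.na(a1)
  expect_identical(a1[keep], 101L - a2[keep])
})

test_that("profile extraction is exact on constant images", {
  ps <- profileScene(seed = 3)
  img <- matrix(4.2, nrow(maskPixels(ps$scene$mask)),
                ncol(maskPixels(ps$scene$mask)))
  p <- extractProfile(img, ps$binning)
  expect_equal(assay(p, "raw")[, 1], rep(4.2, 100),
               ignore_attr = TRUE)
})

test_that("a linear axial gradient yields a linear profile", {
  m <- matrix(FALSE, 70, 220); m[11:60, 11:210] <- TRUE
  om <- OrganoidMask(m, 1)
  ax <- medialAxis(om)
  bn <- makeBins(splitContour(om, ax), om, ax)
  img <- matrix(rep(seq_len(220) - 1, each = 70), 70, 220) # I = x
  p <- extractProfile(img, bn)
  raw <- assay(p, "raw")[, 1]; pos <- assay(p, "position")[, 1]
  # expected bin means: x at tip + position * L; 1 bin width = 2 um
  expect_lt(max(abs(raw - (10 + pos * 200))), 2)
  # blunt ends produce sub-pixel sections (imputed); the measured
  # interior must be strictly monotone
  interior <- setdiff(12:90, colData(p)$imputed_bins[[1]])
  expect_true(all(diff(raw[interior]) > 0))
})

test_that("noiseless logistic images round-trip through the profile", {
  ps <- profileScene(seed = 3)
  mk <- makeMarkerImage(ps$scene$mask, ps$axis,
                        list(list(midpoint = 0.6, steepness = 20)),
                        noise_sd = 0, seed = 1)
  p <- extractProfile(mk$image, ps$binning)
  raw <- assay(p, "raw")[, 1]; pos <- assay(p, "position")[, 1]
  truth <- logisticProfile(pos, 0.6)
  # within one bin's worth of profile change (max slope 5/unit x 0.01)
  expect_lt(max(abs(raw - truth)), 5 * 0.01 + 1e-6)
})

test_that("empty bins are imputed from neighbours and flagged", {
  ps <- profileScene(seed = 3)
  bn <- ps$binning
  bn@assignment[bn@assignment == 50L] <- 49L   # manufacture an empty bin
  img <- matrix(rep(seq_len(ncol(bn@assignment)) - 1, each = nrow(bn@assignment)),
                nrow(bn@assignment))
  p <- extractProfile(img, bn)
  expect_true(50L %in% colData(p)$imputed_bins[[1]])
  raw <- assay(p, "raw")[, 1]
  expect_equal(raw[50], mean(raw[c(49, 51)]))
})

test_that("cohort normalization maps decile anchors to 0 and 1", {
  prof <- c(rep(10, 12), seq(20, 100, length.out = 76), rep(110, 12))
  pos <- matrix(rep((1:100 - 0.5) / 100, 2), 100, 2)
  aps <- profileSet(cbind(prof, prof), pos, c("a", "b"))
  nn <- assay(normalizeCohort(aps), "normalized")
  expect_equal(min(nn), 0)
  expect_equal(max(nn), 1)
  anchors <- S4Vectors::metadata(normalizeCohort(aps))$anchors
  expect_equal(anchors$low, 10)
  expect_equal(anchors$high, 110)
})

test_that("normalization is bit-identical under affine intensity maps", {
  set.seed(2)
  raw <- matrix(sample(10:110, 500, TRUE), 100, 5)
  pos <- matrix(rep((1:100 - 0.5) / 100, 5), 100, 5)
  n1 <- assay(normalizeCohort(profileSet(raw, pos, paste0("o", 1:5))),
              "normalized")
  n2 <- assay(normalizeCohort(profileSet(3 * raw + 7, pos, paste0("o", 1:5))),
              "normalized")
  expect_identical(n1, n2)
})

test_that("flat cohorts are rejected", {
  pos <- matrix(rep((1:100 - 0.5) / 100, 3), 100, 3)
  flat <- profileSet(matrix(5, 100, 3), pos, paste0("f", 1:3))
  expect_error(normalizeCohort(flat), "flat cohort")
  single <- profileSet(matrix(runif(100), 100, 1), pos[, 1, drop = FALSE], "s")
  expect_error(normalizeCohort(single), "fewer than 2")
})

test_that("boundary positions are found at the half-maximum crossing", {
  pos <- (1:100 - 0.5) / 100
  stepv <- c(rep(0, 40), rep(1, 60))
  expect_equal(boundaryPosition(stepv, pos, "rising", c(0, 1)), 0.4,
               tolerance = 0.005)
  expect_equal(boundaryPosition(1 - stepv, pos, "falling", c(0, 1)), 0.4,
               tolerance = 0.005)
  lg <- logisticProfile(pos, 0.6)
  expect_equal(boundaryPosition(lg, pos, "rising", c(0, 1)), 0.6,
               tolerance = 0.01)
  expect_error(boundaryPosition(rep(0.5, 100) + pos * 1e-9, pos,
                                "falling", c(0, 1)), "no falling")
})

test_that("profile reversal mirrors boundary positions exactly", {
  ps <- profileScene(seed = 3)
  mk <- makeMarkerImage(ps$scene$mask, ps$axis,
                        list(list(midpoint = 0.55, steepness = 20)),
                        noise_sd = 0.1, seed = 8)
  p <- extractProfile(mk$image, ps$binning)
  raw <- assay(p, "raw")[, 1]; pos <- assay(p, "position")[, 1]
  xb <- boundaryPosition(raw, pos, "rising", c(0, 1))
  xb_rev <- boundaryPosition(rev(raw), rev(1 - pos), "falling", c(0, 1))
  expect_equal(1 - xb_rev, xb, tolerance = 1e-12)
})

test_that("boundary recovery stays within 0.02 under 10% noise", {
  set.seed(21)
  errs <- vapply(1:12, function(i) {
    ps <- profileScene(curvature = runif(1, -1, 1) / 200, seed = 400 + i)
    mid <- runif(1, 0.2, 0.8)
    mk <- makeMarkerImage(ps$scene$mask, ps$axis,
                          list(list(midpoint = mid, steepness = 20)),
                          noise_sd = 0.1, seed = 500 + i)
    p <- extractProfile(mk$image, ps$binning)
    abs(boundaryPosition(assay(p, "raw")[, 1], assay(p, "position")[, 1],
                         "rising", c(0, 1)) - mid)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})
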