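test_that("track filtering is boundary inclusive at 10 and 25 points", {
  set.seed(1)
  trs <- do.call(rbind, Map(function(n, id) makeTrack(id, n), c(9, 10, 25, 26),
                            c("a", "b", "c", "d")))
  kept <- filterTracks(trs)
  expect_setequal(unique(kept$track_id), c("b", "c"))
  expect_equal(attr(kept, "n_kept"), 2L)
  expect_equal(attr(kept, "n_dropped"), 2L)
})

test_that("mean speed matches arithmetic and a brute-force oracle", {
  tr <- makeTrack("s", 11, dt = 20, fun = function(t) cbind(t / 20, 0, 0))
  expect_equal(meanSpeed(tr), 0.05)   # 1 um per 20-min step

  still <- makeTrack("q", 5, fun = function(t) cbind(0 * t, 0, 0))
  expect_equal(meanSpeed(still), 0)

  set.seed(8)
  rnd <- makeTrack("r", 17, fun = function(t)
    cbind(rnorm(length(t)), rnorm(length(t)), rnorm(length(t))))
  p <- as.matrix(rnd[, c("x", "y", "z")])
  oracle <- sum(sqrt(rowSums(diff(p)^2))) / (max(rnd$t) - min(rnd$t))
  expect_equal(meanSpeed(rnd), oracle, tolerance = 1e-12)
})

test_that("confinement ratio spans straight motion to closed loops", {
  straight <- makeTrack("s", 8, fun = function(t) cbind(t, 2 * t, 0))
  expect_equal(confinementRatio(straight), 1)
  loop <- makeTrack("l", 5, fun = function(t)
    cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), 0))
  expect_equal(confinementRatio(loop), 0)
  ra <- makeTrack("r", 3, fun = function(t) cbind(c(0, 1, 1), c(0, 0, 1), 0))
  expect_equal(confinementRatio(ra), sqrt(2) / 2)
})

test_that("directional change rate matches analytic turning angles", {
  straight <- makeTrack("s", 6, fun = function(t) cbind(t, t, t))
  expect_equal(as.numeric(directionalChangeRate(straight)), 0)

  zig <- makeTrack("z", 8, fun = function(t)
    cbind(c(0, 1, 1, 2, 2, 3, 3, 4), c(0, 0, 1, 1, 2, 2, 3, 3), 0))
  expect_equal(as.numeric(directionalChangeRate(zig)), (pi / 2) / 20)

  mir <- zig; mir$y <- -mir$y
  expect_equal(as.numeric(directionalChangeRate(mir)),
               as.numeric(directionalChangeRate(zig)))

  # zero-length step skipped and counted
  pause <- makeTrack("p", 5, fun = function(t) cbind(c(0, 1, 1, 2, 3), 0, 0))
  r <- directionalChangeRate(pause)
  expect_equal(attr(r, "n_skipped"), 2L)
  expect_equal(as.numeric(r), 0)
  allzero <- makeTrack("p0", 4, fun = function(t) cbind(c(0, 1, 1, 2), 0, 0))
  expect_error(directionalChangeRate(allzero), "no defined turning angles")
})

test_that("all-pairs MSD equals the brute-force double loop", {
  set.seed(3)
  for (n in c(5, 18, 30)) {
    tr <- makeTrack("m", n, fun = function(t)
      cbind(cumsum(rnorm(length(t))), cumsum(rnorm(length(t))),
            cumsum(rnorm(length(t)))))
    expect_equal(trackMSD(tr)$msd_um2, bruteMSD(tr), tolerance = 1e-12)
    expect_equal(trackMSD(tr, dims = 2)$msd_um2, bruteMSD(tr, 2),
                 tolerance = 1e-12)
  }
})

test_that("ballistic tracks give exact closed-form statistics", {
  bal <- makeTracks(3, "ballistic", v = 0.05, n_points = 11, dt_min = 20,
                    localization_noise_um = 0, seed = 4)
  tr1 <- bal$tracks[bal$tracks$track_id == "tr001", ]
  expect_equal(meanSpeed(tr1), 0.05, tolerance = 1e-12)
  expect_equal(confinementRatio(tr1), 1, tolerance = 1e-12)
  fit <- msdFit(bal$tracks, max_lag_fraction = 0.5)
  expect_equal(fit$ensemble_fit$alpha, 2, tolerance = 1e-8)
  expect_equal(fit$per_track$alpha, rep(2, 3), tolerance = 1e-8)
  # MSD(tau) = v^2 tau^2
  msd <- trackMSD(tr1)
  expect_equal(msd$msd_um2, 0.0025 * msd$lag_min^2, tolerance = 1e-10)
})

test_that("stationary tracks flag a degenerate MSD fit", {
  still <- makeTrack("s", 12, fun = function(t) cbind(0 * t, 0, 0))
  fit <- msdFit(still)
  expect_true(fit$per_track$degenerate_fit)
  expect_true(all(trackMSD(still)$msd_um2 == 0))
})

test_that("Brownian simulations recover D and alpha", {
  ests <- vapply(1:3, function(s) {
    br <- makeTracks(50, "brownian", D = 0.01, n_points = 25, dt_min = 20,
                     localization_noise_um = 0, seed = s)
    f <- msdFit(br$tracks)$ensemble_fit
    c(f$D, f$alpha)
  }, numeric(2))
  expect_equal(median(ests[1, ]), 0.01, tolerance = 0.2)
  expect_true(all(ests[2, ] >= 0.85 & ests[2, ] <= 1.15))
})

test_that("track statistics are invariant to rigid motions", {
  set.seed(12)
  tr <- makeTracks(1, "brownian", D = 0.02, n_points = 20, seed = 5)$tracks
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p2 <- as.matrix(tr[, c("x", "y", "z")]) %*% R
  tr2 <- tr
  tr2[, c("x", "y", "z")] <- sweep(p2, 2, c(10, -4, 7), "+")
  expect_equal(meanSpeed(tr2), meanSpeed(tr), tolerance = 1e-12)
  expect_equal(confinementRatio(tr2), confinementRatio(tr), tolerance = 1e-12)
  expect_equal(as.numeric(directionalChangeRate(tr2)),
               as.numeric(directionalChangeRate(tr)), tolerance = 1e-12)
  expect_equal(trackMSD(tr2)$msd_um2, trackMSD(tr)$msd_um2, tolerance = 1e-12)
})
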