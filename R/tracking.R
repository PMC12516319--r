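#' @noRd
splitTracks <- function(tracks) split(tracks, tracks$track_id)

#' @noRd
trackMatrix <- function(track, dims = 3L) {
  cols <- c("x", "y", "z")[seq_len(dims)]
  as.matrix(track[, cols, drop = FALSE])
}

#' Filter tracks by length
#'
#' Keeps tracks whose point count lies in `[min_points, max_points]`,
#' both bounds inclusive -- the track-duration filter used for the
#' light-sheet movies (trajectories of 10-25 time points).
#'
#' @param tracks track `data.frame` (`track_id`, `t`, `x`, `y`, `z`).
#' @param min_points,max_points inclusive bounds (defaults 10 and 25).
#' @return the filtered `data.frame`; attributes `n_kept`/`n_dropped`
#'   report the track counts.
#' @export
filterTracks <- function(tracks, min_points = 10L, max_points = 25L) {
  counts <- table(tracks$track_id)
  keep <- names(counts)[counts >= min_points & counts <= max_points]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- length(keep)
  attr(out, "n_dropped") <- length(counts) - length(keep)
  out
}

#' Mean speed of a track
#'
#' Sum of 3-D (or 2-D) step lengths divided by the track duration, in
#' um/min.
#'
#' @param track one track's rows (`t` in minutes, `x`/`y`/`z` in um).
#' @param dims 3 (default) or 2 (xy projection).
#' @return numeric scalar (um/min).
#' @export
meanSpeed <- function(track, dims = 3L) {
  if (nrow(track) < 2L) stop("need at least 2 points")
  dur <- max(track$t) - min(track$t)
  if (dur <= 0) stop("zero duration")
  p <- trackMatrix(track, dims)
  sum(sqrt(rowSums(diff(p)^2))) / dur
}

#' Confinement ratio of a track
#'
#' Net displacement (first to last point) divided by the total path
#' length; 1 for straight motion, 0 for a closed loop.
#'
#' @inheritParams meanSpeed
#' @return numeric in `[0, 1]`.
#' @export
confinementRatio <- function(track, dims = 3L) {
  if (nrow(track) < 2L) stop("need at least 2 points")
  p <- trackMatrix(track, dims)
  total <- sum(sqrt(rowSums(diff(p)^2)))
  if (total <= 0) stop("zero path length")
  net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  net / total
}

#' Mean directional change rate of a track
#'
#' Mean unsigned angle between consecutive displacement vectors,
#' divided by the sampling interval (rad/min). Zero-length steps leave
#' the angle undefined; those angles are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @inheritParams meanSpeed
#' @return numeric scalar (rad/min) with attribute `n_skipped`.
#' @export
directionalChangeRate <- function(track, dims = 3L) {
  if (nrow(track) < 3L) stop("need at least 3 points")
  p <- trackMatrix(track, dims)
  d <- diff(p)
  nrm <- sqrt(rowSums(d^2))
  dt <- mean(diff(track$t))
  angles <- numeric(0); skipped <- 0L
  for (i in seq_len(nrow(d) - 1L)) {
    if (nrm[i] == 0 || nrm[i + 1L] == 0) { skipped <- skipped + 1L; next }
    ct <- sum(d[i, ] * d[i + 1L, ]) / (nrm[i] * nrm[i + 1L])
    angles <- c(angles, acos(pmin(1, pmax(-1, ct))))
  }
  if (!length(angles)) stop("no defined turning angles (all steps zero)")
  out <- mean(angles) / dt
  attr(out, "n_skipped") <- skipped
  out
}

#' Time-averaged mean squared displacement of one track
#'
#' All-pairs (time-averaged) MSD: for lag `k` steps, the mean squared
#' displacement over every ordered pair of points `k` steps apart.
#' Requires uniform sampling (checked to 1% and flagged otherwise).
#'
#' @inheritParams meanSpeed
#' @return `data.frame` with `lag_min` and `msd_um2` (lag 0 omitted;
#'   MSD(0) = 0 by definition).
#' @export
trackMSD <- function(track, dims = 3L) {
  p <- trackMatrix(track, dims)
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 points")
  dt <- diff(track$t)
  uniform <- max(abs(dt - mean(dt))) <= 0.01 * mean(dt)
  if (!uniform) warning("non-uniform sampling interval (> 1% jitter)")
  step <- mean(dt)
  msd <- vapply(seq_len(n - 1L), function(k) {
    d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(lag_min = seq_len(n - 1L) * step, msd_um2 = msd)
}

#' @noRd
#' Log-log least-squares fit of MSD(tau) = 2 * dims * D * tau^alpha.
fitMSD <- function(msd, dims, max_lag_min) {
  use <- msd$lag_min <= max_lag_min & msd$msd_um2 > 0
  if (sum(use) < 3L)
    return(list(D = NA_real_, alpha = NA_real_, degenerate = TRUE))
  fit <- stats::lm(log(msd_um2) ~ log(lag_min), data = msd[use, ])
  co <- stats::coef(fit)
  list(D = exp(unname(co[1])) / (2 * dims), alpha = unname(co[2]),
       degenerate = FALSE)
}

#' Track statistics and MSD fits for a set of tracks
#'
#' Computes, per track, the motility features (mean speed, confinement
#' ratio, mean directional change rate) together with a log-log fit of
#' the time-averaged MSD, `MSD(tau) = 2 * dims * D * tau^alpha`, over
#' lags up to `max_lag_fraction` of the track duration. The ensemble
#' MSD is the mean of the per-track MSD curves at shared lags, fitted
#' the same way.
#'
#' @param tracks track `data.frame` (`track_id`, `t` min, `x`/`y`/`z` um).
#' @param max_lag_fraction fit range as a fraction of track duration
#'   (default 0.25; long-lag MSD values are high-variance).
#' @param dims 3 (default; the voxel calibration is 3-D) or 2 for
#'   xy-projected analysis.
#' @return list with `per_track` (`data.frame` of statistics, one row
#'   per track), `ensemble_msd` (`data.frame` lag/msd/n) and
#'   `ensemble_fit` (list `D`, `alpha`).
#' @export
msdFit <- function(tracks, max_lag_fraction = 0.25, dims = 3L) {
  trs <- splitTracks(tracks)
  if (!length(trs)) stop("no tracks")
  msds <- lapply(trs, trackMSD, dims = dims)
  per <- do.call(rbind, lapply(names(trs), function(id) {
    tr <- trs[[id]]
    msd <- msds[[id]]
    dur <- max(tr$t) - min(tr$t)
    f <- fitMSD(msd, dims, max_lag_fraction * dur)
    maybe <- function(expr) tryCatch(as.numeric(expr),
                                     error = function(e) NA_real_)
    data.frame(
      track_id = id,
      n_points = nrow(tr),
      duration_min = dur,
      mean_speed_um_per_min = maybe(meanSpeed(tr, dims)),
      confinement_ratio = maybe(confinementRatio(tr, dims)),
      directional_change_rate_rad_per_min =
        if (nrow(tr) >= 3L) maybe(directionalChangeRate(tr, dims)) else NA_real_,
      D_um2_per_min = f$D,
      alpha = f$alpha,
      degenerate_fit = f$degenerate
    )
  }))
  rownames(per) <- NULL
  all_lags <- sort(unique(round(unlist(lapply(msds, `[[`, "lag_min")), 9)))
  ens <- do.call(rbind, lapply(all_lags, function(l) {
    vals <- unlist(lapply(msds, function(m) m$msd_um2[abs(m$lag_min - l) < 1e-6]))
    data.frame(lag_min = l, msd_um2 = mean(vals), n_tracks = length(vals))
  }))
  med_dur <- stats::median(per$duration_min)
  ens_fit <- fitMSD(ens, dims, max_lag_fraction * med_dur)
  list(per_track = per, ensemble_msd = ens, ensemble_fit = ens_fit)
}
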