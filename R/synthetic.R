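# Synthetic-scene generator: every pipeline stage can be exercised
# against known ground truth. Each scene is produced inside
# withr::with_seed, so identical (parameters, seed) regenerate
# bit-identical artifacts and global RNG state is never touched.

#' @noRd
#' Distance from points (x, y) to a constant-curvature centerline of
#' length a starting at the origin with tangent +x, plus the clamped
#' arc-length parameter of the nearest centerline point.
arcDistance <- function(px, py, a, curvature) {
  if (abs(curvature) < 1e-12) {
    s <- pmin(a, pmax(0, px))
    list(dist = sqrt((px - s)^2 + py^2), s = s)
  } else {
    sgn <- sign(curvature)
    k <- abs(curvature)
    R <- 1 / k
    # mirror so the arc always bends upwards
    y <- sgn * py
    ux <- px; uy <- y - R
    alpha <- atan2(ux, -uy)          # = k * s on the arc
    s <- pmin(a, pmax(0, alpha / k))
    cx <- R * sin(k * s); cy <- R * (1 - cos(k * s))
    list(dist = sqrt((px - cx)^2 + (y - cy)^2), s = s)
  }
}

#' @noRd
#' Points and outward tangents of the centerline at parameters s.
arcPoint <- function(s, curvature) {
  if (abs(curvature) < 1e-12) return(cbind(s, 0 * s))
  sgn <- sign(curvature); k <- abs(curvature); R <- 1 / k
  cbind(R * sin(k * s), sgn * R * (1 - cos(k * s)))
}

#' @noRd
arcTangent <- function(s, curvature) {
  if (abs(curvature) < 1e-12) return(cbind(1 + 0 * s, 0 * s))
  sgn <- sign(curvature); k <- abs(curvature)
  cbind(cos(k * s), sgn * sin(k * s))
}

#' Synthetic organoid mask with known medial-axis ground truth
#'
#' Rasterizes a capsule (a disc of radius `cap_radius_um` swept along a
#' constant-curvature arc of length `centerline_length_um`), whose true
#' tangent-extended axis length is `centerline_length_um + 2 *
#' cap_radius_um` and whose true straightness is the chord/arc ratio of
#' that extended axis, both computed in closed form. Optional smooth
#' boundary jitter emulates segmentation noise.
#'
#' @param centerline_length_um arc length of the centerline (um).
#' @param cap_radius_um sweep radius (um).
#' @param curvature signed curvature of the centerline (1/um);
#'   `|curvature| * centerline_length_um` must stay below pi.
#' @param pixel_size_um micrometres per pixel.
#' @param rotation_deg rigid rotation of the scene.
#' @param boundary_noise_px amplitude (pixels) of a smooth radial
#'   perturbation of the boundary; 0 (default) gives the exact shape.
#' @param seed integer seed (the scene is deterministic in it).
#' @param contour_sigma_px passed to [OrganoidMask()].
#' @return list with `mask` ([OrganoidMask-class]) and `truth` (length,
#'   straightness, extended-axis endpoints, all parameters).
#' @examples
#' sc <- makeOrganoidMask(200, 50, 0, pixel_size_um = 2, seed = 1)
#' sc$truth$length_um   # 300
#' @export
makeOrganoidMask <- function(centerline_length_um, cap_radius_um,
                             curvature = 0, pixel_size_um = 1,
                             rotation_deg = 0, boundary_noise_px = 0,
                             seed = 1L, contour_sigma_px = 2) {
  a <- centerline_length_um; r <- cap_radius_um; psz <- pixel_size_um
  stopifnot(a > 0, r > 0, psz > 0)
  if (abs(curvature) * a >= pi) stop("self-intersecting sweep")
  withr::with_seed(as.integer(seed), {
    noise <- NULL
    if (boundary_noise_px > 0) {
      cf <- stats::rnorm(6); ph <- stats::runif(6, 0, 2 * pi)
      noise <- function(s) {
        f <- rowSums(vapply(1:6, function(j)
          cf[j] * cos(2 * pi * j * s / (a + 2 * r) + ph[j]), numeric(length(s))))
        f / max(abs(f), 1e-9) * boundary_noise_px * psz
      }
    }
    theta <- rotation_deg * pi / 180
    Rm <- rotationMatrix(theta)
    sref <- seq(0, a, length.out = 64)
    ref <- arcPoint(sref, curvature) %*% t(Rm)
    margin <- r + boundary_noise_px * psz + 4 * psz
    x0 <- min(ref[, 1]) - margin; x1 <- max(ref[, 1]) + margin
    y0 <- min(ref[, 2]) - margin; y1 <- max(ref[, 2]) + margin
    nx <- ceiling((x1 - x0) / psz) + 1L
    ny <- ceiling((y1 - y0) / psz) + 1L
    gx <- x0 + (seq_len(nx) - 1) * psz
    gy <- y0 + (seq_len(ny) - 1) * psz
    X <- matrix(rep(gx, each = ny), ny, nx)
    Y <- matrix(rep(gy, nx), ny, nx)
    # back to the canonical frame
    cx <- cos(theta) * X + sin(theta) * Y
    cy <- -sin(theta) * X + cos(theta) * Y
    ad <- arcDistance(as.numeric(cx), as.numeric(cy), a, curvature)
    reff <- r
    if (!is.null(noise)) reff <- r + noise(ad$s)
    mask <- matrix(ad$dist <= reff, ny, nx)
    t0 <- arcTangent(0, curvature); t1 <- arcTangent(a, curvature)
    tipA <- arcPoint(0, curvature) - r * t0
    tipB <- arcPoint(a, curvature) + r * t1
    chord <- sqrt(sum((tipB - tipA)^2))
    ext_len <- a + 2 * r
    om <- OrganoidMask(mask, psz, contour_sigma_px = contour_sigma_px)
    # grid origin: pixel (1,1) centre sits at (x0, y0); record the offset
    truth <- list(
      length_um = ext_len,
      straightness = chord / ext_len,
      chord_um = chord,
      centerline_length_um = a, cap_radius_um = r,
      curvature = curvature, pixel_size_um = psz,
      rotation_deg = rotation_deg, boundary_noise_px = boundary_noise_px,
      origin_um = c(x0, y0), seed = as.integer(seed)
    )
    list(mask = om, truth = truth)
  })
}

#' @noRd
#' Logistic axial profile evaluated at relative positions x in [0, 1].
axialProfileFun <- function(profile_spec, baseline = 0.05) {
  force(profile_spec); force(baseline)
  function(x) {
    v <- rep(baseline, length(x))
    for (comp in profile_spec) {
      amp <- if (is.null(comp$amplitude)) 1 else comp$amplitude
      stp <- if (is.null(comp$steepness)) 20 else comp$steepness
      s <- if (identical(comp$direction, "falling")) -1 else 1
      v <- v + amp / (1 + exp(-s * stp * (x - comp$midpoint)))
    }
    v
  }
}

#' Synthetic marker image with a known axial expression profile
#'
#' Paints each foreground pixel with the value of a specified axial
#' profile (a sum of logistic components) evaluated at the pixel's
#' relative position along the medial axis, times multiplicative
#' Gaussian noise. Ground truth records the component midpoints (the
#' true boundary positions) and the implied pole count.
#'
#' @param mask an [OrganoidMask-class].
#' @param path the matching [MedialAxisPath-class]; the axial
#'   coordinate of a pixel is the arc-length parameter of its nearest
#'   point on this path, divided by L.
#' @param profile_spec list of components, each a list with `midpoint`
#'   (in (0, 1)), `steepness` (logistic rate, default 20), `amplitude`
#'   (default 1) and `direction` (`"rising"` or `"falling"`). An empty
#'   list paints the flat baseline (no pole).
#' @param noise_sd multiplicative Gaussian noise sd (default 0.1).
#' @param baseline additive offset (default 0.05).
#' @param seed integer seed.
#' @return list with `image` (matrix) and `truth` (boundaries,
#'   directions, pole count, parameters).
#' @export
makeMarkerImage <- function(mask, path, profile_spec, noise_sd = 0.1,
                            baseline = 0.05, seed = 1L) {
  stopifnot(is(mask, "OrganoidMask"), is(path, "MedialAxisPath"))
  for (comp in profile_spec)
    if (comp$midpoint <= 0 || comp$midpoint >= 1)
      stop("profile midpoints must lie in (0, 1)")
  withr::with_seed(as.integer(seed), {
    psz <- mask@pixel_size_um
    pc <- pixelCenters(mask@pixels, psz)
    ref <- resamplePolyline(path@points, 201L)
    pr <- nearestOnPolyline(ref, pc)
    xrel <- pr$s / path@length_um
    f <- axialProfileFun(profile_spec, baseline)
    vals <- f(xrel)
    if (noise_sd > 0)
      vals <- vals * (1 + stats::rnorm(length(vals), 0, noise_sd))
    vals <- pmax(vals, 0)
    img <- matrix(0, nrow(mask@pixels), ncol(mask@pixels))
    img[mask@pixels] <- vals
    truth <- list(
      boundaries = vapply(profile_spec, `[[`, numeric(1), "midpoint"),
      directions = vapply(profile_spec, function(cmp)
        if (identical(cmp$direction, "falling")) "falling" else "rising",
        character(1)),
      pole_count = length(profile_spec),
      noise_sd = noise_sd, baseline = baseline, seed = as.integer(seed)
    )
    list(image = img, truth = truth)
  })
}

#' Synthetic nuclei plane with a known spot count
#'
#' Sum of isotropic Gaussian spots at uniformly sampled in-mask
#' positions (rejection sampling with a minimum mutual separation and a
#' margin from the mask edge), over a noisy background. Emulates a
#' mitosis-marker plane for the counting pipeline.
#'
#' @param mask an [OrganoidMask-class].
#' @param n_spots number of nuclei.
#' @param spot_sigma_px Gaussian spot width (pixels, default 3).
#' @param min_separation_px minimum centre separation (default 20).
#' @param amplitude peak intensity per spot (default 100).
#' @param background,background_noise_sd background level and Gaussian
#'   noise sd (defaults 10 and 2).
#' @param edge_margin_px minimum distance of centres from the mask
#'   edge (default `2 * spot_sigma_px + 3`).
#' @param centers_px optional explicit n x 2 matrix of (row, col) spot
#'   centres, overriding the sampling (for constructed scenes).
#' @param seed integer seed.
#' @return list with `image` (matrix) and `truth` (count, centres).
#' @export
makeNucleiPlane <- function(mask, n_spots, spot_sigma_px = 3,
                            min_separation_px = 20, amplitude = 100,
                            background = 10, background_noise_sd = 2,
                            edge_margin_px = NULL, centers_px = NULL,
                            seed = 1L) {
  stopifnot(is(mask, "OrganoidMask"))
  if (is.null(edge_margin_px)) edge_margin_px <- 2 * spot_sigma_px + 3
  withr::with_seed(as.integer(seed), {
    mpx <- mask@pixels
    if (is.null(centers_px)) {
      dm <- EBImage::distmap(mpx * 1)
      cand <- which(dm >= edge_margin_px, arr.ind = TRUE)
      if (nrow(cand) == 0L && n_spots > 0L)
        stop("no room for spots at the requested edge margin")
      centers <- matrix(0, 0, 2)
      tries <- 0L
      while (nrow(centers) < n_spots) {
        tries <- tries + 1L
        if (tries > 500L * max(n_spots, 1L))
          stop("spot placement failed: separation constraint too tight")
        p <- cand[sample.int(nrow(cand), 1L), ]
        if (nrow(centers) == 0L ||
            min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                               byrow = TRUE))^2))) >=
            min_separation_px)
          centers <- rbind(centers, p)
      }
    } else {
      centers <- centers_px
    }
    img <- matrix(background, nrow(mpx), ncol(mpx))
    if (background_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(mpx), 0, background_noise_sd),
                          nrow(mpx))
    w <- ceiling(4 * spot_sigma_px)
    if (nrow(centers) > 0) for (i in seq_len(nrow(centers))) {
      r0 <- max(1L, centers[i, 1] - w); r1 <- min(nrow(img), centers[i, 1] + w)
      c0 <- max(1L, centers[i, 2] - w); c1 <- min(ncol(img), centers[i, 2] + w)
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
      img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * spot_sigma_px^2))
    }
    img <- pmax(img, 0)
    list(image = img,
         truth = list(n_spots = nrow(centers), centers_px = centers,
                      spot_sigma_px = spot_sigma_px, seed = as.integer(seed)))
  })
}

#' Synthetic 3-D cell tracks with known motility parameters
#'
#' Generates Brownian, ballistic or confined (Ornstein-Uhlenbeck)
#' trajectories in 3-D with uniform sampling, optional localization
#' noise, and ground-truth parameters. All tracks start at the origin,
#' matching trajectory plots aligned to (0, 0).
#'
#' @param n_tracks number of tracks.
#' @param model `"brownian"`, `"ballistic"` or `"confined"`.
#' @param D diffusion coefficient (um^2/min) for brownian/confined.
#' @param v speed (um/min) for ballistic.
#' @param confinement_radius stationary RMS radius (um) for confined.
#' @param n_points points per track (>= 3).
#' @param dt_min sampling interval (minutes; light-sheet movies were
#'   acquired every 20 min).
#' @param localization_noise_um isotropic Gaussian localization noise
#'   sd per coordinate (default 0.3 um).
#' @param seed integer seed.
#' @return list with `tracks` (`data.frame`: `track_id`, `t`, `x`, `y`,
#'   `z`) and `truth` (all parameters).
#' @export
makeTracks <- function(n_tracks, model = c("brownian", "ballistic", "confined"),
                       D = 0.01, v = 0.05, confinement_radius = 5,
                       n_points = 25L, dt_min = 20,
                       localization_noise_um = 0.3, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_points >= 3L, D >= 0, v >= 0, dt_min > 0)
  withr::with_seed(as.integer(seed), {
    tt <- (seq_len(n_points) - 1) * dt_min
    rows <- lapply(seq_len(n_tracks), function(i) {
      pos <- switch(model,
        brownian = {
          steps <- matrix(stats::rnorm(3L * (n_points - 1L), 0,
                                       sqrt(2 * D * dt_min)), ncol = 3)
          rbind(c(0, 0, 0), apply(steps, 2, cumsum))
        },
        ballistic = {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          outer(tt, u) * v
        },
        confined = {
          theta <- 3 * D / confinement_radius^2
          decay <- exp(-theta * dt_min)
          sd_step <- sqrt(D / theta * (1 - decay^2))
          p <- matrix(0, n_points, 3)
          for (k in 2:n_points)
            p[k, ] <- p[k - 1, ] * decay + stats::rnorm(3, 0, sd_step)
          p
        })
      if (localization_noise_um > 0)
        pos <- pos + matrix(stats::rnorm(3L * n_points, 0,
                                         localization_noise_um), ncol = 3)
      data.frame(track_id = sprintf("tr%03d", i), t = tt,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
    })
    list(tracks = do.call(rbind, rows),
         truth = list(model = model, D = D, v = v,
                      confinement_radius = confinement_radius,
                      n_points = n_points, dt_min = dt_min,
                      localization_noise_um = localization_noise_um,
                      seed = as.integer(seed)))
  })
}

#' Synthetic growing, drifting mask time series
#'
#' Disk masks whose effective radius grows linearly at
#' `radial_growth_um_per_min` and whose centroid drifts by
#' `drift_um_per_frame` per frame, with optional smooth angular
#' boundary jitter, re-rasterized per frame. Ground truth carries the
#' growth rate and drift.
#'
#' @param r0_um initial radius (um).
#' @param radial_growth_um_per_min linear growth rate of the effective
#'   radius (um/min).
#' @param drift_um_per_frame numeric length-2 centroid drift per frame.
#' @param n_frames number of frames (>= 3).
#' @param frame_interval_min minutes per frame (default 30, as in the
#'   wide-field time lapses).
#' @param pixel_size_um micrometres per pixel.
#' @param boundary_noise_px amplitude (pixels) of smooth angular
#'   boundary jitter, redrawn each frame.
#' @param seed integer seed.
#' @return list with `masks` (list of logical matrices), and `truth`.
#' @export
makeTimelapse <- function(r0_um = 50, radial_growth_um_per_min = 0.015,
                          drift_um_per_frame = c(0, 0), n_frames = 25L,
                          frame_interval_min = 30, pixel_size_um = 1,
                          boundary_noise_px = 0, seed = 1L) {
  stopifnot(n_frames >= 3L, r0_um > 0)
  withr::with_seed(as.integer(seed), {
    psz <- pixel_size_um
    tmax <- (n_frames - 1) * frame_interval_min
    rmax <- r0_um + max(0, radial_growth_um_per_min) * tmax
    dx <- drift_um_per_frame[1] * (n_frames - 1)
    dy <- drift_um_per_frame[2] * (n_frames - 1)
    margin <- rmax + boundary_noise_px * psz + 4 * psz
    x0 <- min(0, dx) - margin; x1 <- max(0, dx) + margin
    y0 <- min(0, dy) - margin; y1 <- max(0, dy) + margin
    nx <- ceiling((x1 - x0) / psz) + 1L
    ny <- ceiling((y1 - y0) / psz) + 1L
    if (nx > 4096L || ny > 4096L)
      stop("shape exits the field of view (grid would exceed 4096 px)")
    gx <- x0 + (seq_len(nx) - 1) * psz
    gy <- y0 + (seq_len(ny) - 1) * psz
    X <- matrix(rep(gx, each = ny), ny, nx)
    Y <- matrix(rep(gy, nx), ny, nx)
    masks <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      ti <- (f - 1) * frame_interval_min
      cxy <- c(drift_um_per_frame[1], drift_um_per_frame[2]) * (f - 1)
      rf <- r0_um + radial_growth_um_per_min * ti
      dxp <- X - cxy[1]; dyp <- Y - cxy[2]
      rr <- sqrt(dxp^2 + dyp^2)
      redge <- rf
      if (boundary_noise_px > 0) {
        cf <- stats::rnorm(6); ph <- stats::runif(6, 0, 2 * pi)
        ang <- atan2(dyp, dxp)
        pert <- Reduce(`+`, lapply(1:6, function(j)
          cf[j] * cos(j * ang + ph[j])))
        pert <- pert / max(abs(pert)) * boundary_noise_px * psz
        redge <- rf + pert
      }
      if (rf + boundary_noise_px * psz > margin - psz)
        stop("shape exits the field of view")
      masks[[f]] <- rr <= redge
    }
    list(masks = masks,
         truth = list(r0_um = r0_um,
                      radial_growth_um_per_min = radial_growth_um_per_min,
                      drift_um_per_frame = drift_um_per_frame,
                      n_frames = n_frames,
                      frame_interval_min = frame_interval_min,
                      pixel_size_um = psz,
                      boundary_noise_px = boundary_noise_px,
                      seed = as.integer(seed)))
  })
}
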