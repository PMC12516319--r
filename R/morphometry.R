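#' Medial axis of an organoid, tangent-extended to the contour
#'
#' Computes the organoid body axis: the mask is skeletonized
#' (Zhang-Suen thinning), the skeleton graph is pruned to its longest
#' Euclidean-weighted geodesic between endpoints, the resulting
#' polyline is smoothed with a centred moving average, and each end is
#' extended with a straight ray along the local tangent until it
#' crosses the sub-pixel mask contour. The arc length of the extended
#' polyline is the organoid length L.
#'
#' Degenerate skeletons (near-round masks collapse to a point or a few
#' pixels) fall back to the principal-axis direction of the foreground,
#' so that a disk still reports L close to its diameter.
#'
#' @param x an [OrganoidMask-class].
#' @param smooth_window moving-average window (path points, default 5).
#' @param tangent_k number of terminal path points used for the end
#'   tangent (default 40, capped at a third of the path; a local
#'   quadratic fit over this window is insensitive to the pixel-scale
#'   zigzag that corrupts short windows).
#' @param ... unused.
#' @return a [MedialAxisPath-class].
#' @examples
#' m <- makeOrganoidMask(centerline_length_um = 120, cap_radius_um = 30,
#'                       curvature = 0, pixel_size_um = 1, seed = 1)
#' medialAxis(m$mask)   # L close to 120 + 2 * 30 um
#' @export
setMethod("medialAxis", "OrganoidMask",
          function(x, smooth_window = 5L, tangent_k = 40L, ...) {
  psz <- x@pixel_size_um
  path_px <- skeletonPath(x@pixels)
  pts <- cbind(x = (path_px[, 2] - 1) * psz, y = (path_px[, 1] - 1) * psz)
  degenerate <- nrow(pts) < max(3L, tangent_k %/% 2L) ||
    max(dist(pts[c(1L, nrow(pts)), , drop = FALSE])) < 2 * psz
  if (degenerate) {
    # fall back to a short segment through the centroid along the
    # principal axis of the foreground
    ctr <- centroidUm(x)
    pc <- pixelCenters(x@pixels, psz)
    ev <- eigen(stats::cov(pc), symmetric = TRUE)$vectors[, 1]
    pts <- rbind(ctr - ev * psz, ctr + ev * psz)
  } else {
    dm <- EBImage::distmap(x@pixels * 1)
    pts <- smoothPolyline(pts, smooth_window)
    # Re-centre onto the distance-transform ridge: thinned skeletons
    # carry a lateral staircase bias of up to a few pixels on curved
    # shapes. The dm field is tent-shaped across the axis, so the
    # lateral offset of the ridge is (dm(p + w n) - dm(p - w n)) / 2.
    w <- 2 * psz
    for (it in 1:3) {
      nn <- nrow(pts)
      tang <- rbind(pts[2, ] - pts[1, ],
                    pts[3:nn, , drop = FALSE] - pts[1:(nn - 2), , drop = FALSE],
                    pts[nn, ] - pts[nn - 1, ])
      tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
      nrmv <- cbind(-tang[, 2] / tl, tang[, 1] / tl)
      dmp <- bilinearAt(dm, (pts[, 2] + w * nrmv[, 2]) / psz + 1,
                            (pts[, 1] + w * nrmv[, 1]) / psz + 1)
      dmm2 <- bilinearAt(dm, (pts[, 2] - w * nrmv[, 2]) / psz + 1,
                             (pts[, 1] - w * nrmv[, 1]) / psz + 1)
      v <- pmin(1.5 * psz, pmax(-1.5 * psz, (dmp - dmm2) * psz / 2))
      pts <- pts + v * nrmv
      pts <- smoothPolyline(pts, smooth_window)
    }
    # Prune terminal spurs after re-centring: thinning grows short
    # branches into rounded ends, and such branches run below the
    # local-width plateau of the distance map (they descend from the
    # axis ridge toward the boundary) while re-centred axis points sit
    # on it. A spur cannot outrun its terminal inscribed disk, so the
    # trimmed arc is capped at 1.2 of the plateau radius.
    dmv <- bilinearAt(dm, pts[, 2] / psz + 1, pts[, 1] / psz + 1) * psz
    n0 <- nrow(pts)
    half <- max(2L, floor(n0 / 2))
    spurEnd <- function(ord) {
      dmo <- dmv[ord]
      so <- cumArc(pts[ord, , drop = FALSE])
      plateau <- max(dmo[seq_len(half)])
      slack <- max(1.5 * psz, 0.05 * plateau)
      k <- 1L
      while (k < half && dmo[k] < plateau - slack &&
             so[k] <= 1.2 * plateau) k <- k + 1L
      k
    }
    kA <- spurEnd(seq_len(n0))
    kB <- spurEnd(rev(seq_len(n0)))
    keep <- seq.int(kA, n0 - kB + 1L)
    if (length(keep) >= max(3L, tangent_k %/% 2L)) {
      pts <- pts[keep, , drop = FALSE]
      if (kA > 1L || kB > 1L) pts <- smoothPolyline(pts, smooth_window)
    }
  }
  n <- nrow(pts)
  tangentOut <- function(end) {
    k <- min(max(tangent_k, 5L), max(n %/% 3L, 5L), n)
    seg <- if (end == 1L) pts[seq_len(k), , drop = FALSE]
           else pts[seq(n - k + 1L, n), , drop = FALSE]
    if (end == 2L) seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    if (nrow(unique(seg)) < 2L) stop("degenerate geometry at path end")
    secant <- seg[1L, ] - seg[nrow(seg), ]
    secant <- secant / sqrt(sum(secant^2))
    dirv <- if (nrow(seg) >= 5L) {
      # local quadratic in the secant frame: project onto (secant,
      # normal) axes, fit normal offset against the secant coordinate,
      # and take the analytic tangent at the end point. This removes
      # the curvature bias of a straight-line fit while staying
      # well-conditioned on the pixel-scale zigzag of thinned paths.
      nrm <- c(-secant[2L], secant[1L])
      rel <- sweep(seg, 2L, seg[1L, ])
      u <- -(rel %*% secant)        # distance travelled inward
      v <- rel %*% nrm
      cf <- stats::lm.fit(cbind(1, u, u^2), v)$coefficients
      slope <- cf[2L]               # dv/du at the end (u = 0)
      -(-secant) - slope * nrm      # tangent pointing outward
    } else {
      secant
    }
    nv <- sqrt(sum(dirv^2))
    if (nv == 0) stop("degenerate geometry at path end")
    dirv / nv
  }
  extend <- function(origin, dirv) {
    hit <- rayPolygonIntersect(origin, dirv, x@contour)
    if (is.null(hit))
      stop("extension ray fails to intersect the contour (degenerate geometry)")
    hit
  }
  tipA <- extend(pts[1, ], tangentOut(1L))
  tipB <- extend(pts[n, ], tangentOut(2L))
  full <- rbind(tipA, pts, tipB)
  rownames(full) <- NULL
  new("MedialAxisPath",
      points = full,
      length_um = polylineLength(full),
      chord_um = sqrt(sum((tipB - tipA)^2)),
      endpoints = rbind(tipA, tipB))
})

#' Straightness ratio of a body axis
#'
#' Ratio of the chord (distance between the axis extremities) to the
#' arc length of the axis: 1 for a perfectly straight organoid, smaller
#' for bent ones. The inverse orientation (arc over chord, >= 1) is
#' available for comparison with conventions that quote gastruloid
#' length over extremity distance.
#'
#' @param x a [MedialAxisPath-class].
#' @param orientation `"chord-over-arc"` (default, in (0, 1]) or
#'   `"arc-over-chord"`.
#' @param ... unused.
#' @return numeric scalar.
#' @export
setMethod("straightness", "MedialAxisPath",
          function(x, orientation = c("chord-over-arc", "arc-over-chord"), ...) {
  orientation <- match.arg(orientation)
  if (x@length_um <= 0) stop("zero-length path")
  s <- x@chord_um / x@length_um
  if (orientation == "arc-over-chord") 1 / s else s
})

#' @rdname straightness
#' @description The matrix method treats its argument as a raw polyline
#'   (n x 2, um) without tangent extension -- useful for analytic paths.
#' @export
setMethod("straightness", "matrix", function(x, ...) {
  L <- polylineLength(x)
  if (L <= 0) stop("zero-length path")
  sqrt(sum((x[nrow(x), ] - x[1, ])^2)) / L
})

#' Elongation index of a mask
#'
#' `EI = 1 - 4 * pi * A / P^2`, the complement of circularity, computed
#' from the area and perimeter of the sub-pixel contour polygon: 0 for
#' a disk, increasing as the shape departs from circularity, invariant
#' to rotation and uniform scaling.
#'
#' @param x an [OrganoidMask-class].
#' @return numeric scalar >= 0 (up to discretisation tolerance).
#' @export
setMethod("elongationIndex", "OrganoidMask", function(x) {
  A <- polygonArea(x@contour)
  P <- polylineLength(x@contour)
  if (P <= 0) stop("zero perimeter")
  1 - 4 * pi * A / P^2
})

#' Aspect ratio of a mask
#'
#' Major-to-minor axis ratio of the inertia-equivalent ellipse of the
#' foreground (square root of the second-moment eigenvalue ratio);
#' always >= 1.
#'
#' @param x an [OrganoidMask-class].
#' @return numeric scalar >= 1.
#' @export
setMethod("aspectRatio", "OrganoidMask", function(x) {
  pc <- pixelCenters(x@pixels, x@pixel_size_um)
  cv <- stats::cov(pc)
  # add the second moment of a single square pixel so thin shapes stay
  # non-degenerate
  cv <- cv + diag(x@pixel_size_um^2 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) stop("degenerate (collinear) foreground")
  sqrt(ev[1] / ev[2])
})

#' All shape descriptors of one organoid
#'
#' Convenience wrapper returning the morphometric record used in the
#' output tables: medial-axis length L, straightness S, elongation
#' index EI, aspect ratio AR, area and perimeter.
#'
#' @param mask an [OrganoidMask-class].
#' @param organoid_id identifier copied into the record.
#' @param ... passed to [medialAxis()].
#' @return one-row `data.frame`.
#' @export
morphometry <- function(mask, organoid_id = "organoid", ...) {
  ax <- medialAxis(mask, ...)
  data.frame(
    organoid_id = organoid_id,
    length_um = ax@length_um,
    straightness = straightness(ax),
    elongation_index = elongationIndex(mask),
    aspect_ratio = aspectRatio(mask),
    area_um2 = areaUm2(mask),
    perimeter_um = perimeterUm(mask)
  )
}

#' Centroid trajectory and radial growth of a mask time series
#'
#' Per-frame centroid and effective radius `r(t) = sqrt(A(t) / pi)` of
#' a time-lapse mask series; the radial growth rate is the ordinary
#' least-squares slope of r against t, and the centroid track gives the
#' total (cumulative) displacement.
#'
#' @param masks list of logical matrices (or [OrganoidMask-class]
#'   objects), one per frame, constant calibration.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_min minutes per frame.
#' @return list with `centroid_track` (`data.frame` t/x/y),
#'   `total_displacement_um`, `effective_radius_series` (`data.frame`
#'   t/r_um) and `radial_growth_rate_um_per_min`.
#' @export
timelapseMotion <- function(masks, pixel_size_um, frame_interval_min) {
  if (length(masks) < 3L) stop("need at least 3 frames for the growth slope")
  getpx <- function(m) if (is(m, "OrganoidMask")) m@pixels else (m != 0)
  tt <- (seq_along(masks) - 1) * frame_interval_min
  cent <- t(vapply(masks, function(m) {
    p <- pixelCenters(getpx(m), pixel_size_um)
    c(mean(p[, 1]), mean(p[, 2]))
  }, numeric(2)))
  r <- vapply(masks, function(m)
    sqrt(sum(getpx(m)) * pixel_size_um^2 / pi), numeric(1))
  steps <- sqrt(rowSums(diff(cent)^2))
  fit <- stats::lm.fit(cbind(1, tt), r)
  list(
    centroid_track = data.frame(t = tt, x = cent[, 1], y = cent[, 2]),
    total_displacement_um = sum(steps),
    effective_radius_series = data.frame(t = tt, r_um = r),
    radial_growth_rate_um_per_min = unname(fit$coefficients[2])
  )
}
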