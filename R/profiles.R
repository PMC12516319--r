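#' Cut the organoid contour at the axis endpoints into two sides
#'
#' The sub-pixel mask contour is cut at the two points where the
#' tangent-extended medial axis meets it, producing two open arcs; each
#' arc is resampled to 101 arc-length-equidistant points and oriented
#' from axis end A to end B. Side A is the arc lying to the left of the
#' A-to-B chord.
#'
#' @param mask an [OrganoidMask-class].
#' @param path the matching [MedialAxisPath-class].
#' @param tol_px maximum allowed distance (pixels) between an axis
#'   endpoint and the contour (default 0.5).
#' @return list with `side_A` and `side_B`, each a 101 x 2 matrix (um).
#' @export
splitContour <- function(mask, path, tol_px = 0.5) {
  stopifnot(is(mask, "OrganoidMask"), is(path, "MedialAxisPath"))
  ct <- mask@contour
  psz <- mask@pixel_size_um
  tips <- path@endpoints
  if (sqrt(sum((tips[1, ] - tips[2, ])^2)) < 1e-9)
    stop("axis endpoints coincide")
  loc <- locateOnPolygon(ct, tips)
  if (any(loc$dist > tol_px * psz))
    stop("axis endpoint lies off the contour by more than ", tol_px, " px")
  arcs <- cutPolygon(ct, loc, tips)
  chord <- tips[2, ] - tips[1, ]
  sideOf <- function(arc) {
    mid <- arc[ceiling(nrow(arc) / 2), ]
    v <- mid - tips[1, ]
    sign(chord[1] * v[2] - chord[2] * v[1])
  }
  s1 <- sideOf(arcs[[1]])
  if (s1 > 0) {
    sideA <- arcs[[1]]; sideB <- arcs[[2]]
  } else {
    sideA <- arcs[[2]]; sideB <- arcs[[1]]
  }
  list(side_A = resamplePolyline(sideA, 101L),
       side_B = resamplePolyline(sideB, 101L))
}

#' @noRd
#' Locate query points on a closed polygon: nearest segment index,
#' along-segment fraction, and distance.
locateOnPolygon <- function(poly, q) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  seg <- integer(nrow(q)); u <- numeric(nrow(q)); d <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    wx <- q[i, 1] - a[, 1]; wy <- q[i, 2] - a[, 2]
    uu <- pmin(1, pmax(0, (wx * ex + wy * ey) / len2))
    dx <- wx - uu * ex; dy <- wy - uu * ey
    d2 <- dx^2 + dy^2
    k <- which.min(d2)
    seg[i] <- k; u[i] <- uu[k]; d[i] <- sqrt(d2[k])
  }
  list(segment = seg, frac = u, dist = d)
}

#' @noRd
#' Split a closed polygon at two located points into the two open arcs
#' joining them; both arcs run from tips[1, ] to tips[2, ].
cutPolygon <- function(poly, loc, tips) {
  nseg <- nrow(poly) - 1L
  key <- loc$segment + loc$frac
  firstIsA <- key[1] <= key[2]
  o <- if (firstIsA) c(1L, 2L) else c(2L, 1L)
  kA <- loc$segment[o[1]]; kB <- loc$segment[o[2]]
  pA <- tips[o[1], ]; pB <- tips[o[2], ]
  mids1 <- if (kA < kB) (kA + 1L):kB else integer(0)
  arc1 <- rbind(pA, poly[mids1, , drop = FALSE], pB)
  mids2 <- c(if (kB < nseg) (kB + 1L):nseg else integer(0),
             if (kA >= 1L) 1L:kA else integer(0))
  arc2raw <- rbind(pB, poly[mids2, , drop = FALSE], pA)
  arc2 <- arc2raw[rev(seq_len(nrow(arc2raw))), , drop = FALSE]
  if (!firstIsA) {
    arc1 <- arc1[rev(seq_len(nrow(arc1))), , drop = FALSE]
    arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]
  }
  lapply(list(arc1, arc2), function(a) a[!duplicated(a), , drop = FALSE])
}

#' Build the 100 anteroposterior sections from the two contour sides
#'
#' Section i is the quadrilateral `(A_i, A_{i+1}, B_{i+1}, B_i)`.
#' Foreground pixels are assigned to the section containing their
#' centre; pixels falling in no section (discretisation slivers) go to
#' the section with the nearest centroid. Sections whose bounding
#' cross-lines intersect (pathological non-convex geometry) are
#' flagged. Relative axial positions are the arc-length coordinates of
#' the section centroids projected onto the medial axis, divided by L.
#'
#' @param sides list with `side_A`, `side_B` from [splitContour()].
#' @param mask the [OrganoidMask-class].
#' @param path the [MedialAxisPath-class].
#' @return a [ContourBinning-class].
#' @export
makeBins <- function(sides, mask, path) {
  A <- sides$side_A; B <- sides$side_B
  stopifnot(nrow(A) == 101L, nrow(B) == 101L)
  psz <- mask@pixel_size_um
  bins <- vector("list", 100L)
  flags <- character(100L)
  areas <- numeric(100L)
  cents <- matrix(0, 100L, 2L)
  for (i in 1:100) {
    quad <- rbind(A[i, ], A[i + 1L, ], B[i + 1L, ], B[i, ])
    quad <- quad[!duplicated(quad), , drop = FALSE]
    poly <- rbind(quad, quad[1, ])
    bins[[i]] <- poly
    areas[i] <- polygonArea(poly)
    cents[i, ] <- polygonCentroid(poly)
    if (segmentsIntersect(A[i, ], B[i, ], A[i + 1L, ], B[i + 1L, ]))
      flags[i] <- "crossing section lines"
  }
  idx <- which(mask@pixels, arr.ind = TRUE)
  pts <- cbind((idx[, 2] - 1) * psz, (idx[, 1] - 1) * psz)
  # membership of every pixel in every candidate bin; pixels claimed by
  # several bins (centres exactly on a shared edge) or by none
  # (discretisation slivers) go to the nearest section centroid, so the
  # assignment is independent of bin order and symmetric under
  # reversing the sides
  assign_vec <- rep(NA_integer_, nrow(pts))
  nhits <- integer(nrow(pts))
  for (i in 1:100) {
    poly <- bins[[i]]
    bb <- apply(poly, 2, range)
    cand <- which(pts[, 1] >= bb[1, 1] - 1e-9 & pts[, 1] <= bb[2, 1] + 1e-9 &
                  pts[, 2] >= bb[1, 2] - 1e-9 & pts[, 2] <= bb[2, 2] + 1e-9)
    if (!length(cand)) next
    inside <- mgcv::in.out(poly, pts[cand, , drop = FALSE])
    hit <- cand[inside]
    assign_vec[hit] <- i
    nhits[hit] <- nhits[hit] + 1L
  }
  todo <- which(nhits != 1L)
  if (length(todo)) {
    d <- outer(pts[todo, 1], cents[, 1], "-")^2 +
         outer(pts[todo, 2], cents[, 2], "-")^2
    assign_vec[todo] <- max.col(-d, ties.method = "first")
  }
  assignment <- matrix(NA_integer_, nrow(mask@pixels), ncol(mask@pixels))
  assignment[idx] <- assign_vec
  proj <- nearestOnPolyline(path@points, cents)
  pos <- proj$s / path@length_um
  pos <- pmin(pmax(pos, 1e-9), 1 - 1e-9)   # blunt end bins can project
  if (any(diff(pos) <= 0)) {               # onto the clamped axis tips
    # enforce monotone positions on pathological geometries and flag
    bad <- which(diff(pos) <= 0)
    flags[bad + 1L] <- paste(flags[bad + 1L], "non-monotone position")
    pos <- cummax(pos) + seq_along(pos) * 1e-12
  }
  new("ContourBinning", side_A = A, side_B = B, bins = bins,
      bin_areas_um2 = areas, positions = pos, assignment = assignment,
      pixel_size_um = psz, flags = flags)
}

#' Extract a 100-bin intensity profile along the anteroposterior axis
#'
#' Mean image intensity over the pixels of each of the 100 sections,
#' on the relative axial position grid of the binning. Empty sections
#' (possible at sub-pixel-thin tips) are imputed as the mean of their
#' nearest non-empty neighbours and flagged.
#'
#' @param image numeric matrix, same geometry as the mask the binning
#'   was built from.
#' @param binning a [ContourBinning-class].
#' @param organoid_id,channel,experiment identifiers stored with the
#'   profile.
#' @return one-column [APProfileSet-class].
#' @export
extractProfile <- function(image, binning, organoid_id = "organoid",
                           channel = "marker", experiment = "exp1") {
  stopifnot(is(binning, "ContourBinning"))
  if (!all(dim(image) == dim(binning@assignment)))
    stop("image and binning geometry differ")
  vals <- image[!is.na(binning@assignment)]
  grp <- binning@assignment[!is.na(binning@assignment)]
  raw <- rep(NA_real_, 100L)
  agg <- tapply(vals, grp, mean)
  raw[as.integer(names(agg))] <- agg
  flagged <- which(is.na(raw))
  if (length(flagged)) {
    filled <- which(!is.na(raw))
    for (i in flagged) {
      lo <- filled[filled < i]; hi <- filled[filled > i]
      nb <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
      raw[i] <- mean(raw[nb])
    }
  }
  profileSet(raw = matrix(raw, ncol = 1),
             positions = matrix(binning@positions, ncol = 1),
             organoid_id = organoid_id, channel = channel,
             experiment = experiment,
             imputed_bins = list(flagged))
}

#' Assemble profiles into an APProfileSet
#'
#' @param raw 100 x n matrix of bin means (a.u.), one column per organoid.
#' @param positions 100 x n matrix of relative axial bin positions.
#' @param organoid_id,channel,experiment per-column metadata (recycled).
#' @param imputed_bins optional list (per column) of imputed bin indices.
#' @return an [APProfileSet-class].
#' @export
profileSet <- function(raw, positions, organoid_id, channel = "marker",
                       experiment = "exp1", imputed_bins = NULL) {
  raw <- as.matrix(raw); positions <- as.matrix(positions)
  n <- ncol(raw)
  cd <- S4Vectors::DataFrame(
    organoid_id = rep_len(organoid_id, n),
    channel = rep_len(channel, n),
    experiment = rep_len(experiment, n)
  )
  if (!is.null(imputed_bins)) cd$imputed_bins <- I(rep_len(imputed_bins, n))
  colnames(raw) <- cd$organoid_id
  colnames(positions) <- cd$organoid_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw, position = positions),
    rowData = S4Vectors::DataFrame(bin = seq_len(nrow(raw)),
                                   position_mid = (seq_len(nrow(raw)) - 0.5) / nrow(raw)),
    colData = cd
  )
  new("APProfileSet", se)
}

#' Combine profile sets column-wise
#' @param ... [APProfileSet-class] objects with equal bin counts.
#' @return an [APProfileSet-class].
#' @export
bindProfiles <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "APProfileSet"))
    sets <- sets[[1]]
  out <- do.call(SummarizedExperiment::cbind, sets)
  new("APProfileSet", out)
}

#' Per-experiment cohort normalization of intensity profiles
#'
#' For every experiment group (and channel), the cohort-average profile
#' is computed bin-wise over all organoids; the normalization anchors
#' are the means of its lowest and highest decile of bins (the 10
#' lowest and 10 highest of the 100 bins). Each profile is then
#' rescaled as `(raw - low) / (high - low)`, which removes affine
#' intensity differences between fixation protocols while preserving
#' profile shape. Anchors are recorded in `metadata(x)$anchors`.
#'
#' The arithmetic is arranged so that an affine transform of a cohort
#' (`I -> a*I + b`, with exactly representable inputs) produces
#' bit-identical normalized output: the anchor sums are kept unscaled
#' and the single division happens last.
#'
#' @param x an [APProfileSet-class] (assay `"raw"`).
#' @param by column-data variable(s) defining the cohort (default
#'   `c("experiment", "channel")`).
#' @param decile fraction of bins averaged into each anchor (default 0.1).
#' @return the input with an added `"normalized"` assay and anchors in
#'   the metadata.
#' @export
normalizeCohort <- function(x, by = c("experiment", "channel"),
                            decile = 0.1) {
  stopifnot(is(x, "APProfileSet"))
  raw <- SummarizedExperiment::assay(x, "raw")
  cd <- SummarizedExperiment::colData(x)
  key <- do.call(paste, c(lapply(by, function(b) cd[[b]]), sep = "\r"))
  norm <- raw
  anchors <- NULL
  nb <- nrow(raw)
  k <- max(1L, floor(decile * nb))
  for (g in unique(key)) {
    cols <- which(key == g)
    if (length(cols) < 2L)
      stop("cohort '", gsub("\r", "/", g), "' has fewer than 2 profiles")
    m <- length(cols)
    tot <- rowSums(raw[, cols, drop = FALSE])   # m * average profile
    ord <- order(tot)
    Slo <- sum(tot[ord[seq_len(k)]])
    Shi <- sum(tot[ord[seq(nb - k + 1L, nb)]])
    if (!(Shi > Slo) || (Shi - Slo) < 1e-12 * max(abs(Shi), 1))
      stop("flat cohort: normalization anchors coincide")
    # (raw - Slo/(m k)) / ((Shi - Slo)/(m k)) with one final division
    norm[, cols] <- (m * k * raw[, cols, drop = FALSE] - Slo) / (Shi - Slo)
    anchors <- rbind(anchors, data.frame(
      group = gsub("\r", "/", g),
      low = Slo / (m * k), high = Shi / (m * k), n = m
    ))
  }
  SummarizedExperiment::assay(x, "normalized") <- norm
  S4Vectors::metadata(x)$anchors <- anchors
  x
}

#' Half-maximum boundary position of a marker profile
#'
#' Within a search window of relative axial positions, finds where the
#' profile crosses the half-maximum of its in-window values -- i.e.
#' `(min + max) / 2` -- in the requested direction, with linear
#' interpolation between bins. When several crossings exist, the one
#' nearest the window's steepest gradient is returned.
#'
#' @param x numeric profile values (typically normalized), or an
#'   [APProfileSet-class].
#' @param positions relative axial positions matching `x` (numeric method).
#' @param direction `"rising"` (posterior markers such as BRA; default
#'   window `[0.5, 1]`) or `"falling"` (anterior markers such as FOXC1;
#'   default window `[0, 0.5]`).
#' @param window numeric length-2 search window in `[0, 1]`; `NULL`
#'   picks the direction default.
#' @param ... unused.
#' @return numeric boundary position in `[0, 1]` (numeric method), or a
#'   `data.frame` with one row per profile (set method).
#' @export
setMethod("boundaryPosition", "numeric",
          function(x, positions, direction = c("rising", "falling"),
                   window = NULL, ...) {
  direction <- match.arg(direction)
  if (is.null(window))
    window <- if (direction == "rising") c(0.5, 1) else c(0, 0.5)
  sel <- which(positions >= window[1] & positions <= window[2])
  if (length(sel) < 3L) stop("search window contains fewer than 3 bins")
  v <- x[sel]; p <- positions[sel]
  half <- (min(v) + max(v)) / 2
  n <- length(v)
  cross <- numeric(0)
  for (i in seq_len(n - 1L)) {
    up <- v[i] < half && v[i + 1L] >= half
    down <- v[i] >= half && v[i + 1L] < half
    if ((direction == "rising" && up) || (direction == "falling" && down)) {
      f <- (half - v[i]) / (v[i + 1L] - v[i])
      cross <- c(cross, p[i] + f * (p[i + 1L] - p[i]))
    }
  }
  if (!length(cross)) stop("no ", direction, " half-maximum crossing in window")
  dv <- diff(v)
  steep <- if (direction == "rising") which.max(dv) else which.min(dv)
  steep_pos <- (p[steep] + p[steep + 1L]) / 2
  xb <- cross[which.min(abs(cross - steep_pos))]
  min(1, max(0, xb))
})

#' @rdname boundaryPosition
#' @param assay which assay of the profile set to use.
#' @export
setMethod("boundaryPosition", "APProfileSet",
          function(x, direction = c("rising", "falling"), window = NULL,
                   assay = "normalized", ...) {
  direction <- match.arg(direction)
  vals <- SummarizedExperiment::assay(x, assay)
  pos <- SummarizedExperiment::assay(x, "position")
  cd <- SummarizedExperiment::colData(x)
  xb <- vapply(seq_len(ncol(vals)), function(j)
    boundaryPosition(vals[, j], pos[, j], direction = direction,
                     window = window), numeric(1))
  data.frame(organoid_id = cd$organoid_id, channel = cd$channel,
             experiment = cd$experiment, direction = direction, x_b = xb)
})
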