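#' Maximum intensity projection over z
#'
#' Per-pixel maximum over the z planes, separately for every channel
#' and time point. The stack must have been loaded with a z axis.
#'
#' @param stack an [ImageStack-class] whose `axes` include `"z"`.
#' @param t,channel which frame / channel to project (defaults: first).
#' @return a numeric matrix `(y, x)`.
#' @export
maxProjection <- function(stack, t = 1L, channel = 1L) {
  stopifnot(is(stack, "ImageStack"))
  if (!"z" %in% stack@axes) stop("stack has no z axis")
  v <- stack@voxels
  planes <- v[t, , channel, , , drop = FALSE]
  apply(planes, c(4, 5), max)[, ]
}

#' Maximum-entropy (Kapur) threshold of a histogram
#'
#' Returns the level that maximises the sum of the Shannon entropies of
#' the background (bins `1..t`) and foreground (bins `t+1..L`) class
#' distributions -- the MaxEntropy criterion of ImageJ. Ties are broken
#' by the lowest qualifying level.
#'
#' @param counts non-negative histogram counts, one per intensity level;
#'   at least two levels must be occupied.
#' @return the 1-based index `t` of the last background bin.
#' @examples
#' h <- c(rep(0, 9), 50, rep(0, 189), 30, rep(0, 56))
#' kapurThreshold(h)   # strictly between the two occupied levels
#' @export
kapurThreshold <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts > 0) < 2L)
    stop("histogram needs at least 2 nonzero bins")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)            # background mass up to level t
  Slog <- cumsum(plogp)
  total <- sum(plogp)
  L <- length(p)
  t <- seq_len(L - 1L)
  Pb <- P[t]
  Pf <- 1 - Pb
  valid <- Pb > 0 & Pf > 0
  Hb <- ifelse(valid, log(Pb) - Slog[t] / Pb, -Inf)
  Hf <- ifelse(valid, log(Pf) - (total - Slog[t]) / Pf, -Inf)
  crit <- Hb + Hf
  # lowest level within float tolerance of the maximum (documented
  # tie-break; exact ties arise for e.g. symmetric spike histograms)
  which(crit >= max(crit) - 1e-10)[1]
}

#' @describeIn kapurThreshold apply the criterion to raw intensity
#'   values via an equal-width histogram over their range; returns an
#'   intensity cut (upper edge of the last background bin).
#' @param values numeric intensities.
#' @param bins number of histogram bins (ImageJ uses an 8-bit histogram,
#'   i.e. 256).
#' @export
kapurThresholdValues <- function(values, bins = 256L) {
  r <- range(values)
  if (diff(r) <= 0) stop("histogram needs at least 2 nonzero bins")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)$counts
  edges[kapurThreshold(h) + 1L]
}

#' @noRd
#' Otsu threshold, made exactly shift- and scale-covariant by
#' normalising to [0, 1] before calling EBImage::otsu and mapping back.
otsuThresholdValues <- function(values, bins = 256L) {
  r <- range(values)
  if (diff(r) <= 0) stop("image is constant; cannot threshold")
  scaled <- (values - r[1]) / (r[2] - r[1])
  th <- EBImage::otsu(matrix(scaled, nrow = 1L), range = c(0, 1),
                      levels = bins)
  th * (r[2] - r[1]) + r[1]
}

#' Segment a single organoid from a 2-D image
#'
#' Gaussian smoothing, a global threshold (Otsu by default), retention
#' of the largest connected component, unconditional hole filling and
#' optional morphological closing. Intended for fields dominated by one
#' organoid (DAPI maximum projections or brightfield).
#'
#' @param image numeric matrix `(y, x)`.
#' @param pixel_size_um micrometres per pixel.
#' @param smoothing_sigma Gaussian sigma in pixels (default 2).
#' @param method `"otsu"` (default), `"maxentropy"`, or `"fixed"`.
#' @param fixed_value threshold used when `method = "fixed"`.
#' @param closing_radius radius (px) of an optional binary closing; 0
#'   disables it.
#' @param bins histogram bins for the threshold methods.
#' @param contour_sigma_px passed to [OrganoidMask()].
#' @return an [OrganoidMask-class].
#' @export
segmentOrganoid <- function(image, pixel_size_um, smoothing_sigma = 2,
                            method = c("otsu", "maxentropy", "fixed"),
                            fixed_value = NULL, closing_radius = 0,
                            bins = 256L, contour_sigma_px = 2) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  g <- if (smoothing_sigma > 0) EBImage::gblur(image, sigma = smoothing_sigma) else image
  if (diff(range(g)) <= 0)
    stop("empty foreground after threshold (blank image)")
  th <- switch(method,
    otsu = otsuThresholdValues(as.numeric(g), bins),
    maxentropy = kapurThresholdValues(as.numeric(g), bins),
    fixed = {
      if (is.null(fixed_value)) stop("fixed_value required for method 'fixed'")
      fixed_value
    })
  bw <- g > th
  if (!any(bw)) stop("empty foreground after threshold")
  lab <- EBImage::bwlabel(bw * 1)
  keep <- which.max(tabulate(lab[lab > 0]))
  bw <- lab == keep
  border <- c(bw[1, ], bw[nrow(bw), ], bw[, 1], bw[, ncol(bw)])
  if (mean(border) > 0.5)
    stop("foreground touches more than 50% of the image border; likely segmentation failure")
  if (closing_radius > 0) {
    k <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    bw <- EBImage::closing(bw * 1, k) > 0
  }
  OrganoidMask(bw, pixel_size_um, contour_sigma_px = contour_sigma_px)
}

#' Count mitotic nuclei in a single plane
#'
#' Implements the dividing-cell density measurement for an H3S10P (or
#' comparable mitosis marker) plane: Gaussian filter (sigma = 5 px),
#' maximum-entropy threshold of the in-mask intensity histogram,
#' watershed splitting of touching objects seeded at local maxima of the
#' Euclidean distance transform, then a count of objects of at least
#' `min_area_px` pixels. When a DAPI plane is supplied its mean
#' intensity within the mask is reported alongside, as a cell-density
#' proxy.
#'
#' Note the resolution limit set by the filter: two nuclei whose
#' centres are closer than about twice the combined Gaussian width
#' merge into a blob with no waist and cannot be split by any watershed.
#'
#' @param plane numeric matrix, the marker channel.
#' @param mask [OrganoidMask-class] of the organoid slice.
#' @param dapi optional numeric matrix, the DAPI channel.
#' @param sigma Gaussian sigma in pixels (default 5, as in the assay).
#' @param min_area_px minimum object area kept (default 10 px).
#' @param bins histogram bins for the threshold.
#' @param ws_ext neighbourhood radius (px) used when detecting distance
#'   -transform maxima for the watershed (default 5).
#' @param ws_tolerance minimum depth separating two watershed objects.
#' @return one-row `data.frame`: `mean_dapi_intensity`, `mitotic_count`,
#'   `slice_area_um2`, `mitotic_density_per_um2`.
#' @export
countMitotic <- function(plane, mask, dapi = NULL, sigma = 5,
                         min_area_px = 10L, bins = 256L,
                         ws_ext = 5L, ws_tolerance = 1) {
  stopifnot(is(mask, "OrganoidMask"))
  if (!all(dim(plane) == dim(mask@pixels)))
    stop("mask/plane shape mismatch")
  mpx <- mask@pixels
  area_um2 <- areaUm2(mask)
  mean_dapi <- if (is.null(dapi)) NA_real_ else {
    if (!all(dim(dapi) == dim(mpx))) stop("mask/plane shape mismatch")
    mean(dapi[mpx])
  }
  sm <- EBImage::gblur(plane, sigma = sigma)
  vals <- sm[mpx]
  count <- 0L
  if (diff(range(vals)) > 1e-12) {
    th <- kapurThresholdValues(vals, bins)
    bw <- (sm > th) & mpx
    if (any(bw)) {
      dm <- EBImage::distmap(bw * 1)
      labels <- EBImage::watershed(dm, tolerance = ws_tolerance, ext = ws_ext)
      sizes <- tabulate(labels[labels > 0])
      count <- sum(sizes >= min_area_px)
    }
  }
  data.frame(
    mean_dapi_intensity = mean_dapi,
    mitotic_count = as.integer(count),
    slice_area_um2 = area_um2,
    mitotic_density_per_um2 = count / area_um2
  )
}
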