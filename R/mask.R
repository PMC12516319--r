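#' Construct an OrganoidMask from a logical matrix
#'
#' Validates the foreground (single component, holes filled -- holes are
#' filled here unconditionally, because profile binning needs a simply
#' connected region) and extracts the sub-pixel boundary polygon by
#' marching squares (`contourLines`) at level 0.5 on a Gaussian-smoothed
#' copy of the mask. The smoothing (default sigma 2 px) removes the
#' orientation-dependent staircase bias that pixel-edge contours impose
#' on perimeters, at a boundary-displacement cost of order
#' `sigma^2 * curvature / 2` (hundredths of a pixel for organoid-scale
#' shapes).
#'
#' @param pixels logical matrix (y, x), `TRUE` = organoid.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param contour_sigma_px Gaussian sigma (pixels) used only for contour
#'   extraction; the pixel mask itself is untouched.
#' @return an [OrganoidMask-class] object.
#' @export
OrganoidMask <- function(pixels, pixel_size_um, contour_sigma_px = 2) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  pixels <- pixels != 0
  if (!any(pixels)) stop("mask has empty foreground")
  lab <- EBImage::bwlabel(pixels * 1)
  if (max(lab) > 1L) {
    keep <- which.max(tabulate(lab[lab > 0]))
    pixels <- lab == keep
  }
  pixels <- EBImage::fillHull(pixels * 1) > 0
  ct <- maskContour(pixels, pixel_size_um, sigma = contour_sigma_px)
  new("OrganoidMask", pixels = pixels, pixel_size_um = pixel_size_um,
      contour = ct)
}

#' @noRd
#' Sub-pixel closed boundary polygon of a binary mask, in micrometres.
#' The mask is zero-padded, smoothed with a small Gaussian and contoured
#' at 0.5; the loop with the largest area is returned counter-clockwise.
maskContour <- function(pixels, pixel_size_um, sigma = 1) {
  pad <- max(4L, ceiling(4 * sigma))
  nr <- nrow(pixels); nc <- ncol(pixels)
  m <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- pixels * 1
  if (sigma > 0) m <- EBImage::gblur(m, sigma = sigma)
  # contourLines: its x runs over rows of z, its y over columns
  rows <- (seq_len(nrow(m)) - 1L - pad) * pixel_size_um  # our y
  cols <- (seq_len(ncol(m)) - 1L - pad) * pixel_size_um  # our x
  cl <- grDevices::contourLines(rows, cols, m, levels = 0.5)
  if (length(cl) == 0L) stop("no contour found at level 0.5")
  areas <- vapply(cl, function(l) abs(pracma::polyarea(l$y, l$x)), numeric(1))
  l <- cl[[which.max(areas)]]
  p <- cbind(x = l$y, y = l$x)
  closePolygon(p)
}

#' Mask accessors
#'
#' `areaUm2` is the foreground pixel count times the squared pixel size;
#' `perimeterUm` is the arc length of the sub-pixel contour polygon;
#' `centroidUm` the mean of foreground pixel centres, `(x, y)` in um.
#'
#' @param x an [OrganoidMask-class].
#' @return a numeric scalar (or length-2 vector for `centroidUm`).
#' @name areaUm2
#' @aliases areaUm2,OrganoidMask-method
#' @export
setMethod("areaUm2", "OrganoidMask", function(x)
  sum(x@pixels) * x@pixel_size_um^2)

#' @rdname areaUm2
#' @name perimeterUm
#' @aliases perimeterUm,OrganoidMask-method
#' @export
setMethod("perimeterUm", "OrganoidMask", function(x)
  polylineLength(x@contour))

#' @rdname areaUm2
#' @name centroidUm
#' @aliases centroidUm,OrganoidMask-method
#' @export
setMethod("centroidUm", "OrganoidMask", function(x) {
  p <- pixelCenters(x@pixels, x@pixel_size_um)
  c(x = mean(p[, 1]), y = mean(p[, 2]))
})

#' Physical pixel size
#' @param x an object with a pixel calibration.
#' @return micrometres per pixel.
#' @name pixelSize
#' @export
setMethod("pixelSize", "OrganoidMask", function(x) x@pixel_size_um)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixel_size_um)

#' Mask pixels
#' @param x an [OrganoidMask-class].
#' @return logical matrix.
#' @export
maskPixels <- function(x) x@pixels

#' Mask boundary polygon
#' @param x an [OrganoidMask-class].
#' @return closed n x 2 polygon (um).
#' @export
maskBoundary <- function(x) x@contour

setMethod("show", "OrganoidMask", function(object) {
  cat(sprintf(
    "OrganoidMask: %d x %d px at %.3g um/px | area %.1f um^2, perimeter %.1f um\n",
    nrow(object@pixels), ncol(object@pixels), object@pixel_size_um,
    areaUm2(object), perimeterUm(object)))
})

setMethod("show", "MedialAxisPath", function(object) {
  cat(sprintf(
    "MedialAxisPath: %d points | L = %.2f um, chord = %.2f um, S = %.4f\n",
    nrow(object@points), object@length_um, object@chord_um,
    object@chord_um / object@length_um))
})

setMethod("show", "PoleCall", function(object) {
  cat(sprintf("PoleCall [%s]: %d pole(s)%s\n", object@organoid_id,
              object@n_poles,
              if (object@n_poles)
                paste0(" at x = ",
                       paste(sprintf("%.3f", object@pole_positions),
                             collapse = ", "))
              else ""))
})

setMethod("show", "ProportionEstimate", function(object) {
  cat(sprintf(
    "ProportionEstimate: p = %.3f (n = %d), bootstrap se = %.4f, %d%% CI [%.3f, %.3f], B = %d\n",
    object@p_hat, object@n, object@se_boot, round(100 * object@conf),
    object@ci_low, object@ci_high, object@B))
})
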