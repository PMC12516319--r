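#' @import methods
NULL

#' Calibrated multi-dimensional image stack
#'
#' Container for a microscopy acquisition after loading: a 5-D intensity
#' array in fixed `(t, z, channel, y, x)` order (singleton dimensions kept)
#' together with its physical calibration. Calibration is always supplied
#' by the caller -- TIFF tags are at best a cross-check -- so that all
#' downstream quantities are unit-true (micrometres and minutes).
#'
#' @slot voxels numeric 5-D array, dimension order `(t, z, channel, y, x)`.
#' @slot axes character; which axes were declared at load time (subset of
#'   `"t"`, `"z"`, `"c"`). Operations that need a z axis check this.
#' @slot pixel_size_um micrometres per pixel in x and y.
#' @slot z_step_um micrometres per z plane (`NA` when no z axis).
#' @slot frame_interval_min minutes per frame (`NA` when no time axis).
#' @slot channel_names one label per channel.
#'
#' @seealso [readImageStack()], [maxProjection()]
#' @export
setClass("ImageStack",
  representation(
    voxels = "array",
    axes = "character",
    pixel_size_um = "numeric",
    z_step_um = "numeric",
    frame_interval_min = "numeric",
    channel_names = "character"
  )
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 5L)
    return("voxels must be a 5-D array (t, z, channel, y, x)")
  if (!all(is.finite(v)) || any(v < 0))
    return("intensities must be finite and non-negative")
  if (length(object@pixel_size_um) != 1L || object@pixel_size_um <= 0)
    return("pixel_size_um must be a single positive number")
  if (dim(v)[2] > 1L && (is.na(object@z_step_um) || object@z_step_um <= 0))
    return("z_step_um must be positive when more than one z plane is present")
  if (length(object@channel_names) != dim(v)[3])
    return("channel_names must have one entry per channel")
  if (!all(object@axes %in% c("t", "z", "c")))
    return("axes must be a subset of t, z, c")
  TRUE
})

#' Binary silhouette of a single organoid
#'
#' A validated organoid mask: exactly one 4-connected foreground
#' component with all holes filled, its physical pixel size, and a
#' sub-pixel closed boundary polygon extracted by marching squares on a
#' lightly smoothed copy of the mask. The polygon is used wherever a
#' perimeter enters a formula, because pixel-edge perimeters bias
#' circularity by roughly 10%.
#'
#' @slot pixels logical matrix `(y, x)`; `TRUE` = organoid.
#' @slot pixel_size_um micrometres per pixel.
#' @slot contour closed counter-clockwise polygon (n x 2, columns x/y, um).
#'
#' @seealso [segmentOrganoid()], [makeOrganoidMask()], [medialAxis()],
#'   [areaUm2()], [perimeterUm()], [centroidUm()]
#' @export
setClass("OrganoidMask",
  representation(
    pixels = "matrix",
    pixel_size_um = "numeric",
    contour = "matrix"
  )
)

setValidity("OrganoidMask", function(object) {
  m <- object@pixels
  if (!is.logical(m)) return("pixels must be a logical matrix")
  if (!any(m)) return("mask has empty foreground")
  if (length(object@pixel_size_um) != 1L || object@pixel_size_um <= 0)
    return("pixel_size_um must be a single positive number")
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) != 1L) return("mask must contain exactly one connected component")
  if (any(EBImage::fillHull(m * 1) != (m * 1))) return("mask must not contain holes")
  ct <- object@contour
  if (nrow(ct) < 4L || any(ct[1, ] != ct[nrow(ct), ]))
    return("contour must be a closed polygon")
  TRUE
})

#' Tangent-extended medial-axis path (the organoid body axis)
#'
#' The ordered body-axis polyline: the pruned medial-axis skeleton path,
#' smoothed, then extended at both ends with straight rays tangent to the
#' path until they cross the mask contour. Its arc length is the organoid
#' length L; the chord between the two contour intersections feeds the
#' straightness ratio.
#'
#' @slot points ordered polyline (n x 2, columns x/y, um) from end A to end B.
#' @slot length_um arc length L of the extended path (um).
#' @slot chord_um straight-line distance between the two endpoints (um).
#' @slot endpoints 2 x 2 matrix; rows are the contour intersection points.
#'
#' @seealso [medialAxis()], [straightness()]
#' @export
setClass("MedialAxisPath",
  representation(
    points = "matrix",
    length_um = "numeric",
    chord_um = "numeric",
    endpoints = "matrix"
  )
)

setValidity("MedialAxisPath", function(object) {
  p <- object@points
  if (nrow(p) < 2L) return("path needs at least 2 points")
  if (object@chord_um <= 0) return("chord must be positive")
  if (object@length_um < object@chord_um - 1e-9)
    return("arc length cannot be smaller than the chord")
  if (max(abs(object@endpoints - p[c(1L, nrow(p)), ])) > 1e-9)
    return("endpoints must equal the first and last path points")
  TRUE
})

#' Anteroposterior contour binning of an organoid
#'
#' The 100 quadrilateral sections used for profile extraction: the mask
#' contour is cut at the two medial-axis endpoints, each half is
#' resampled to 101 arc-length-equidistant points, and section i joins
#' points i and i+1 across the two sides. Every foreground pixel is
#' assigned to the section containing its centre (discretisation slivers
#' go to the nearest section centroid).
#'
#' @slot side_A,side_B 101 x 2 point matrices (um), both ordered from
#'   axis end A to end B.
#' @slot bins list of 100 closed quadrilateral polygons (um).
#' @slot bin_areas_um2 polygon area of each section.
#' @slot positions relative axial position of each section centroid
#'   (arc length along the medial axis divided by L), strictly increasing.
#' @slot assignment integer matrix matching the mask; bin index per
#'   foreground pixel, `NA` outside.
#' @slot pixel_size_um micrometres per pixel.
#' @slot flags character vector of per-bin warnings ("" when clean).
#'
#' @seealso [splitContour()], [makeBins()], [extractProfile()]
#' @export
setClass("ContourBinning",
  representation(
    side_A = "matrix",
    side_B = "matrix",
    bins = "list",
    bin_areas_um2 = "numeric",
    positions = "numeric",
    assignment = "matrix",
    pixel_size_um = "numeric",
    flags = "character"
  )
)

setValidity("ContourBinning", function(object) {
  if (nrow(object@side_A) != 101L || nrow(object@side_B) != 101L)
    return("each side must carry 101 points")
  if (length(object@bins) != 100L) return("there must be 100 bins")
  if (any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  TRUE
})

#' Set of 100-bin anteroposterior intensity profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation holding
#' one column per organoid profile: assay `"raw"` (mean intensity per
#' bin, a.u.), assay `"position"` (exact relative axial position of each
#' bin for that organoid) and, after [normalizeCohort()], assay
#' `"normalized"`. Column data carry `organoid_id`, `channel` and
#' `experiment`; normalization anchors land in `metadata()$anchors`.
#'
#' @seealso [profileSet()], [extractProfile()], [normalizeCohort()],
#'   [boundaryPosition()], [callPoles()]
#' @export
setClass("APProfileSet", contains = "SummarizedExperiment")

#' Pole call for one organoid profile
#'
#' Result of thresholding a normalized marker profile and counting
#' sufficiently long supra-threshold runs of bins; each run is one
#' expression pole.
#'
#' @slot n_poles integer number of poles.
#' @slot unique_pole `TRUE` iff exactly one pole.
#' @slot pole_positions relative axial position of each run centre.
#' @slot organoid_id identifier.
#' @seealso [callPoles()]
#' @export
setClass("PoleCall",
  representation(
    n_poles = "integer",
    unique_pole = "logical",
    pole_positions = "numeric",
    organoid_id = "character"
  )
)

setValidity("PoleCall", function(object) {
  if (object@unique_pole != (object@n_poles == 1L))
    return("unique_pole must equal (n_poles == 1)")
  if (object@n_poles != length(object@pole_positions))
    return("one position per pole required")
  TRUE
})

#' Proportion estimate with bootstrap uncertainty
#'
#' A sample proportion together with its nonparametric bootstrap
#' standard error and percentile confidence interval, as used for
#' pole-formation fractions.
#'
#' @slot p_hat observed fraction.
#' @slot n sample size.
#' @slot se_boot bootstrap standard error.
#' @slot ci_low,ci_high percentile interval bounds.
#' @slot conf confidence level of the interval.
#' @slot B number of bootstrap resamples.
#' @slot seed RNG seed used for the resampling.
#' @seealso [bootstrapProportion()]
#' @export
setClass("ProportionEstimate",
  representation(
    p_hat = "numeric",
    n = "integer",
    se_boot = "numeric",
    ci_low = "numeric",
    ci_high = "numeric",
    conf = "numeric",
    B = "integer",
    seed = "integer"
  )
)

setValidity("ProportionEstimate", function(object) {
  if (object@p_hat < 0 || object@p_hat > 1) return("p_hat must lie in [0, 1]")
  if (object@se_boot < 0) return("se_boot must be non-negative")
  if (!(object@ci_low <= object@p_hat + 1e-12 &&
        object@p_hat <= object@ci_high + 1e-12))
    return("percentile interval must bracket p_hat")
  if (object@ci_low < -1e-12 || object@ci_high > 1 + 1e-12)
    return("interval bounds must lie in [0, 1]")
  TRUE
})
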