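#' Call expression poles on a normalized marker profile
#'
#' Operationalizes pole scoring as a reproducible criterion: the
#' normalized profile is thresholded (default 0.5) and every maximal
#' run of at least `min_run` consecutive supra-threshold bins counts as
#' one pole, reported with the run-centre axial position. A "unique
#' pole" is exactly one such run.
#'
#' @param x numeric normalized profile (values expected in roughly
#'   `[0, 1]`; values outside `[-0.5, 1.5]` raise an error), or an
#'   [APProfileSet-class] with a `"normalized"` assay.
#' @param positions relative axial positions (numeric method; defaults
#'   to bin mid-points).
#' @param threshold intensity cut (default 0.5).
#' @param min_run minimum run length in bins (default 10).
#' @param organoid_id identifier for the returned call.
#' @param ... unused.
#' @return a [PoleCall-class] (numeric method) or a `data.frame` with
#'   one row per profile (set method).
#' @export
setMethod("callPoles", "numeric",
          function(x, positions = NULL, threshold = 0.5, min_run = 10L,
                   organoid_id = "organoid", ...) {
  if (any(!is.finite(x)))
    stop("profile contains non-finite values")
  if (any(x < -0.5 | x > 1.5))
    stop("profile does not look normalized (values outside [-0.5, 1.5])")
  if (is.null(positions)) positions <- (seq_along(x) - 0.5) / length(x)
  r <- rle(x >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  centers <- vapply(which(keep), function(i)
    mean(positions[starts[i]:ends[i]]), numeric(1))
  n <- length(centers)
  new("PoleCall", n_poles = as.integer(n), unique_pole = n == 1L,
      pole_positions = as.numeric(centers),
      organoid_id = as.character(organoid_id))
})

#' @rdname callPoles
#' @param assay assay of the profile set to threshold.
#' @export
setMethod("callPoles", "APProfileSet",
          function(x, threshold = 0.5, min_run = 10L,
                   assay = "normalized", ...) {
  vals <- SummarizedExperiment::assay(x, assay)
  pos <- SummarizedExperiment::assay(x, "position")
  cd <- SummarizedExperiment::colData(x)
  rows <- lapply(seq_len(ncol(vals)), function(j) {
    pc <- callPoles(vals[, j], pos[, j], threshold = threshold,
                    min_run = min_run, organoid_id = cd$organoid_id[j])
    data.frame(organoid_id = pc@organoid_id,
               channel = cd$channel[j], experiment = cd$experiment[j],
               n_poles = pc@n_poles, unique_pole = pc@unique_pole,
               pole_positions = paste(sprintf("%.4f", pc@pole_positions),
                                      collapse = ";"))
  })
  do.call(rbind, rows)
})

#' Bootstrap estimate of a proportion
#'
#' Sample proportion of a binary outcome vector with a nonparametric
#' bootstrap standard error and percentile confidence interval, as used
#' for the fraction of gastruloids forming a unique BRA/SOX2 pole. The
#' resampling is fully determined by `seed`.
#'
#' @param outcomes logical or 0/1 vector, `n >= 1`.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @param conf confidence level of the percentile interval.
#' @return a [ProportionEstimate-class].
#' @examples
#' bootstrapProportion(c(rep(1, 15), rep(0, 5)), B = 1000, seed = 7)
#' @export
bootstrapProportion <- function(outcomes, B = 1000L, seed, conf = 0.95) {
  outcomes <- as.numeric(outcomes)
  n <- length(outcomes)
  if (n < 1L) stop("empty outcome list")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  if (missing(seed)) stop("seed is required")
  p_hat <- mean(outcomes)
  stats <- withr::with_seed(as.integer(seed), {
    res <- matrix(sample(outcomes, n * B, replace = TRUE), nrow = B)
    rowMeans(res)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha)))
  new("ProportionEstimate", p_hat = p_hat, n = as.integer(n),
      se_boot = stats::sd(stats), ci_low = min(ci[1], p_hat),
      ci_high = max(ci[2], p_hat), conf = conf, B = as.integer(B),
      seed = as.integer(seed))
}
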