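#' Read a TIFF file into a calibrated ImageStack
#'
#' Reads a single- or multi-page TIFF and arranges the pages into the
#' fixed `(t, z, channel, y, x)` order according to the caller's axis
#' specification. Calibration is never guessed from TIFF tags: the
#' caller supplies it (the same scene may come from different
#' microscopes), which keeps every downstream quantity in micrometres
#' and minutes.
#'
#' @param path TIFF file (integer or float samples).
#' @param axes axis specification for the page dimension, a
#'   comma-separated subset of `"t"`, `"z"`, `"c"` ordered slowest to
#'   fastest (page index = ((t-1)*nz + (z-1))*nc + c for `"t,z,c"`).
#'   Pages holding multiple samples per pixel (e.g. RGB) contribute the
#'   channel axis automatically and `"c"` must then be absent from `axes`.
#' @param pixel_size_um micrometres per pixel in x/y.
#' @param z_step_um micrometres per z plane; required when `axes`
#'   contains `"z"` with more than one plane.
#' @param frame_interval_min minutes between frames (optional).
#' @param nt,nz,nchannel declared sizes for the axes named in `axes`;
#'   the trailing axis size may be omitted and is inferred. The product
#'   must equal the page count, otherwise an error is raised.
#' @param channel_names optional channel labels.
#' @return an [ImageStack-class].
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(lapply(1:6, function(i) matrix(i / 10, 4, 5)), tf)
#' stk <- readImageStack(tf, axes = "z", pixel_size_um = 0.22, z_step_um = 5)
#' dim(stackVoxels(stk))  # 1 6 1 4 5
#' @export
readImageStack <- function(path, axes = "z", pixel_size_um,
                           z_step_um = NA_real_,
                           frame_interval_min = NA_real_,
                           nt = NULL, nz = NULL, nchannel = NULL,
                           channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  npage <- length(pages)
  d1 <- dim(pages[[1]])
  page_channels <- if (length(d1) == 3L) d1[3] else 1L

  ax <- if (nzchar(axes)) strsplit(axes, ",", fixed = TRUE)[[1]] else character()
  ax <- trimws(ax)
  if (anyDuplicated(ax) || !all(ax %in% c("t", "z", "c")))
    stop("axes must be a comma-separated subset of t, z, c")
  if (page_channels > 1L && "c" %in% ax)
    stop("pages already carry a channel dimension; drop 'c' from axes")

  declared <- list(t = nt, z = nz, c = nchannel)
  sizes <- vapply(ax, function(a) {
    v <- declared[[a]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  if (length(ax) == 0L) {
    if (npage != 1L) stop("multi-page TIFF needs an axis specification")
    sizes <- integer(0)
  } else if (sum(is.na(sizes)) > 1L) {
    stop("at most one axis size may be left to inference")
  } else if (any(is.na(sizes))) {
    known <- prod(sizes[!is.na(sizes)])
    if (npage %% known != 0L)
      stop(sprintf("page count %d is not divisible by declared sizes (%d)",
                   npage, known))
    sizes[is.na(sizes)] <- npage %/% known
  }
  if (length(sizes) && prod(sizes) != npage)
    stop(sprintf("axis sizes (product %d) inconsistent with %d pages",
                 prod(sizes), npage))

  get <- function(a) if (a %in% ax) sizes[[a]] else 1L
  ntt <- get("t"); nzz <- get("z"); ncc <- max(get("c"), page_channels)
  ny <- d1[1]; nx <- d1[2]

  vox <- array(0, dim = c(ntt, nzz, ncc, ny, nx))
  for (p in seq_len(npage)) {
    # decompose page index along declared axes, slowest first
    rem <- p - 1L
    idx <- c(t = 1L, z = 1L, c = 1L)
    for (a in rev(ax)) {           # fastest axis varies first
      idx[a] <- rem %% sizes[[a]] + 1L
      rem <- rem %/% sizes[[a]]
    }
    pg <- pages[[p]]
    if (page_channels > 1L) {
      for (ch in seq_len(page_channels))
        vox[idx["t"], idx["z"], ch, , ] <- pg[, , ch]
    } else {
      vox[idx["t"], idx["z"], idx["c"], , ] <- pg
    }
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncc))
  axset <- ax
  if (page_channels > 1L) axset <- union(axset, "c")
  new("ImageStack", voxels = vox, axes = axset,
      pixel_size_um = pixel_size_um, z_step_um = z_step_um,
      frame_interval_min = frame_interval_min,
      channel_names = channel_names)
}

#' @describeIn readImageStack raw `(t, z, channel, y, x)` voxel array.
#' @param x an [ImageStack-class].
#' @export
stackVoxels <- function(x) x@voxels

#' @describeIn readImageStack channel labels.
#' @export
channelNames <- function(x) x@channel_names

#' Read a single-cell track table
#'
#' Loads a delimited TrackMate-style export (columns `TRACK_ID`,
#' `POSITION_T`, `POSITION_X`, `POSITION_Y` and, for 3-D data,
#' `POSITION_Z`), applies the caller-supplied calibration so that
#' positions are in micrometres and times in minutes, and sorts points
#' by time within each track. Row order in the file is irrelevant.
#'
#' @param path delimited text file with a header line.
#' @param dialect only `"trackmate-csv"` is supported.
#' @param ndim 3 (default) requires `POSITION_Z`; 2 tolerates its
#'   absence and fills z with 0.
#' @param xy_scale,z_scale micrometres per input position unit (1 when
#'   the file is already calibrated).
#' @param t_scale minutes per input time unit.
#' @param sep field separator.
#' @return a `data.frame` with columns `track_id`, `t` (min), `x`, `y`,
#'   `z` (um), sorted by track and time; every track has >= 2 points and
#'   strictly increasing timestamps.
#' @export
readTracks <- function(path, dialect = "trackmate-csv", ndim = 3,
                       xy_scale = 1, z_scale = 1, t_scale = 1, sep = ",") {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "POSITION_T", "POSITION_X", "POSITION_Y")
  if (ndim >= 3) need <- c(need, "POSITION_Z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(
    track_id = as.character(df$TRACK_ID),
    t = df$POSITION_T * t_scale,
    x = df$POSITION_X * xy_scale,
    y = df$POSITION_Y * xy_scale,
    z = if (ndim >= 3) df$POSITION_Z * z_scale else 0,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(out[c("t", "x", "y", "z")]))))
    stop("non-finite coordinates in track table")
  out <- out[order(out$track_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  for (id in unique(out$track_id)) {
    tt <- out$t[out$track_id == id]
    if (length(tt) < 2L)
      stop("track ", id, " has fewer than 2 points")
    if (any(diff(tt) <= 0))
      stop("track ", id, " has duplicated or non-increasing timestamps")
  }
  out
}

#' Write result records as annotated CSV
#'
#' Writes any module's output rows as comma-separated text with a
#' header line, preceded by `#`-prefixed comment lines documenting units
#' and provenance. Numbers are written with full precision so a
#' write/read round trip preserves values to better than 1e-9 relative
#' error.
#'
#' @param records a `data.frame` (possibly empty).
#' @param path output file.
#' @param comments character vector of comment lines (without the `#`).
#' @return `path`, invisibly.
#' @seealso [readRecords()]
#' @export
writeRecords <- function(records, path, comments = character()) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  out[num] <- lapply(records[num], function(v)
    formatC(v, digits = 17, format = "g"))
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read records written by writeRecords
#' @param path file produced by [writeRecords()].
#' @return a `data.frame`.
#' @export
readRecords <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
}
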