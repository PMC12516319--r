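#' Run the analysis pipeline from a single configuration
#'
#' Orchestrates the stages in dependency order (simulate -> segment ->
#' morphometry / profiles -> poles; density, tracks and motion run on
#' their own inputs) from one serializable configuration, so a run is
#' fully described by the config plus a seed. Every output table starts
#' with `#` provenance comments (package version, config hash, seed,
#' effective parameters), and re-running the same config and seed
#' reproduces the tables exactly.
#'
#' @param config a list, or the path of a YAML file, with entries:
#'   `calibration` (must contain `pixel_size_um`; `frame_interval_min`
#'   where time is involved), `seed`, `stages` (character vector),
#'   `output_dir`, and one optional block of parameters per stage
#'   (`simulate`, `segment`, `morphometry`, `profiles`, `poles`,
#'   `density`, `tracks`, `motion`). The `simulate` block selects a
#'   `scene` of `"organoid"`, `"timelapse"` or `"tracks"` and passes
#'   its remaining entries to the matching generator.
#' @param seed overrides `config$seed` when given.
#' @param output_dir overrides `config$output_dir` when given.
#' @return invisibly, a list with the per-stage results and the paths
#'   of the written tables.
#' @export
runPipeline <- function(config, seed = NULL, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$calibration$pixel_size_um))
    stop("config is missing calibration$pixel_size_um")
  psz <- config$calibration$pixel_size_um
  if (!is.numeric(psz) || psz <= 0)
    stop("calibration$pixel_size_um must be a positive number")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (is.null(config$output_dir)) config$output_dir <- tempfile("gastromorph_run_")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages)) stop("config lists no stages")

  eff <- config
  eff$output_dir <- NULL            # paths do not affect the numbers
  prov <- c(
    paste0("gastromorph ", as.character(utils::packageVersion("gastromorph"))),
    paste0("config_hash ", configHash(eff)),
    paste0("seed ", config$seed)
  )
  results <- list(files = character())
  emit <- function(df, name, units = character()) {
    path <- file.path(config$output_dir, paste0(name, ".csv"))
    writeRecords(df, path, comments = c(prov, units))
    results$files[[name]] <<- path
  }
  stageArgs <- function(stage) {
    a <- config[[stage]]
    if (is.null(a)) list() else a
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  scene <- NULL
  for (stage in stages) {
    switch(stage,
      simulate = runStage("simulate", function() {
        a <- stageArgs("simulate")
        kind <- if (is.null(a$scene)) "organoid" else a$scene
        a$scene <- NULL
        a$seed <- config$seed
        scene <<- switch(kind,
          organoid = {
            a$pixel_size_um <- psz
            c(do.call(makeOrganoidMask, a), list(kind = "organoid"))
          },
          timelapse = {
            a$pixel_size_um <- psz
            if (!is.null(config$calibration$frame_interval_min))
              a$frame_interval_min <- config$calibration$frame_interval_min
            c(do.call(makeTimelapse, a), list(kind = "timelapse"))
          },
          tracks = c(do.call(makeTracks, a), list(kind = "tracks")),
          stop("unknown scene '", kind, "'"))
        emit(as.data.frame(scene$truth[!vapply(scene$truth, is.list, TRUE) &
                                       lengths(scene$truth) == 1L]),
             "scene_truth")
        results$scene <<- scene
      }),
      segment = runStage("segment", function() {
        a <- stageArgs("segment")
        img <- if (!is.null(scene$mask)) maskPixels(scene$mask) * 100
               else stop("no input image available")
        a$image <- img; a$pixel_size_um <- psz
        results$mask <<- do.call(segmentOrganoid, a)
      }),
      morphometry = runStage("morphometry", function() {
        mask <- if (!is.null(results$mask)) results$mask else scene$mask
        if (is.null(mask)) stop("no mask available")
        rec <- morphometry(mask)
        results$morphometry <<- rec
        emit(rec, "morphometry",
             "units: length_um/area_um2/perimeter_um in um; straightness, elongation_index, aspect_ratio dimensionless")
      }),
      profiles = runStage("profiles", function() {
        mask <- if (!is.null(results$mask)) results$mask else scene$mask
        if (is.null(mask)) stop("no mask available")
        a <- stageArgs("profiles")
        ax <- medialAxis(mask)
        binning <- makeBins(splitContour(mask, ax), mask, ax)
        mk <- makeMarkerImage(mask, ax,
                              profile_spec = if (is.null(a$profile_spec)) list() else a$profile_spec,
                              noise_sd = if (is.null(a$noise_sd)) 0.1 else a$noise_sd,
                              seed = config$seed)
        prof <- extractProfile(mk$image, binning)
        results$profiles <<- prof
        emit(data.frame(bin = 1:100,
                        position = SummarizedExperiment::assay(prof, "position")[, 1],
                        raw = SummarizedExperiment::assay(prof, "raw")[, 1]),
             "profile", "units: position relative (0-1); raw intensity a.u.")
      }),
      poles = runStage("poles", function() {
        if (is.null(results$profiles)) stop("poles stage needs profiles")
        raw <- SummarizedExperiment::assay(results$profiles, "raw")[, 1]
        sc <- (raw - min(raw)) / max(max(raw) - min(raw), 1e-12)
        pc <- callPoles(sc,
                        SummarizedExperiment::assay(results$profiles, "position")[, 1])
        df <- data.frame(organoid_id = pc@organoid_id, n_poles = pc@n_poles,
                         unique_pole = pc@unique_pole)
        results$poles <<- pc
        emit(df, "poles")
      }),
      density = runStage("density", function() {
        mask <- if (!is.null(results$mask)) results$mask else scene$mask
        if (is.null(mask)) stop("no mask available")
        a <- stageArgs("density")
        n <- if (is.null(a$n_spots)) 10L else a$n_spots
        np <- makeNucleiPlane(mask, n, seed = config$seed)
        rec <- countMitotic(np$image, mask)
        results$density <<- rec
        emit(rec, "density", "units: areas um^2, density 1/um^2")
      }),
      tracks = runStage("tracks", function() {
        tr <- if (!is.null(scene$tracks)) scene$tracks
              else stop("no track table available")
        a <- stageArgs("tracks")
        tr <- filterTracks(tr,
          min_points = if (is.null(a$min_points)) 10L else a$min_points,
          max_points = if (is.null(a$max_points)) 25L else a$max_points)
        fit <- msdFit(tr,
          max_lag_fraction = if (is.null(a$max_lag_fraction)) 0.25 else a$max_lag_fraction,
          dims = if (is.null(a$dims)) 3L else a$dims)
        results$tracks <<- fit
        emit(fit$per_track, "track_stats",
             "units: speed um/min, rates rad/min, D um^2/min")
        emit(fit$ensemble_msd, "ensemble_msd", "units: lag min, msd um^2")
      }),
      motion = runStage("motion", function() {
        if (is.null(scene$masks)) stop("motion stage needs a timelapse scene")
        fim <- config$calibration$frame_interval_min
        if (is.null(fim)) stop("config is missing calibration$frame_interval_min")
        mo <- timelapseMotion(scene$masks, psz, fim)
        results$motion <<- mo
        emit(data.frame(total_displacement_um = mo$total_displacement_um,
                        radial_growth_rate_um_per_min = mo$radial_growth_rate_um_per_min),
             "motion", "units: um and um/min")
      }),
      stop("unknown stage '", stage, "'")
    )
  }
  invisible(results)
}

#' @noRd
#' md5 of the canonicalized config; changes iff an effective parameter
#' changes.
configHash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(canon(config)), tmp)
  unname(tools::md5sum(tmp))
}
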