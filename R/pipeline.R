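#' Run configuration for end-to-end still-series analysis
#'
#' Collects the analysis parameters of the still-diffraction pipeline with
#' defaults matching the reference workflow: detection threshold 1.25x
#' background, diamond mask radius 25 px, brightest 20% of traces summed,
#' derivative bins of 0.1 e-/A^2, k = 5 trace clusters, 2-sigma mis-index
#' rejection. Serializable as a plain-text key = value file.
#'
#' @param stack_path input stack (MRC file or SMV directory), or "" when the
#'   stack is passed in memory.
#' @param format `"mrc"` or `"smv-series"`.
#' @param threshold_factor,mask_radius,top_fraction,bin_width,k,sigma_k,
#'   point_group,quake_threshold analysis parameters (see the stage
#'   functions).
#' @param seed integer seed for the clustering restarts.
#' @return object of class `RunConfig` (a named list).
#' @export
run_config <- function(stack_path = "", format = "mrc",
                       threshold_factor = 1.25, mask_radius = 25,
                       top_fraction = 0.2, bin_width = 0.1, k = 5,
                       sigma_k = 2, point_group = "1", quake_threshold = 1,
                       seed = 0) {
  structure(list(stack_path = stack_path, format = format,
                 threshold_factor = threshold_factor,
                 mask_radius = mask_radius, top_fraction = top_fraction,
                 bin_width = bin_width, k = k, sigma_k = sigma_k,
                 point_group = point_group, quake_threshold = quake_threshold,
                 seed = seed),
            class = "RunConfig")
}

#' @rdname run_config
#' @param path file to write/read.
#' @export
write_run_config <- function(config, path) {
  write_manifest(unclass(config), path)
}

#' @rdname run_config
#' @param config a `RunConfig` (for writing).
#' @export
read_run_config <- function(path) {
  vals <- read_manifest(path)
  cfg <- run_config()
  for (nm in names(vals)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    # manifest values parse as numeric when possible; restore declared types
    cfg[[nm]] <- if (is.character(cfg[[nm]])) as.character(vals[[nm]]) else vals[[nm]]
  }
  cfg
}

#' End-to-end still-diffraction dose-series analysis
#'
#' Runs the full spot-tracing pipeline on a diffraction stack: detection
#' image, spot finding, trace integration, summed trace of the brightest
#' reflections, derivative profile, and k-means trace clustering; when an
#' orientation table is supplied, also symmetry disambiguation, mis-index
#' rejection, net-rotation decomposition and quake detection. All numeric
#' outputs are written as TSV under `out_dir` together with a manifest
#' recording the parameters and input hashes.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @param stack optional in-memory `FrameStack` (overrides
#'   `config$stack_path`).
#' @param orientations optional `OrientationSeries` or path to a TSV
#'   orientation table.
#' @return invisibly, a list with the stage results (`spots`, `traces`,
#'   `summed`, `profile`, `clusters`, and when orientations were given
#'   `series`, `rotation`, `quake_fluence`).
#' @export
run_still_series <- function(config, out_dir, stack = NULL, orientations = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  if (is.null(stack)) {
    if (!nzchar(config$stack_path) || !file.exists(config$stack_path)) {
      stop("input stack not found: '", config$stack_path, "'")
    }
    stack <- read_stack(config$stack_path, config$format)
  }
  log_msg("[trace] %d frames; threshold %.3g x background, mask radius %d px",
          n_frames(stack), config$threshold_factor, config$mask_radius)
  det_img <- detection_image(stack)
  spots <- find_spots(det_img, config$threshold_factor,
                      mask_radius = config$mask_radius,
                      geometry = stack$detector)
  if (nrow(spots) == 0) stop("stage find_spots: no spots detected")
  log_msg("[trace] %d spots detected", nrow(spots))
  traces <- integrate_traces(stack, spots)
  summed <- summed_trace(traces, config$top_fraction)
  profile <- derivative_profile(summed, stack$fluence_axis, config$bin_width)
  norm <- normalize_per_trace(traces)
  clusters <- if (nrow(norm$values) >= config$k) {
    cluster_traces(norm, k = config$k, seed = config$seed)
  } else {
    log_msg("[cluster] skipped: %d traces < k = %d", nrow(norm$values), config$k)
    NULL
  }
  utils::write.table(
    data.frame(id = traces$spot_id, traces$values, check.names = FALSE),
    file.path(out_dir, "traces.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(fluence = stack$fluence_axis, summed = as.numeric(summed)),
    file.path(out_dir, "summed_trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(mid_fluence = profile$mid_fluence, derivative = profile$derivative),
    file.path(out_dir, "derivative.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(clusters)) {
    utils::write.table(
      data.frame(id = clusters$spot_id, cluster = clusters$labels),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  result <- list(spots = spots, traces = traces, summed = summed,
                 profile = profile, clusters = clusters)
  if (!is.null(orientations)) {
    series <- if (inherits(orientations, "OrientationSeries")) {
      orientations
    } else {
      read_orientation_table(orientations, point_group = config$point_group)
    }
    series$point_group <- config$point_group
    series <- disambiguate(series)
    series <- reject_misindexed(series, config$sigma_k)
    n_rej <- length(attr(series, "rejected"))
    log_msg("[bir] %d frame(s) rejected as mis-indexed", n_rej)
    rot <- net_rotation(series)
    quake <- detect_quake(rot, config$quake_threshold)
    utils::write.table(
      data.frame(frame = rot$frame, fluence = rot$fluence,
                 angle = rot$per_frame_angle,
                 a = rot$per_vector_angles[, 1],
                 b = rot$per_vector_angles[, 2],
                 c = rot$per_vector_angles[, 3]),
      file.path(out_dir, "rotation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    result$series <- series
    result$rotation <- rot
    result$quake_fluence <- quake
    log_msg("[bir] net rotation %.4f deg at %.4g e-/A^2%s",
            rot$final_angle, rot$final_fluence,
            if (is.null(quake)) "" else sprintf("; quake at %.4g e-/A^2", quake))
  }
  manifest <- c(unclass(config),
                list(n_frames = n_frames(stack), n_spots = nrow(spots),
                     package_version = as.character(utils::packageVersion("birtrack"))))
  if (nzchar(config$stack_path) && file.exists(config$stack_path)) {
    manifest$stack_md5 <- unname(tools::md5sum(config$stack_path))
  }
  write_manifest(manifest, file.path(out_dir, "manifest.txt"))
  invisible(result)
}

#' Generate canonical ground-truth fixtures
#'
#' Writes small synthetic datasets with known ground truth to `dir`:
#' a drift-only orientation track, a quake track, a decay-only rendered
#' diffraction series (MRC), a static imaging stack and a migrating-band
#' imaging stack (MRC), each with a key = value manifest of the generating
#' parameters.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_frames frames per fixture.
#' @return invisibly, the fixture directory.
#' @export
make_fixtures <- function(dir, seed = 1, n_frames = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- crystal_model(seed = seed)
  det <- detector_geometry(shape = c(256, 256), distance = 250)

  drift <- simulate_orientation_track(
    model, bir_trajectory(n_frames = n_frames, fluence_per_frame = 0.01,
                          drift_rate = 1, drift_axis = c(0, 0, 1)))
  write_orientation_table(drift, file.path(dir, "drift_track.tsv"))
  write_manifest(list(kind = "drift", drift_rate = 1, fluence_per_frame = 0.01,
                      n_frames = n_frames, drift_axis = c(0, 0, 1),
                      gt_final_angle = attr(drift, "gt_final_angle"),
                      point_group = model$point_group, seed = seed),
                 file.path(dir, "drift_track.manifest"))

  quake <- simulate_orientation_track(
    model, bir_trajectory(n_frames = n_frames, fluence_per_frame = 0.01,
                          quake_fluence = 0.08, quake_angle = 3,
                          quake_axis = c(2, -1, 1) / sqrt(6)))
  write_orientation_table(quake, file.path(dir, "quake_track.tsv"))
  write_manifest(list(kind = "quake", quake_fluence = 0.08, quake_angle = 3,
                      fluence_per_frame = 0.01, n_frames = n_frames,
                      gt_quake_frame = attr(quake, "gt_quake_frame"),
                      point_group = model$point_group, seed = seed),
                 file.path(dir, "quake_track.manifest"))

  # static series at a generic orientation with a well-spread still pattern
  nd <- min(n_frames, 40)
  Mfix <- rotation_about_axis(c(1, 1, 1), 15) %*% cell_matrix(model$cell)
  static <- orientation_series(array(rep(Mfix, nd), c(3, 3, nd)),
                               (1:nd) * 0.05, model$cell, model$point_group)
  decay <- render_dose_series(model, static, det, background = 2)
  write_stack(decay, file.path(dir, "decay_only.mrc"), "mrc")
  write_manifest(list(kind = "decay-only", decay_rate = model$decay_rate,
                      n_frames = length(static), fluence_per_frame = 0.05,
                      resolution_limit = model$resolution_limit, seed = seed),
                 file.path(dir, "decay_only.manifest"))

  still <- generate_bend_contour_stack(
    n_frames = n_frames, band_params = list(width = 3, contrast = 0.6,
                                            speed = 0, settle_fluence = 0.5),
    seed = seed, noise_sd = 0)
  write_stack(still, file.path(dir, "static_imaging.mrc"), "mrc")
  write_manifest(list(kind = "static-imaging", speed = 0, n_frames = n_frames,
                      seed = seed),
                 file.path(dir, "static_imaging.manifest"))

  band <- generate_bend_contour_stack(
    n_frames = n_frames, band_params = list(width = 3, contrast = 0.6,
                                            speed = 20, settle_fluence = 0.5),
    seed = seed, noise_sd = 1)
  write_stack(band, file.path(dir, "migrating_band.mrc"), "mrc")
  write_manifest(list(kind = "migrating-band", speed = 20, settle_fluence = 0.5,
                      fluence_per_frame = 0.01, n_frames = n_frames, seed = seed),
                 file.path(dir, "migrating_band.manifest"))
  invisible(dir)
}
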