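#' Run an end-to-end SMLM analysis pipeline
#'
#' Thin orchestration over the library: executes a list of stages in order,
#' writing every intermediate artifact (filtered movie, localization tables,
#' drift trace, renders, reports) plus a JSON run manifest with parameters
#' and seeds. Stages may be skipped or reordered freely as long as each
#' stage's input exists.
#'
#' Supported stage types and their parameters:
#' \describe{
#'   \item{simulate}{`n_frames`, `shape`, `n_emitters`, `k_on`, `k_off`,
#'     `photons`, `background`, `read_noise` — writes `raw.tif` and truth.}
#'   \item{bgfilter}{`window_frames` — writes `filtered.tif`.}
#'   \item{localize}{detection parameters — writes `locs.csv`.}
#'   \item{merge}{`max_jump_px`, `max_gap_frames` — writes `merged.csv`.}
#'   \item{drift_cc}{`bin_frames`, `zoom` — writes `drift.csv`,
#'     `corrected.csv`.}
#'   \item{render}{`method`, `zoom`, `sigma_render_px` — writes
#'     `render.csv` (raster as CSV matrix).}
#'   \item{frc}{`render_pixel_nm` — adds the resolution to the manifest.}
#'   \item{nena}{`capture_radius_px` — adds sigma to the manifest.}
#' }
#'
#' @param config list with `seed`, `pixel_size_nm`, `frame_interval_s` and
#'   `stages` (named list of stage parameter lists, executed in order).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  px <- config$pixel_size_nm %||% 100
  dt <- config$frame_interval_s %||% 0.03
  manifest <- list(seed = seed, pixel_size_nm = px, frame_interval_s = dt,
                   stages = list())
  movie <- NULL; filtered <- NULL; locs <- NULL
  for (nm in names(config$stages)) {
    p <- config$stages[[nm]]
    t0 <- proc.time()[["elapsed"]]
    if (nm == "simulate") {
      shape <- p$shape %||% c(48, 48)
      ne <- p$n_emitters %||% 20
      set.seed(seed)
      pos <- cbind(runif(ne, 6, shape[2] - 6), runif(ne, 6, shape[1] - 6))
      sim <- simulate_movie(
        emitter_model(pos, k_on = p$k_on %||% 0.02, k_off = p$k_off %||% 0.5,
                      photons_per_frame = p$photons %||% 2000),
        noise_model(background_offset = p$background %||% 20,
                    read_noise_sigma = p$read_noise %||% 2),
        n_frames = p$n_frames %||% 200, shape = shape, seed = seed,
        pixel_size_nm = px, frame_interval_s = dt)
      movie <- sim$movie
      write_movie(movie, file.path(out_dir, "raw.tif"))
      write_localizations(
        loc_table(frame = sim$truth$emissions$frame,
                  x = sim$truth$emissions$x, y = sim$truth$emissions$y,
                  intensity = rep(p$photons %||% 2000,
                                  nrow(sim$truth$emissions)),
                  pixel_size_nm = px, frame_interval_s = dt),
        file.path(out_dir, "truth.csv"))
    } else if (nm == "bgfilter") {
      if (is.null(movie)) stop("bgfilter: no movie available")
      filtered <- temporal_median_filter(movie, p$window_frames %||% 51)
      write_movie(filtered, file.path(out_dir, "filtered.tif"))
    } else if (nm == "localize") {
      if (is.null(movie)) stop("localize: no movie available")
      locs <- localize_movie(movie, filtered,
                             detection_params(threshold_k = p$threshold_k %||% 3))
      write_localizations(locs, file.path(out_dir, "locs.csv"))
    } else if (nm == "merge") {
      if (is.null(locs)) stop("merge: no localizations available")
      linked <- link_localizations(locs,
                                   link_params(p$max_jump_px %||% 0.8,
                                               p$max_gap_frames %||% 2))
      locs <- merge_linked(linked, max_jump_px = p$max_jump_px %||% 0.8)
      write_localizations(locs, file.path(out_dir, "merged.csv"))
    } else if (nm == "drift_cc") {
      if (is.null(locs)) stop("drift_cc: no localizations available")
      nf <- max(locs$frame) + 1L
      tr <- estimate_drift_cc(locs, nf, bin_frames = p$bin_frames,
                              zoom = p$zoom %||% 5)
      write_drift_trace(tr, file.path(out_dir, "drift.csv"))
      locs <- apply_drift(locs, tr)
      write_localizations(locs, file.path(out_dir, "corrected.csv"))
    } else if (nm == "render") {
      if (is.null(locs)) stop("render: no localizations available")
      img <- render_locs(locs, method = p$method %||% "histogram",
                         zoom = p$zoom %||% 10,
                         sigma_render_px = p$sigma_render_px)
      utils::write.table(img$data, file.path(out_dir, "render.csv"),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    } else if (nm == "frc") {
      if (is.null(locs)) stop("frc: no localizations available")
      fc <- frc_resolution(locs, render_pixel_nm = p$render_pixel_nm %||% 10,
                           seed = seed)
      manifest$frc_resolution_nm <- fc$resolution_nm
    } else if (nm == "nena") {
      if (is.null(locs)) stop("nena: no localizations available")
      nf <- nena_precision(locs, capture_radius_px = p$capture_radius_px %||% 2)
      manifest$nena_sigma_nm <- nf$sigma_nm
    } else {
      stop("unknown pipeline stage: ", nm)
    }
    manifest$stages[[nm]] <- c(p, list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
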