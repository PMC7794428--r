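#' Analyse a sperm sample from captured fields
#'
#' Runs the full pipeline for each field -- artefact mask, segmentation,
#' track linking, kinematics, motility classification, concentration --
#' then aggregates fields into a sample result with QC flags.  Fully
#' deterministic given the input and settings.
#'
#' Each element of `fields` may be a [frame_stack()], a detections
#' data.frame (columns `frame`, `x_um`, `y_um`, `area_um2`, `intensity`),
#' or a path to a multi-page TIFF (`.tif`/`.tiff`) or detections CSV
#' (`.csv`).  For stacks the field size, calibration and frame rate come
#' from the stack; for detection tables they come from the settings
#' (`field_width_um`, `field_height_um`, `frame_rate_hz`,
#' `capture_duration_s`).
#'
#' @param fields list of field inputs (at least one).
#' @param settings a [casa_settings()].
#' @param sample_id,treatment sample metadata.
#' @param output_dir if non-NULL, writes `tracks.csv`, `kinematics.csv` and
#'   `sample.json` (sample result + QC report) there.
#' @param use_mask build and apply the static-artefact mask on image stacks
#'   with at least 5 frames.
#' @return list of class `casa_analysis`: `sample` ([aggregate_sample()]
#'   result), `qc` ([qc_report()]), `fields` (per-field results), `tracks`
#'   and `kinematics` (combined tables with a `field` column).
#' @export
analyze <- function(fields, settings = casa_settings(),
                    sample_id = "sample", treatment = NA_character_,
                    output_dir = NULL, use_mask = TRUE) {
  if (!is.list(fields) || length(fields) == 0)
    stopf("at least one field is required")
  field_results <- list()
  all_tracks <- list()
  all_kin <- list()
  track_offset <- 0L
  load_time <- capture_time <- NA

  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (is.character(f)) f <- read_field_input(f)
    if (inherits(f, "frame_stack")) {
      s <- settings
      s$microns_per_pixel <- f$microns_per_pixel
      s$frame_rate_hz <- f$frame_rate_hz
      mask <- if (use_mask && length(f$frames) >= 5)
        build_artifact_mask(f, s) else NULL
      det <- segment_stack(f, s, mask)
      dims <- stack_field_um(f)
      area <- dims[["width_um"]] * dims[["height_um"]]
      n_frames <- length(f$frames)
      if (i == 1) { load_time <- f$load_time; capture_time <- f$capture_time }
    } else if (is.data.frame(f)) {
      s <- settings
      det <- f
      area <- settings$field_width_um * settings$field_height_um
      n_frames <- n_capture_frames(settings)
    } else {
      stopf("field %d: unsupported input of class '%s'", i, class(f)[1])
    }
    if (nrow(det) > 0 && min(det$frame) < 0)
      stopf("field %d: frame indices must be 0-based (non-negative)", i)
    tracks <- link_detections(det, s$cell_travel_max_um)
    kin <- track_kinematics(tracks, s)
    field_results[[i]] <- field_result(kin, det, n_frames, area, s,
                                       field_id = i)
    if (nrow(tracks) > 0) {
      tracks$track_id <- tracks$track_id + track_offset
      kin$track_id <- kin$track_id + track_offset
      track_offset <- track_offset + max(tracks$track_id - track_offset)
    }
    if (nrow(tracks) > 0)
      all_tracks[[i]] <- cbind(field = i, tracks)
    if (nrow(kin) > 0)
      all_kin[[i]] <- cbind(field = i, kin)
  }

  tracks <- if (length(all_tracks)) do.call(rbind, all_tracks) else
    cbind(field = integer(0), link_detections(empty_detections(), 1))
  kin <- if (length(all_kin)) do.call(rbind, all_kin) else NULL
  rownames(tracks) <- NULL
  if (!is.null(kin)) rownames(kin) <- NULL

  n_cells <- sum(vapply(field_results, `[[`, numeric(1), "n_tracks"))
  conc <- mean(vapply(field_results, `[[`, numeric(1), "concentration"))
  qc <- qc_report(length(field_results), n_cells, conc, tracks,
                  load_time, capture_time, settings)
  sample <- aggregate_sample(field_results, settings, sample_id, treatment,
                             qc = qc)
  out <- structure(list(sample = sample, qc = qc, fields = field_results,
                        tracks = tracks, kinematics = kin),
                   class = "casa_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

#' @export
print.casa_analysis <- function(x, ...) {
  print(x$sample)
  invisible(x)
}

read_field_input <- function(path) {
  if (!file.exists(path)) stopf("input not found: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    read_tiff_stack(path)
  else if (grepl("\\.csv$", path, ignore.case = TRUE))
    read_detections_csv(path)
  else stopf("unsupported input format: %s (TIFF or detections CSV)", path)
}

write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks_csv(analysis$tracks, file.path(dir, "tracks.csv"))
  if (!is.null(analysis$kinematics))
    write_kinematics_csv(analysis$kinematics,
                         file.path(dir, "kinematics.csv"))
  write_sample_json(analysis, file.path(dir, "sample.json"))
  invisible(dir)
}

#' Write a sample result (with QC report) as JSON
#'
#' The JSON carries no timestamps, so the same input and settings produce
#' byte-identical output.
#'
#' @param analysis a [analyze()] result (or a bare `sample_result`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_json <- function(analysis, path) {
  obj <- if (inherits(analysis, "casa_analysis"))
    list(sample = unclass(analysis$sample),
         qc = unclass(analysis$qc))
  else list(sample = unclass(analysis))
  obj$units <- list(coordinates = "um", velocity = "um/s",
                    concentration = "cells/mL", frames = "0-based")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Batch comparison table of sample results
#'
#' One row per sample (ordered by sample id): treatment, motility
#' percentages (to 0.1), concentrations (3 significant figures) and a QC
#' summary -- the season-to-season comparison surface.
#'
#' @param results list of [aggregate_sample()] results or [analyze()]
#'   results.
#' @param path optional CSV output path.
#' @return data.frame.
#' @export
report <- function(results, path = NULL) {
  if (inherits(results, c("sample_result", "casa_analysis")))
    results <- list(results)
  if (length(results) == 0) stopf("at least one sample result is required")
  rows <- lapply(results, function(r) {
    if (inherits(r, "casa_analysis")) r <- r$sample
    stopifnot(inherits(r, "sample_result"))
    data.frame(sample_id = r$sample_id,
               treatment = r$treatment,
               n_fields = r$n_fields,
               n_cells = r$n_cells,
               total_motility_pct = round(r$total_motility_pct, 1),
               progressive_motility_pct =
                 round(r$progressive_motility_pct, 1),
               total_concentration = signif(r$total_concentration, 3),
               motile_concentration = signif(r$motile_concentration, 3),
               qc_flags = paste(r$qc_flags, collapse = ";"))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$sample_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}

# ---- CSV layouts ---------------------------------------------------------

#' Read/write detections, tracks and kinematics CSV files
#'
#' Plain CSV with documented headers; coordinates in um, frames 0-based.
#' Detections: `frame,x_um,y_um,area_um2,intensity`.  Tracks add
#' `track_id` (and `field` when written from [analyze()]).  Kinematics:
#' `track_id,n_frames,duration_s,vcl,vap,vsl,max_excursion_um,`
#' `head_diameter_um,motility_class`.
#'
#' @param detections,tracks,kinematics data.frames in the package layouts.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @name casa_csv
NULL

#' @rdname casa_csv
#' @export
write_detections_csv <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname casa_csv
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stopf("detections CSV must have columns: %s",
          paste(need, collapse = ", "))
  if (is.null(d$area_um2)) d$area_um2 <- NA_real_
  if (is.null(d$intensity)) d$intensity <- NA_real_
  d
}

#' @rdname casa_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname casa_csv
#' @export
read_tracks_csv <- function(path) {
  d <- read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stopf("tracks CSV must have columns: %s", paste(need, collapse = ", "))
  d
}

#' @rdname casa_csv
#' @export
write_kinematics_csv <- function(kinematics, path) {
  write.csv(kinematics, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as CSV files
#'
#' Writes `<prefix>_cells.csv` (per-track metadata) and
#' `<prefix>_positions.csv` (frame-by-frame um coordinates).
#'
#' @param truth a [simulate_tracks()] result.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_truth_csv <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  p1 <- paste0(prefix, "_cells.csv")
  p2 <- paste0(prefix, "_positions.csv")
  write.csv(truth$cells, p1, row.names = FALSE)
  write.csv(truth$positions, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
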