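#' CASA analysis settings
#'
#' Builds the full analysis configuration used by every pipeline stage.
#' Defaults reproduce a coral-sperm protocol on a 60 Hz darkfield capture of
#' a 20 um-deep counting chamber: 0.75 s captures, a 5--150 um^2 head-area
#' gate, a maximum inter-frame travel ("Cell Travel Max") of 10 um (lowerable
#' to 5 um when bright static artefacts litter the field), a static rule of
#' 0.8 x head diameter, and 20 / 80 um/s slow/motile/progressive velocity
#' bins.
#'
#' `static_tail_filter` is permanently `FALSE`: segmenting tails (instead of
#' heads only) makes tail-less static cells invisible, which underestimates
#' concentration and overestimates motility.  Attempting `TRUE` is an error.
#'
#' @param frame_rate_hz capture frame rate, Hz.
#' @param capture_duration_s capture length, s.
#' @param microns_per_pixel spatial calibration, um/px.
#' @param min_head_area_um2,max_head_area_um2 head-area gate, um^2.
#' @param cell_travel_max_um maximum inter-frame displacement still linked as
#'   the same cell, um.  A step exactly equal to the bound links (closed
#'   bound), so the last unsplit speed is `cell_travel_max_um * frame_rate_hz`.
#' @param static_width_multiplier a track is static if it never leaves a
#'   radius of this multiple of its head diameter around its first position.
#' @param slow_bound_um_s,progressive_bound_um_s velocity bin edges, um/s:
#'   below `slow_bound` is slow; above `progressive_bound` is progressive;
#'   both edges inclusive to motile.
#' @param classification_velocity which velocity the bins apply to:
#'   `"vap"` (default), `"vcl"` or `"vsl"`.
#' @param smoothing_frames odd moving-average window for the average path
#'   (VAP), frames.
#' @param min_track_frames tracks shorter than this are excluded from
#'   motility percentages (still counted for concentration).
#' @param chamber_depth_um counting-chamber depth, um.
#' @param field_width_um,field_height_um imaged field size, um (used when the
#'   input is a detections table; for image stacks the frame size wins).
#' @param min_fields,min_cells capture sufficiency thresholds (flags below
#'   5 fields / 200 cells by default).
#' @param working_range,ideal_range instrument concentration ranges,
#'   cells/mL (length-2 numeric).
#' @param drift_threshold_um_s uniform-flow flag threshold, um/s.
#' @param stale_well_max_s maximum delay between well loading and capture
#'   before the stale-well flag, s.
#' @param species_max_vcl_um_s fastest VCL expected for the species profile;
#'   used by [split_risk_report()].
#' @param static_tail_filter must be `FALSE` (see Details).
#' @param fixed_threshold optional fixed segmentation threshold (intensity
#'   units); `NA` selects an Otsu threshold per frame.
#' @param mask_percentile global-intensity percentile above which an
#'   always-bright pixel is treated as a static bloom artefact.
#' @param dilution sample dilution factor applied to concentrations.
#' @param seed optional integer seed recorded with the settings.
#'
#' @return an object of class `casa_settings` (a validated named list).
#' @examples
#' s <- casa_settings(cell_travel_max_um = 5)
#' split_risk_report(s)$max_trackable_vcl_um_s  # 300 um/s
#' @export
casa_settings <- function(frame_rate_hz = 60,
                          capture_duration_s = 0.75,
                          microns_per_pixel = 1.0,
                          min_head_area_um2 = 5,
                          max_head_area_um2 = 150,
                          cell_travel_max_um = 10,
                          static_width_multiplier = 0.8,
                          slow_bound_um_s = 20,
                          progressive_bound_um_s = 80,
                          classification_velocity = c("vap", "vcl", "vsl"),
                          smoothing_frames = 5,
                          min_track_frames = 30,
                          chamber_depth_um = 20,
                          field_width_um = 640,
                          field_height_um = 480,
                          min_fields = 5,
                          min_cells = 200,
                          working_range = c(8e6, 5e7),
                          ideal_range = c(1e7, 3e7),
                          drift_threshold_um_s = 10,
                          stale_well_max_s = 120,
                          species_max_vcl_um_s = 300,
                          static_tail_filter = FALSE,
                          fixed_threshold = NA_real_,
                          mask_percentile = 0.9999,
                          dilution = 1,
                          seed = NA_integer_) {
  classification_velocity <- match.arg(classification_velocity)
  s <- list(
    frame_rate_hz = frame_rate_hz,
    capture_duration_s = capture_duration_s,
    microns_per_pixel = microns_per_pixel,
    min_head_area_um2 = min_head_area_um2,
    max_head_area_um2 = max_head_area_um2,
    cell_travel_max_um = cell_travel_max_um,
    static_width_multiplier = static_width_multiplier,
    slow_bound_um_s = slow_bound_um_s,
    progressive_bound_um_s = progressive_bound_um_s,
    classification_velocity = classification_velocity,
    smoothing_frames = as.integer(smoothing_frames),
    min_track_frames = as.integer(min_track_frames),
    chamber_depth_um = chamber_depth_um,
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    min_fields = as.integer(min_fields),
    min_cells = as.integer(min_cells),
    working_range = as.numeric(working_range),
    ideal_range = as.numeric(ideal_range),
    drift_threshold_um_s = drift_threshold_um_s,
    stale_well_max_s = stale_well_max_s,
    species_max_vcl_um_s = species_max_vcl_um_s,
    static_tail_filter = static_tail_filter,
    fixed_threshold = as.numeric(fixed_threshold),
    mask_percentile = mask_percentile,
    dilution = dilution,
    seed = suppressWarnings(as.integer(seed))
  )
  class(s) <- "casa_settings"
  validate_settings(s)
}

validate_settings <- function(s) {
  pos <- c("frame_rate_hz", "capture_duration_s", "microns_per_pixel",
           "min_head_area_um2", "max_head_area_um2", "cell_travel_max_um",
           "static_width_multiplier", "slow_bound_um_s",
           "progressive_bound_um_s", "chamber_depth_um", "field_width_um",
           "field_height_um", "species_max_vcl_um_s", "dilution")
  for (f in pos) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stopf("setting '%s' must be a single positive number", f)
  }
  if (s$min_head_area_um2 >= s$max_head_area_um2)
    stopf("min_head_area_um2 must be below max_head_area_um2")
  if (s$slow_bound_um_s >= s$progressive_bound_um_s)
    stopf("slow_bound_um_s must be below progressive_bound_um_s")
  if (s$smoothing_frames < 1 || s$smoothing_frames %% 2 == 0)
    stopf("smoothing_frames must be a positive odd integer")
  if (s$min_track_frames < 2)
    stopf("min_track_frames must be at least 2")
  for (f in c("working_range", "ideal_range")) {
    v <- s[[f]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] <= 0 || v[1] >= v[2])
      stopf("setting '%s' must be an increasing positive length-2 range", f)
  }
  if (!identical(s$static_tail_filter, FALSE))
    stopf(paste("static_tail_filter must be FALSE: with tail segmentation",
                "enabled, tail-less static heads are never counted, which",
                "underestimates concentration and overestimates motility"))
  if (s$mask_percentile <= 0 || s$mask_percentile >= 1)
    stopf("mask_percentile must be in (0, 1)")
  if (s$drift_threshold_um_s < 0 || s$stale_well_max_s < 0 ||
      s$min_fields < 1 || s$min_cells < 1)
    stopf("thresholds must be non-negative (min_fields/min_cells >= 1)")
  s
}

#' @export
print.casa_settings <- function(x, ...) {
  cat("CASA settings (units: um, s, Hz, cells/mL; frames 0-based)\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-26s %s\n", f, paste(format(v, trim = TRUE),
                                         collapse = ",")))
  }
  invisible(x)
}

#' Number of frames in a capture
#' @param settings a [casa_settings()] object.
#' @return integer, `round(capture_duration_s * frame_rate_hz)`.
#' @export
n_capture_frames <- function(settings) {
  as.integer(round(settings$capture_duration_s * settings$frame_rate_hz))
}

#' Read settings from a plain-text configuration file
#'
#' The file holds one `key = value` pair per line (`#` comments and blank
#' lines ignored); length-2 ranges are comma-separated.  Keys mirror the
#' argument names of [casa_settings()].  Missing keys take the defaults;
#' `overrides` (a named list, e.g. from command-line flags) win over the
#' file.  Settings -> file -> settings is an identity.
#'
#' @param path configuration file path, or `NULL` for defaults-plus-overrides.
#' @param overrides named list of settings overriding the file.
#' @return a validated [casa_settings()] object.
#' @export
load_settings <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("settings file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) stopf("cannot parse settings line: '%s'", ln)
      vals[[m[2]]] <- m[3]
    }
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(casa_settings))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown settings key(s): %s",
                         paste(bad, collapse = ", "))
  args <- lapply(names(vals), function(k) coerce_setting(k, vals[[k]]))
  names(args) <- names(vals)
  do.call(casa_settings, args)
}

coerce_setting <- function(key, value) {
  if (!is.character(value)) return(value)  # already typed override
  value <- trimws(value)
  if (key == "classification_velocity") return(value)
  if (key == "static_tail_filter")
    return(toupper(value) %in% c("TRUE", "T", "1", "YES"))
  parts <- strsplit(value, ",")[[1]]
  out <- suppressWarnings(as.numeric(trimws(parts)))
  if (anyNA(out) && !identical(toupper(value), "NA"))
    stopf("setting '%s': cannot parse numeric value '%s'", key, value)
  out
}

#' Write settings to a plain-text configuration file
#'
#' @param settings a [casa_settings()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_settings <- function(settings, path) {
  stopifnot(inherits(settings, "casa_settings"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
               collapse = ",")
  }
  lines <- c("# coralcasa settings (um, s, Hz, cells/mL; frames 0-based)",
             vapply(names(settings),
                    function(f) sprintf("%s = %s", f, fmt(settings[[f]])),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}
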