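#' Capture sufficiency flags
#'
#' A capture should comprise at least five fields and at least 200 measured
#' cells before motility percentages are trusted (boundary inclusive).
#'
#' @param n_fields fields captured.
#' @param n_cells cells measured.
#' @param settings a [casa_settings()] (thresholds `min_fields`,
#'   `min_cells`).
#' @return character vector of flags (possibly empty): any of
#'   `"insufficient_fields"`, `"insufficient_cells"`.
#' @export
check_capture <- function(n_fields, n_cells, settings = casa_settings()) {
  if (n_fields < 0 || n_cells < 0) stopf("counts must be non-negative")
  flags <- character(0)
  if (n_fields < settings$min_fields) flags <- c(flags, "insufficient_fields")
  if (n_cells < settings$min_cells) flags <- c(flags, "insufficient_cells")
  flags
}

#' Concentration working-range flags
#'
#' The instrument reads reliably at roughly 8e6--5e7 cells/mL and ideally
#' 1e7--3e7 cells/mL.  Outside the working range the stronger
#' below/above flag is raised; `outside_ideal_range` is raised only for
#' samples inside the working range but outside the ideal band.
#'
#' @param concentration cells/mL (>= 0).
#' @param settings a [casa_settings()] (`working_range`, `ideal_range`).
#' @return character vector of flags (possibly empty).
#' @export
check_working_range <- function(concentration,
                                settings = casa_settings()) {
  if (is.na(concentration)) return(character(0))
  if (concentration < 0) stopf("concentration must be >= 0")
  w <- settings$working_range; i <- settings$ideal_range
  if (concentration < w[1]) return("below_working_range")
  if (concentration > w[2]) return("above_working_range")
  if (concentration < i[1] || concentration > i[2])
    return("outside_ideal_range")
  character(0)
}

#' Detect uniform flow (bulk drift) in a set of tracks
#'
#' Improper removal of excess fluid before capture leaves the whole sample
#' drifting, which inflates apparent motility.  The drift estimate is the
#' component-wise median of all per-step displacement vectors (median, not
#' mean, so the genuinely motile subpopulation cannot dominate) scaled by
#' the frame rate.  The flag is raised when the drift magnitude exceeds
#' `settings$drift_threshold_um_s` (default 10 um/s, half the slow/motile
#' bound) and at least 5 tracks are available; with fewer tracks only
#' diagnostics are returned.
#'
#' @param tracks tidy tracks from [link_detections()].
#' @param settings a [casa_settings()].
#' @return list of class `drift_report`: `drift_um_s` (length-2),
#'   `magnitude_um_s`, `n_tracks`, `n_steps`, `flag` (logical).
#' @export
detect_uniform_flow <- function(tracks, settings = casa_settings()) {
  steps <- matrix(numeric(0), ncol = 2)
  n_tracks <- 0L
  if (nrow(tracks) > 0) {
    pieces <- split(tracks[, c("x_um", "y_um")], tracks$track_id)
    n_tracks <- length(pieces)
    steps <- do.call(rbind, lapply(pieces, function(p)
      if (nrow(p) >= 2) diff(as.matrix(p)) else NULL))
    if (is.null(steps)) steps <- matrix(numeric(0), ncol = 2)
  }
  if (nrow(steps) == 0) {
    return(structure(list(drift_um_s = c(NA_real_, NA_real_),
                          magnitude_um_s = NA_real_, n_tracks = n_tracks,
                          n_steps = 0L, flag = FALSE),
                     class = "drift_report"))
  }
  drift <- c(median(steps[, 1]), median(steps[, 2])) * settings$frame_rate_hz
  mag <- sqrt(sum(drift^2))
  structure(list(drift_um_s = drift, magnitude_um_s = mag,
                 n_tracks = n_tracks, n_steps = nrow(steps),
                 flag = n_tracks >= 5 && mag > settings$drift_threshold_um_s),
            class = "drift_report")
}

#' Stale-well check
#'
#' Cells migrate toward the well edges over time, so delayed capture after
#' loading under-estimates concentration.  Flags captures acquired more
#' than `settings$stale_well_max_s` (default 120 s) after loading.
#'
#' @param load_time,capture_time POSIXct (or numeric seconds) timestamps;
#'   `NA` gives an `"unknown"` diagnostic and no flag.
#' @param settings a [casa_settings()].
#' @return list of class `staleness_report`: `elapsed_s` (`NA` when
#'   unknown), `status` (`"ok"`, `"stale_well"`, `"unknown"`), `flag`.
#' @export
check_staleness <- function(load_time, capture_time,
                            settings = casa_settings()) {
  if (is.null(load_time) || is.null(capture_time) ||
      is.na(load_time) || is.na(capture_time)) {
    return(structure(list(elapsed_s = NA_real_, status = "unknown",
                          flag = FALSE), class = "staleness_report"))
  }
  elapsed <- if (inherits(capture_time, "POSIXt"))
    as.numeric(difftime(capture_time, load_time, units = "secs"))
  else as.numeric(capture_time) - as.numeric(load_time)
  if (elapsed < 0) stopf("capture_time precedes load_time")
  stale <- elapsed > settings$stale_well_max_s
  structure(list(elapsed_s = elapsed,
                 status = if (stale) "stale_well" else "ok",
                 flag = stale), class = "staleness_report")
}

#' Assemble a QC report
#'
#' Combines capture sufficiency, working range, drift and staleness checks
#' into one flag set with its diagnostics.
#'
#' @param n_fields,n_cells capture counts.
#' @param concentration total concentration, cells/mL (or `NA`).
#' @param tracks tidy tracks (for drift detection), or `NULL`.
#' @param load_time,capture_time timestamps (or `NA`).
#' @param settings a [casa_settings()].
#' @return list of class `qc_report`: `flags` (character) and
#'   `diagnostics` (drift vector um/s, elapsed s, max trackable VCL um/s).
#' @export
qc_report <- function(n_fields, n_cells, concentration = NA_real_,
                      tracks = NULL, load_time = NA, capture_time = NA,
                      settings = casa_settings()) {
  flags <- check_capture(n_fields, n_cells, settings)
  flags <- c(flags, check_working_range(concentration, settings))
  drift <- if (is.null(tracks))
    structure(list(drift_um_s = c(NA_real_, NA_real_),
                   magnitude_um_s = NA_real_, n_tracks = 0L, n_steps = 0L,
                   flag = FALSE), class = "drift_report")
  else detect_uniform_flow(tracks, settings)
  if (drift$flag) flags <- c(flags, "uniform_flow_detected")
  stale <- check_staleness(load_time, capture_time, settings)
  if (stale$flag) flags <- c(flags, "stale_well")
  split <- split_risk_report(settings)
  if (split$split_risk) flags <- c(flags, "split_risk")
  structure(list(flags = sort(unique(flags)),
                 diagnostics = list(
                   drift_um_s = drift$drift_um_s,
                   drift_magnitude_um_s = drift$magnitude_um_s,
                   elapsed_since_load_s = stale$elapsed_s,
                   staleness = stale$status,
                   max_trackable_vcl_um_s = split$max_trackable_vcl_um_s)),
            class = "qc_report")
}
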