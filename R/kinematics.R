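#' Per-track kinematic metrics
#'
#' Computes the three standard CASA velocities for one track:
#' \describe{
#'   \item{VCL}{curvilinear velocity -- raw point-to-point path length
#'     divided by track duration.}
#'   \item{VAP}{average-path velocity -- path length of the trajectory
#'     smoothed with a centred moving average (window
#'     `settings$smoothing_frames`, odd; endpoints preserved by window
#'     shrinkage) divided by duration.}
#'   \item{VSL}{straight-line velocity -- net first-to-last displacement
#'     divided by duration.}
#' }
#' Endpoint-preserving smoothing guarantees `VSL <= VAP <= VCL` up to
#' 1e-9 um/s.  Also reports the maximum excursion (largest distance from
#' the first position), which drives the static rule.
#'
#' @param track data.frame with consecutive `frame` values and `x_um`,
#'   `y_um` (at least 2 frames).
#' @param settings a [casa_settings()].
#' @return list of class `track_kinematics`: `n_frames`, `duration_s`,
#'   `vcl`, `vap`, `vsl` (um/s), `max_excursion_um`.
#' @export
compute_kinematics <- function(track, settings = casa_settings()) {
  n <- nrow(track)
  if (n < 2) stopf("kinematics needs at least 2 frames (got %d)", n)
  if (any(diff(track$frame) != 1))
    stopf("track frames must be strictly consecutive")
  xy <- cbind(track$x_um, track$y_um)
  duration <- (n - 1) / settings$frame_rate_hz
  path_len <- function(p) sum(row_norm(diff(p)))
  sm <- smooth_path(xy, settings$smoothing_frames)
  structure(list(
    n_frames = n,
    duration_s = duration,
    vcl = path_len(xy) / duration,
    vap = path_len(sm) / duration,
    vsl = sqrt(sum((xy[n, ] - xy[1, ])^2)) / duration,
    max_excursion_um = max(row_norm(sweep(xy, 2, xy[1, ])))),
    class = "track_kinematics")
}

# centred moving average with symmetric window shrinkage at the ends, so
# the first and last points are unchanged
smooth_path <- function(xy, window) {
  n <- nrow(xy)
  h <- (window - 1) %/% 2
  if (h == 0 || n < 3) return(xy)
  out <- xy
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    if (hi > 0)
      out[i, ] <- colMeans(xy[(i - hi):(i + hi), , drop = FALSE])
  }
  out
}

#' Assign a motility class to a track
#'
#' A track is `static` when its maximum excursion from its first position
#' stays below `static_width_multiplier x head diameter` (default 0.8) for
#' the whole capture.  Non-static tracks are binned on the classification
#' velocity (VAP by default): below 20 um/s is `slow`, 20--80 um/s
#' inclusive is `motile`, above 80 um/s is `progressive` (bounds
#' configurable per species).
#'
#' @param kin a [compute_kinematics()] result.
#' @param head_diameter_um circular-equivalent head diameter of the track's
#'   cell, um.
#' @param settings a [casa_settings()].
#' @return one of `"static"`, `"slow"`, `"motile"`, `"progressive"`.
#' @export
classify_track <- function(kin, head_diameter_um,
                           settings = casa_settings()) {
  if (head_diameter_um <= 0) stopf("head diameter must be positive")
  if (kin$max_excursion_um <
      settings$static_width_multiplier * head_diameter_um)
    return("static")
  v <- kin[[settings$classification_velocity]]
  if (v < settings$slow_bound_um_s) "slow"
  else if (v <= settings$progressive_bound_um_s) "motile"
  else "progressive"
}

#' Kinematics and classification for all tracks
#'
#' Computes [compute_kinematics()] and [classify_track()] for every track
#' long enough to qualify for motility statistics
#' (`settings$min_track_frames`, default 30 of a 45-frame capture: tracks
#' covering less than about two thirds of the capture are excluded from
#' percentages but still count toward concentration).
#'
#' @param tracks tidy tracks from [link_detections()] (needs `area_um2` for
#'   the head-diameter rule; tracks lacking it get the mid-gate area).
#' @param settings a [casa_settings()].
#' @param min_frames minimum track length in frames; defaults to
#'   `settings$min_track_frames`.
#' @return data.frame: `track_id`, `n_frames`, `duration_s`, `vcl`, `vap`,
#'   `vsl`, `max_excursion_um`, `head_diameter_um`, `motility_class`.
#' @export
track_kinematics <- function(tracks, settings = casa_settings(),
                             min_frames = settings$min_track_frames) {
  if (nrow(tracks) == 0 || is.null(tracks$track_id))
    return(data.frame(track_id = integer(0), n_frames = integer(0),
                      duration_s = numeric(0), vcl = numeric(0),
                      vap = numeric(0), vsl = numeric(0),
                      max_excursion_um = numeric(0),
                      head_diameter_um = numeric(0),
                      motility_class = character(0)))
  min_frames <- max(2L, as.integer(min_frames))
  pieces <- split(tracks, tracks$track_id)
  rows <- lapply(pieces, function(tr) {
    if (nrow(tr) < min_frames) return(NULL)
    kin <- compute_kinematics(tr, settings)
    area <- if (!is.null(tr$area_um2) && all(is.finite(tr$area_um2)))
      mean(tr$area_um2)
    else (settings$min_head_area_um2 + settings$max_head_area_um2) / 2
    hd <- head_diameter(area)
    data.frame(track_id = tr$track_id[1], n_frames = kin$n_frames,
               duration_s = kin$duration_s, vcl = kin$vcl, vap = kin$vap,
               vsl = kin$vsl, max_excursion_um = kin$max_excursion_um,
               head_diameter_um = hd,
               motility_class = classify_track(kin, hd, settings))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- track_kinematics(tracks[0, ], settings)
  else out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
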