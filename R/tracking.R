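#' Link detections across frames into tracks
#'
#' For each consecutive frame pair, computes the minimum-total-distance
#' one-to-one assignment among detection pairs whose displacement is within
#' `cell_travel_max` (the maximum distance a cell may travel between frames
#' and still be considered the same cell).  Assigned detections extend
#' tracks; unassigned detections open new tracks.  The bound is closed: a
#' step exactly equal to `cell_travel_max` links, so at 60 Hz and a 5 um
#' bound the last unsplit speed is 300 um/s -- faster swimmers are split
#' into multiple tracks, the documented failure mode an operator must check
#' for.  There is no gap closing: a missed frame always starts a new track.
#'
#' The assignment is solved exactly (Hungarian algorithm on a padded square
#' matrix with dummy rows/columns), so linking is deterministic and can be
#' checked against exhaustive enumeration.
#'
#' @param detections data.frame with `frame` (0-based), `x_um`, `y_um` and
#'   optionally `area_um2`, `intensity`.
#' @param cell_travel_max_um maximum inter-frame displacement, um.
#' @return tracks data.frame: `track_id`, `frame`, `x_um`, `y_um` plus any
#'   carried columns, ordered by track then frame.  Track ids number tracks
#'   in order of first appearance.
#' @examples
#' d <- data.frame(frame = 0:2, x_um = c(0, 5, 10), y_um = 0)
#' link_detections(d, cell_travel_max_um = 5)   # one track
#' link_detections(d, cell_travel_max_um = 4.9) # three tracks
#' @export
link_detections <- function(detections, cell_travel_max_um) {
  if (cell_travel_max_um <= 0) stopf("cell_travel_max_um must be positive")
  d <- as.data.frame(detections)
  if (nrow(d) == 0) {
    out <- cbind(data.frame(track_id = integer(0)), d)
    return(out)
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(d)))
  d <- d[order(d$frame), , drop = FALSE]
  rownames(d) <- NULL
  frames <- sort(unique(d$frame))
  rows_by_frame <- split(seq_len(nrow(d)), factor(d$frame, levels = frames))

  track_of <- integer(nrow(d))
  next_id <- 0L
  open_track <- function(rows) {
    for (r in rows) { next_id <<- next_id + 1L; track_of[r] <<- next_id }
  }
  open_track(rows_by_frame[[1]])

  for (k in seq_len(length(frames) - 1)) {
    nxt <- rows_by_frame[[k + 1]]
    if (frames[k + 1] != frames[k] + 1) { open_track(nxt); next }
    prev <- rows_by_frame[[k]]
    match_j <- match_frame_pair(d$x_um[prev], d$y_um[prev],
                                d$x_um[nxt], d$y_um[nxt],
                                cell_travel_max_um)
    linked <- !is.na(match_j)
    track_of[nxt[match_j[linked]]] <- track_of[prev[linked]]
    open_track(nxt[setdiff(seq_along(nxt), match_j[linked])])
  }

  # renumber by first appearance so ids are stable and gap-free
  remap <- match(track_of, unique(track_of))
  out <- cbind(data.frame(track_id = remap), d)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# optimal gated assignment between two frames; returns, for each detection
# in the previous frame, the index of its match in the next frame (NA if
# unmatched)
match_frame_pair <- function(x1, y1, x2, y2, bound) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  dist <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  # closed bound with a relative epsilon so a step of exactly `bound`
  # links regardless of floating-point representation
  bound <- bound * (1 + 1e-9)
  allowed <- dist <= bound
  if (!any(allowed)) return(rep(NA_integer_, n1))
  n <- n1 + n2
  pen <- bound * n + 1          # cost of leaving a detection unmatched
  forbid <- pen * n * 10 + 1e6  # never chosen when avoidable
  cost <- matrix(forbid, n, n)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(allowed, dist, forbid)
  for (i in seq_len(n1)) cost[i, n2 + i] <- pen       # row dummy
  for (j in seq_len(n2)) cost[n1 + j, j] <- pen       # column dummy
  cost[(n1 + 1):n, (n2 + 1):n] <- 0
  a <- solve_assignment_cpp(cost)
  match_j <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- a[i]
    if (j <= n2 && dist[i, j] <= bound) match_j[i] <- j
  }
  match_j
}

#' Maximum trackable velocity under the current linking bound
#'
#' The linker cannot follow a cell moving more than `cell_travel_max` per
#' frame, so the maximum trackable curvilinear velocity is
#' `cell_travel_max x frame rate` (e.g. 5 um x 60 Hz = 300 um/s).  Faster
#' genuine paths are falsely split; the report warns when the bound falls
#' below the fastest VCL expected for the species profile.
#'
#' @param settings a [casa_settings()].
#' @return list of class `split_risk_report`: `cell_travel_max_um`,
#'   `frame_rate_hz`, `max_trackable_vcl_um_s`, `species_max_vcl_um_s`,
#'   `split_risk` (logical).
#' @export
split_risk_report <- function(settings = casa_settings()) {
  stopifnot(inherits(settings, "casa_settings"))
  vmax <- settings$cell_travel_max_um * settings$frame_rate_hz
  structure(list(cell_travel_max_um = settings$cell_travel_max_um,
                 frame_rate_hz = settings$frame_rate_hz,
                 max_trackable_vcl_um_s = vmax,
                 species_max_vcl_um_s = settings$species_max_vcl_um_s,
                 split_risk = vmax < settings$species_max_vcl_um_s),
            class = "split_risk_report")
}

#' @export
print.split_risk_report <- function(x, ...) {
  cat(sprintf(
    "max trackable VCL: %g um/s (Cell Travel Max %g um x %g Hz)\n",
    x$max_trackable_vcl_um_s, x$cell_travel_max_um, x$frame_rate_hz))
  if (x$split_risk)
    cat(sprintf(paste0(
      "WARNING: below the %g um/s expected for this species profile --\n",
      "genuine fast paths will be split; check analysed videos.\n"),
      x$species_max_vcl_um_s))
  invisible(x)
}
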