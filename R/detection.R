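#' Circular-equivalent head diameter
#'
#' The static-classification rule is expressed in head diameters; detections
#' carry areas, so the diameter of the circle of equal area is used:
#' `2 * sqrt(area / pi)`.
#'
#' @param area_um2 head area(s), um^2 (positive).
#' @return diameter(s), um.
#' @examples
#' head_diameter(pi)     # 2
#' head_diameter(78.54)  # ~10
#' @export
head_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stopf("head area must be positive")
  2 * sqrt(area_um2 / pi)
}

#' Otsu threshold of an intensity matrix
#'
#' Maximises between-class variance over a 256-bin histogram of the frame's
#' dynamic range.  Returns the intensity value separating background from
#' foreground (foreground is strictly above the threshold).
#'
#' @param frame numeric matrix.
#' @return scalar threshold, or `NA` if the frame has zero dynamic range.
#' @export
otsu_threshold <- function(frame) {
  rng <- range(frame)
  if (diff(rng) == 0) return(NA_real_)
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1)
  h <- tabulate(pmin(pmax(findInterval(frame, br, all.inside = TRUE), 1L),
                     nb), nbins = nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nb])
  br[k + 1]
}

#' Segment candidate sperm heads in one frame
#'
#' Thresholds the frame (Otsu by default, or a fixed threshold), labels
#' 8-connected bright components, discards components outside the head-area
#' gate (5--150 um^2 by default) or overlapping the artefact mask, and
#' returns intensity-weighted centroids in um.
#'
#' A blank frame (zero dynamic range) yields an empty result carrying a
#' `"blank_frame"` warning attribute rather than an error.
#'
#' @param frame numeric intensity matrix.
#' @param settings a [casa_settings()]; `microns_per_pixel`, the area gate
#'   and `fixed_threshold` are used.
#' @param mask optional logical matrix (TRUE = artefact pixel) of the same
#'   shape as `frame`.
#' @param frame_index 0-based frame index stored in the result.
#' @return detections data.frame: `frame`, `x_um`, `y_um`, `area_um2`,
#'   `intensity` (mean component intensity).
#' @export
segment_frame <- function(frame, settings = casa_settings(), mask = NULL,
                          frame_index = 0L) {
  stopifnot(is.matrix(frame))
  if (!is.null(mask) && !identical(dim(mask), dim(frame)))
    stopf("mask shape %s does not match frame shape %s",
          paste(dim(mask), collapse = "x"),
          paste(dim(frame), collapse = "x"))
  thr <- if (is.finite(settings$fixed_threshold)) settings$fixed_threshold
         else otsu_threshold(frame)
  if (is.na(thr)) {
    out <- empty_detections()
    attr(out, "warning") <- "blank_frame"
    return(out)
  }
  lab <- label_components_cpp(frame > thr)
  idx <- which(lab > 0)
  if (length(idx) == 0) return(empty_detections())
  li <- lab[idx]
  nr <- nrow(frame)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  w <- frame[idx]
  grp <- factor(li, levels = sort(unique(li)))
  sw <- rowsum(w, grp)[, 1]
  sx <- rowsum(w * cols, grp)[, 1]
  sy <- rowsum(w * rows, grp)[, 1]
  npx <- rowsum(rep(1, length(idx)), grp)[, 1]
  mpp <- settings$microns_per_pixel
  area <- npx * mpp^2
  hit_mask <- if (is.null(mask)) rep(FALSE, length(sw))
              else rowsum(as.numeric(mask[idx]), grp)[, 1] > 0
  keep <- area >= settings$min_head_area_um2 &
          area <= settings$max_head_area_um2 & !hit_mask
  data.frame(frame = rep(as.integer(frame_index), sum(keep)),
             x_um = (sx[keep] / sw[keep] - 0.5) * mpp,
             y_um = (sy[keep] / sw[keep] - 0.5) * mpp,
             area_um2 = area[keep],
             intensity = sw[keep] / npx[keep],
             row.names = NULL)
}

#' Segment every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param settings a [casa_settings()].
#' @param mask optional artefact mask (see [build_artifact_mask()]).
#' @return detections data.frame over all frames (0-based `frame` column);
#'   a `"blank_frames"` attribute lists any zero-range frames.
#' @export
segment_stack <- function(stack, settings = casa_settings(), mask = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  s <- settings
  s$microns_per_pixel <- stack$microns_per_pixel
  blank <- integer(0)
  out <- lapply(seq_along(stack$frames), function(i) {
    d <- segment_frame(stack$frames[[i]], s, mask, frame_index = i - 1L)
    if (identical(attr(d, "warning"), "blank_frame"))
      blank <<- c(blank, i - 1L)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(blank)) attr(res, "blank_frames") <- blank
  res
}

#' Build a static-artefact (bloom) mask
#'
#' Dust and salt on chamber cassettes produce bright static blooms that seed
#' false tracks.  A pixel is masked when its temporal minimum intensity --
#' i.e. it is bright in every frame -- reaches a high percentile
#' (`settings$mask_percentile`, default 0.9999) of the global intensity
#' distribution; the mask is then dilated by one maximum head diameter so
#' bloom fringes are covered.  Saturated blooms sit at the very top of the
#' intensity distribution in every frame, while even the slowest swimming
#' cell drops below its own peak at some point of the capture, so cells
#' survive.  Static dirt dimmer than the brightest cells is not caught;
#' see the vignette for limitations.
#'
#' @param stack a [frame_stack()] with at least 5 frames.
#' @param settings a [casa_settings()].
#' @return logical matrix (TRUE = masked), possibly all-FALSE.
#' @export
build_artifact_mask <- function(stack, settings = casa_settings()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) < 5)
    stopf("artefact mask needs at least 5 frames")
  minproj <- Reduce(pmin, stack$frames)
  v <- unlist(stack$frames, use.names = FALSE)
  if (diff(range(v)) == 0)  # flat stack: nothing can be called an artefact
    return(matrix(FALSE, nrow(minproj), ncol(minproj)))
  if (length(v) > 4e6) v <- v[seq(1, length(v), length.out = 4e6)]
  q <- quantile(v, settings$mask_percentile, names = FALSE)
  mask <- minproj >= q
  if (!any(mask)) return(mask)
  r_px <- ceiling(head_diameter(settings$max_head_area_um2) /
                  stack$microns_per_pixel)
  dilate_mask(mask, r_px)
}

# binary dilation with a disc structuring element of radius r (pixels)
dilate_mask <- function(mask, r) {
  idx <- which(mask)
  if (length(idx) == 0 || r < 1) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  out <- mask
  for (dc in -r:r) {
    span <- floor(sqrt(r^2 - dc^2))
    for (dr in -span:span) {
      rr <- rows + dr; cc <- cols + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  out
}
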