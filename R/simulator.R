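#' Motility mixture specification
#'
#' Describes the population a synthetic capture should contain: the fraction
#' of cells in each motility class, per-class swimming speed ranges, heading
#' persistence, positional jitter of static cells, cell concentration,
#' optional uniform drift (a chamber-loading artefact) and static bloom
#' artefacts.
#'
#' Default speed ranges sit at least 5 um/s inside the classification bins
#' (slow < 20, motile 20--80, progressive > 80 um/s) so a cell's intended
#' class and its classified class coincide; they are placeholders, not
#' species measurements, and should be tuned per species.
#'
#' @param fraction_static,fraction_slow,fraction_motile,fraction_progressive
#'   class fractions in `[0, 1]`, summing to 1 (tolerance 1e-9).
#' @param speed_ranges named list of length-2 um/s ranges for `slow`,
#'   `motile` and `progressive`; each must lie inside its class bin
#'   (slow in `[0, 20)`, motile in `[20, 80]`, progressive in `(80, Inf)`).
#' @param directional_persistence named unitless values in `[0, 1]` per
#'   swimming class; 1 is a straight path.  Heading increments are Gaussian
#'   with sd `2 * (1 - persistence)` radians per frame.
#' @param static_jitter_sd Brownian jitter sd of static cells, um per frame.
#' @param head_area_range head-area range, um^2 (inside the detection gate).
#' @param concentration cells/mL; the instrument working regime is roughly
#'   8e6--5e7 cells/mL.
#' @param drift_velocity uniform drift, um/s, length-2 `(vx, vy)`.
#' @param bloom_count number of static saturated bloom artefacts.
#' @param seed integer seed for reproducibility.
#' @return an object of class `motility_mixture`.
#' @export
motility_mixture <- function(fraction_static = 0.25,
                             fraction_slow = 0.25,
                             fraction_motile = 0.25,
                             fraction_progressive = 0.25,
                             speed_ranges = list(slow = c(8, 18),
                                                 motile = c(25, 75),
                                                 progressive = c(85, 150)),
                             directional_persistence = c(slow = 0.85,
                                                         motile = 0.85,
                                                         progressive = 0.95),
                             static_jitter_sd = 0.3,
                             head_area_range = c(10, 25),
                             concentration = 2e7,
                             drift_velocity = c(0, 0),
                             bloom_count = 0,
                             seed = NA_integer_) {
  fr <- c(static = fraction_static, slow = fraction_slow,
          motile = fraction_motile, progressive = fraction_progressive)
  if (any(fr < 0) || any(fr > 1))
    stopf("class fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    stopf("class fractions must sum to 1 (got %.12f)", sum(fr))
  bins <- list(slow = c(0, 20), motile = c(20, 80), progressive = c(80, Inf))
  for (cl in names(bins)) {
    r <- speed_ranges[[cl]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stopf("speed_ranges$%s must be a non-decreasing length-2 range", cl)
    b <- bins[[cl]]
    ok <- switch(cl,
      slow = r[1] >= b[1] && r[2] < b[2],
      motile = r[1] >= b[1] && r[2] <= b[2],
      progressive = r[1] > b[1])
    if (!ok)
      stopf("speed_ranges$%s = [%g, %g] lies outside its class bin", cl,
            r[1], r[2])
  }
  for (cl in c("slow", "motile", "progressive")) {
    p <- directional_persistence[[cl]]
    if (is.null(p) || is.na(p) || p < 0 || p > 1)
      stopf("directional_persistence$%s must lie in [0, 1]", cl)
  }
  if (!is.numeric(concentration) || concentration <= 0)
    stopf("concentration must be positive (cells/mL)")
  if (static_jitter_sd < 0) stopf("static_jitter_sd must be >= 0")
  if (length(head_area_range) != 2 || head_area_range[1] <= 0 ||
      head_area_range[1] > head_area_range[2])
    stopf("head_area_range must be an increasing positive length-2 range")
  if (length(drift_velocity) != 2 || any(!is.finite(drift_velocity)))
    stopf("drift_velocity must be a finite length-2 vector (um/s)")
  if (bloom_count < 0 || bloom_count != round(bloom_count))
    stopf("bloom_count must be a non-negative integer")
  structure(list(fractions = fr,
                 speed_ranges = speed_ranges,
                 directional_persistence = directional_persistence,
                 static_jitter_sd = static_jitter_sd,
                 head_area_range = as.numeric(head_area_range),
                 concentration = concentration,
                 drift_velocity = as.numeric(drift_velocity),
                 bloom_count = as.integer(bloom_count),
                 seed = suppressWarnings(as.integer(seed))),
            class = "motility_mixture")
}

#' Field geometry of a chamber capture
#'
#' @param width_um,height_um imaged field size, um.
#' @param depth_um chamber depth, um (20 um for a standard fixed-depth
#'   counting cassette).
#' @return an object of class `field_geometry`.
#' @export
field_geometry <- function(width_um = 640, height_um = 480, depth_um = 20) {
  if (width_um <= 0 || height_um <= 0)
    stopf("field must have positive area")
  if (depth_um <= 0) stopf("chamber depth must be positive")
  structure(list(width_um = width_um, height_um = height_um,
                 depth_um = depth_um), class = "field_geometry")
}

#' Field volume in mL
#' @param geometry a [field_geometry()].
#' @return volume in mL (`width * height * depth * 1e-12`).
#' @export
field_volume_ml <- function(geometry) {
  geometry$width_um * geometry$height_um * geometry$depth_um * 1e-12
}

#' Simulate ground-truth sperm tracks
#'
#' Places cells as a homogeneous Poisson process at the mixture concentration
#' and moves each by its class motion model: static cells jitter around
#' their initial position (rejection-sampled to stay strictly inside 0.8 x
#' head diameter); slow and motile cells follow a persistent random walk at
#' a per-cell speed drawn from the class range; progressive cells swim
#' near-straight.  Uniform drift, if any, is added to all positions.
#'
#' Cells are spawned in a buffer region around the imaged field (margin =
#' maximum class speed x duration + drift displacement) so that cells enter
#' as well as leave and the in-field count at every frame stays Poisson with
#' mean `concentration x field volume`.  A truth track is a maximal run of
#' consecutive in-field frames; a cell that leaves the field ends its track
#' (re-entries start a new track id).
#'
#' @param mixture a [motility_mixture()].
#' @param geometry a [field_geometry()].
#' @param duration_s capture duration, s.
#' @param frame_rate_hz frame rate, Hz.
#' @return an object of class `ground_truth`: `cells` (one row per truth
#'   track: `track_id`, `cell_id`, `class`, `head_area_um2`, `speed_um_s`,
#'   `n_frames`), `positions` (`track_id`, `frame`, `x_um`, `y_um`; frames
#'   0-based, um, top-left origin), `blooms`, `geometry`, `frame_rate_hz`,
#'   `n_frames`, `mixture`.
#' @examples
#' mix <- motility_mixture(concentration = 5e6, seed = 1)
#' truth <- simulate_tracks(mix)
#' table(truth$cells$class)
#' @export
simulate_tracks <- function(mixture, geometry = field_geometry(),
                            duration_s = 0.75, frame_rate_hz = 60) {
  stopifnot(inherits(mixture, "motility_mixture"),
            inherits(geometry, "field_geometry"))
  if (duration_s <= 0) stopf("capture duration must be positive")
  if (frame_rate_hz <= 0) stopf("frame rate must be positive")
  n_frames <- as.integer(round(duration_s * frame_rate_hz))
  if (n_frames < 1) stopf("capture too short for one frame")

  with_seed(mixture$seed, {
    W <- geometry$width_um; H <- geometry$height_um
    vmax <- max(vapply(mixture$speed_ranges, max, numeric(1)))
    margin <- vmax * duration_s +
      sqrt(sum(mixture$drift_velocity^2)) * duration_s +
      5 * mixture$static_jitter_sd
    bw <- W + 2 * margin; bh <- H + 2 * margin
    lambda <- mixture$concentration * bw * bh * geometry$depth_um * 1e-12
    n_cells <- rpois(1, lambda)

    classes <- character(0); areas <- speeds <- numeric(0)
    pos_list <- list()
    if (n_cells > 0) {
      classes <- sample(names(mixture$fractions), n_cells, replace = TRUE,
                        prob = mixture$fractions)
      areas <- runif(n_cells, mixture$head_area_range[1],
                     mixture$head_area_range[2])
      speeds <- numeric(n_cells)
      x0 <- runif(n_cells, -margin, W + margin)
      y0 <- runif(n_cells, -margin, H + margin)
      tt <- (seq_len(n_frames) - 1) / frame_rate_hz
      drift_x <- mixture$drift_velocity[1] * tt
      drift_y <- mixture$drift_velocity[2] * tt
      for (i in seq_len(n_cells)) {
        cl <- classes[i]
        if (cl == "static") {
          hd <- head_diameter(areas[i])
          off <- static_jitter(n_frames, mixture$static_jitter_sd,
                               0.8 * hd * 0.98)
          px <- x0[i] + off[, 1]; py <- y0[i] + off[, 2]
        } else {
          speeds[i] <- runif(1, mixture$speed_ranges[[cl]][1],
                             mixture$speed_ranges[[cl]][2])
          sd_theta <- 2 * (1 - mixture$directional_persistence[[cl]])
          theta <- runif(1, 0, 2 * pi) +
            cumsum(c(0, rnorm(n_frames - 2, 0, sd_theta)))
          step <- speeds[i] / frame_rate_hz
          px <- x0[i] + c(0, cumsum(step * cos(theta)))
          py <- y0[i] + c(0, cumsum(step * sin(theta)))
        }
        pos_list[[i]] <- cbind(px + drift_x, py + drift_y)
      }
    }

    # carve each cell's path into maximal in-field runs -> truth tracks
    cells <- list(); positions <- list(); tid <- 0L
    for (i in seq_len(n_cells)) {
      p <- pos_list[[i]]
      inside <- p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H
      if (!any(inside)) next
      r <- rle(inside)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        tid <- tid + 1L
        idx <- starts[k]:ends[k]
        cells[[tid]] <- data.frame(
          track_id = tid, cell_id = i, class = classes[i],
          head_area_um2 = areas[i], speed_um_s = speeds[i],
          n_frames = length(idx))
        positions[[tid]] <- data.frame(
          track_id = tid, frame = idx - 1L,
          x_um = p[idx, 1], y_um = p[idx, 2])
      }
    }

    blooms <- data.frame(x_um = numeric(0), y_um = numeric(0),
                         radius_um = numeric(0))
    if (mixture$bloom_count > 0) {
      radius <- runif(mixture$bloom_count, 8, 14)  # area 200--615 um^2
      blooms <- data.frame(
        x_um = runif(mixture$bloom_count, 20, W - 20),
        y_um = runif(mixture$bloom_count, 20, H - 20),
        radius_um = radius)
    }

    structure(list(
      cells = if (tid > 0) do.call(rbind, cells) else
        data.frame(track_id = integer(0), cell_id = integer(0),
                   class = character(0), head_area_um2 = numeric(0),
                   speed_um_s = numeric(0), n_frames = integer(0)),
      positions = if (tid > 0) do.call(rbind, positions) else
        data.frame(track_id = integer(0), frame = integer(0),
                   x_um = numeric(0), y_um = numeric(0)),
      blooms = blooms,
      geometry = geometry,
      frame_rate_hz = frame_rate_hz,
      n_frames = n_frames,
      mixture = mixture), class = "ground_truth")
  })
}

# zero-mean jitter offsets, first frame pinned at the origin, rejection-
# sampled so no offset norm reaches `rmax` (the static excursion rule)
static_jitter <- function(n_frames, sd, rmax) {
  off <- matrix(0, n_frames, 2)
  if (n_frames > 1 && sd > 0) {
    m <- n_frames - 1
    ox <- rnorm(m, 0, sd); oy <- rnorm(m, 0, sd)
    bad <- which(sqrt(ox^2 + oy^2) >= rmax)
    guard <- 0
    while (length(bad) && guard < 100) {
      ox[bad] <- rnorm(length(bad), 0, sd)
      oy[bad] <- rnorm(length(bad), 0, sd)
      bad <- bad[sqrt(ox[bad]^2 + oy[bad]^2) >= rmax]
      guard <- guard + 1
    }
    if (length(bad)) {  # pathological sd: clip instead of spinning
      s <- (rmax * 0.99) / sqrt(ox[bad]^2 + oy[bad]^2)
      ox[bad] <- ox[bad] * s; oy[bad] <- oy[bad] * s
    }
    off[-1, ] <- cbind(ox, oy)
  }
  off
}

#' Truth positions as a detections table
#'
#' Converts ground-truth positions into the canonical detections layout so
#' the tracking/kinematics/quantitation stages can be exercised without
#' rendering and re-detecting frames.
#'
#' @param truth a [simulate_tracks()] result.
#' @return data.frame with `frame`, `x_um`, `y_um`, `area_um2`, `intensity`.
#' @export
truth_to_detections <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$positions
  if (nrow(p) == 0) return(empty_detections())
  area <- truth$cells$head_area_um2[match(p$track_id, truth$cells$track_id)]
  d <- data.frame(frame = p$frame, x_um = p$x_um, y_um = p$y_um,
                  area_um2 = area, intensity = 1)
  d[order(d$frame), , drop = FALSE]
}

#' Truth positions as tidy tracks
#'
#' Ground-truth tracks in the [link_detections()] output layout, for
#' exercising track-level stages (kinematics, drift QC) without detection
#' and linking.
#'
#' @param truth a [simulate_tracks()] result.
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`, `area_um2`.
#' @export
truth_to_tracks <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$positions
  data.frame(track_id = p$track_id, frame = p$frame,
             x_um = p$x_um, y_um = p$y_um,
             area_um2 = truth$cells$head_area_um2[
               match(p$track_id, truth$cells$track_id)])
}

#' Per-frame in-field cell counts of a ground truth
#'
#' @param truth a [simulate_tracks()] result.
#' @return integer vector of length `n_frames` (frame 0 first).
#' @export
truth_frame_counts <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tabulate(truth$positions$frame + 1L, nbins = truth$n_frames)
}

#' Optics for rendering synthetic frames
#'
#' @param microns_per_pixel spatial sampling, um/px.
#' @param spot_amplitude peak intensity of a sperm head above background.
#' @param background uniform background level.
#' @param noise_sd additive Gaussian noise sd (0 disables noise).
#' @param bloom_intensity intensity of static bloom discs (saturation).
#' @param max_intensity clip ceiling (8-bit by default).
#' @param seed integer seed for the noise stream.
#' @return an object of class `casa_optics`.
#' @export
casa_optics <- function(microns_per_pixel = 1.0, spot_amplitude = 200,
                        background = 20, noise_sd = 5,
                        bloom_intensity = 255, max_intensity = 255,
                        seed = NA_integer_) {
  if (microns_per_pixel <= 0) stopf("microns_per_pixel must be positive")
  if (spot_amplitude < background)
    stopf("spot_amplitude must be at least the background level")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(microns_per_pixel = microns_per_pixel,
                 spot_amplitude = spot_amplitude, background = background,
                 noise_sd = noise_sd, bloom_intensity = bloom_intensity,
                 max_intensity = max_intensity,
                 seed = suppressWarnings(as.integer(seed))),
            class = "casa_optics")
}

#' Render ground-truth tracks into a synthetic frame stack
#'
#' Draws each cell as a 2-D Gaussian spot whose area at the half-maximum
#' level equals its head area (`sigma = sqrt(area / pi) / sqrt(2 ln 2)`),
#' overlays static saturated bloom discs (larger than the maximum head
#' size), and adds Gaussian noise.  Intensities are clipped to
#' `[0, max_intensity]` and rounded.
#'
#' @param truth a [simulate_tracks()] result.
#' @param optics a [casa_optics()].
#' @return a [frame_stack()].
#' @export
render_frames <- function(truth, optics = casa_optics()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optics, "casa_optics"))
  mpp <- optics$microns_per_pixel
  sigma_um <- sqrt(truth$cells$head_area_um2 / pi) / sqrt(2 * log(2))
  if (nrow(truth$cells) > 0 && any(sigma_um / mpp < 1))
    stopf(paste("calibration too coarse: smallest spot sigma is %.2f px",
                "(< 1 px) at %.2f um/px"), min(sigma_um / mpp), mpp)
  nr <- as.integer(round(truth$geometry$height_um / mpp))
  nc <- as.integer(round(truth$geometry$width_um / mpp))
  if (nr < 1 || nc < 1) stopf("field too small to render at %.2f um/px", mpp)

  # pixel-centre coordinates, um (row r, col c) -> ((c-0.5)*mpp, (r-0.5)*mpp)
  bloom_mask <- NULL
  if (nrow(truth$blooms) > 0) {
    xs <- (seq_len(nc) - 0.5) * mpp
    ys <- (seq_len(nr) - 0.5) * mpp
    bloom_mask <- matrix(FALSE, nr, nc)
    for (b in seq_len(nrow(truth$blooms))) {
      dx2 <- outer(rep(1, nr), (xs - truth$blooms$x_um[b])^2)
      dy2 <- outer((ys - truth$blooms$y_um[b])^2, rep(1, nc))
      bloom_mask <- bloom_mask | (dx2 + dy2 <= truth$blooms$radius_um[b]^2)
    }
  }

  pos <- truth$positions
  sigma_by_track <- sigma_um[match(seq_len(nrow(truth$cells)),
                                   truth$cells$track_id)]
  frames <- with_seed(optics$seed, lapply(seq_len(truth$n_frames) - 1L,
    function(f) {
      m <- matrix(optics$background, nr, nc)
      rows <- which(pos$frame == f)
      for (j in rows) {
        s_um <- sigma_by_track[pos$track_id[j]]
        s_px <- s_um / mpp
        cx <- pos$x_um[j] / mpp + 0.5  # pixel-index coordinates (centre at 1)
        cy <- pos$y_um[j] / mpp + 0.5
        ext <- ceiling(4 * s_px)
        c1 <- max(1L, floor(cx - ext)); c2 <- min(nc, ceiling(cx + ext))
        r1 <- max(1L, floor(cy - ext)); r2 <- min(nr, ceiling(cy + ext))
        if (c1 > c2 || r1 > r2) next
        gx <- exp(-((c1:c2) - cx)^2 / (2 * s_px^2))
        gy <- exp(-((r1:r2) - cy)^2 / (2 * s_px^2))
        m[r1:r2, c1:c2] <- m[r1:r2, c1:c2] +
          optics$spot_amplitude * outer(gy, gx)
      }
      if (optics$noise_sd > 0)
        m <- m + matrix(rnorm(nr * nc, 0, optics$noise_sd), nr, nc)
      # blooms after noise: saturated sensor pixels carry no noise, so a
      # bloom is bright at its ceiling in every frame
      if (!is.null(bloom_mask)) m[bloom_mask] <- optics$bloom_intensity
      round(clip(m, 0, optics$max_intensity))
    }))
  frame_stack(frames, microns_per_pixel = mpp,
              frame_rate_hz = truth$frame_rate_hz)
}

#' Parameters of a synthetic fertilisation dataset
#'
#' The generator emulates fertilisation trials in which eggs receive a
#' measured dose of motile sperm: fertilisation success is linear in
#' log10(motile cells per egg) plus Gaussian noise, clipped to `[0, 100]` --
#' the logarithmic dose-response shape seen when success is plotted against
#' sperm dose on a log axis.
#'
#' @param intercept,slope success (percentage points) intercept and slope
#'   per log10(cells/egg).
#' @param noise_sd residual sd, percentage points.
#' @param n_records number of fertilisation records (>= 3).
#' @param ratio_range_log10 length-2 range of log10(cells/egg) sampled
#'   uniformly.
#' @param seed integer seed.
#' @return an object of class `fert_params`.
#' @export
fert_params <- function(intercept = -52, slope = 32, noise_sd = 12,
                        n_records = 24, ratio_range_log10 = c(2.9, 4.6),
                        seed = NA_integer_) {
  if (n_records < 3) stopf("n_records must be at least 3")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(ratio_range_log10) != 2 ||
      ratio_range_log10[1] >= ratio_range_log10[2])
    stopf("ratio_range_log10 must be a non-empty increasing range")
  structure(list(intercept = intercept, slope = slope, noise_sd = noise_sd,
                 n_records = as.integer(n_records),
                 ratio_range_log10 = as.numeric(ratio_range_log10),
                 seed = suppressWarnings(as.integer(seed))),
            class = "fert_params")
}

#' Theoretical dose-response correlation of a fertilisation generator
#'
#' For success `= a + b * x + e` with `x` uniform on the ratio range and
#' `e ~ N(0, sd^2)` (clipping ignored), the population Pearson correlation
#' is `b * sd(x) / sqrt(b^2 var(x) + sd^2)`.
#'
#' @param params a [fert_params()].
#' @return the population correlation coefficient.
#' @export
fert_theoretical_r <- function(params) {
  stopifnot(inherits(params, "fert_params"))
  sx <- diff(params$ratio_range_log10) / sqrt(12)
  num <- params$slope * sx
  num / sqrt(num^2 + params$noise_sd^2)
}

#' Generate a synthetic fertilisation dataset
#'
#' Draws `n_records` fertilisation records with log10(motile cells per egg)
#' uniform on the configured range and success
#' `clip(intercept + slope * log10(ratio) + noise, 0, 100)`.  Egg counts are
#' sampled from 28--90 (a realistic per-bowl range for solitary coral
#' spawning trials); sperm volume is back-solved so that
#' [egg_sperm_ratio()] of each record reproduces its sampled ratio exactly.
#'
#' @param params a [fert_params()].
#' @return data.frame of fertilisation records: `sample_id`, `treatment`,
#'   `motile_concentration` (cells/mL), `sperm_volume_ul`, `n_eggs`,
#'   `n_cleaved`, `n_uncleaved`, `log10_cells_per_egg`.
#' @export
synth_fert_dataset <- function(params = fert_params()) {
  stopifnot(inherits(params, "fert_params"))
  with_seed(params$seed, {
    n <- params$n_records
    treatments <- rep(c("fresh", "fresh_dmso", "cryo"), length.out = n)
    conc <- c(fresh = 2.4e7, fresh_dmso = 1.1e7, cryo = 2.0e6)[treatments]
    log_ratio <- runif(n, params$ratio_range_log10[1],
                       params$ratio_range_log10[2])
    success <- clip(params$intercept + params$slope * log_ratio +
                      rnorm(n, 0, params$noise_sd), 0, 100)
    n_eggs <- sample(28:90, n, replace = TRUE)
    n_cleaved <- round(success / 100 * n_eggs)
    data.frame(
      sample_id = sprintf("F%03d", seq_len(n)),
      treatment = treatments,
      motile_concentration = unname(conc),
      sperm_volume_ul = 10^log_ratio * n_eggs / conc * 1e3,
      n_eggs = n_eggs,
      n_cleaved = n_cleaved,
      n_uncleaved = n_eggs - n_cleaved,
      log10_cells_per_egg = log_ratio)
  })
}
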