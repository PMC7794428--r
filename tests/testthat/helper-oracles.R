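# shared fixtures and independent oracles (built in code, no data files)

# detections of one cell moving in a straight line at `speed` um/s
line_detections <- function(speed_um_s, frame_rate = 60, n_frames = 45,
                            origin = c(10, 10), angle = 0) {
  step <- speed_um_s / frame_rate
  f <- seq_len(n_frames) - 1L
  data.frame(frame = f,
             x_um = origin[1] + f * step * cos(angle),
             y_um = origin[2] + f * step * sin(angle),
             area_um2 = 20, intensity = 1)
}

# square-wave zigzag: steps alternate (+step,0) and (0,+step)
zigzag_track <- function(step = 5, n_frames = 45) {
  dx <- ifelse(seq_len(n_frames - 1) %% 2 == 1, step, 0)
  dy <- ifelse(seq_len(n_frames - 1) %% 2 == 1, 0, step)
  data.frame(track_id = 1L, frame = seq_len(n_frames) - 1L,
             x_um = cumsum(c(0, dx)), y_um = cumsum(c(0, dy)))
}

# exhaustive maximum-cardinality / minimum-total-distance partial matching
# between two frames (independent oracle for the Hungarian linker)
brute_force_match <- function(x1, y1, x2, y2, bound) {
  n1 <- length(x1); n2 <- length(x2)
  dmat <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  best <- list(card = -1L, cost = Inf, match = rep(NA_integer_, n1))
  recurse <- function(i, used, match, card, cost) {
    if (i > n1) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost, match = match)
      return(invisible())
    }
    recurse(i + 1L, used, match, card, cost)
    for (j in seq_len(n2)) {
      if (!used[j] && dmat[i, j] <= bound) {
        used[j] <- TRUE; match[i] <- j
        recurse(i + 1L, used, match, card + 1L, cost + dmat[i, j])
        used[j] <- FALSE; match[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, n2), rep(NA_integer_, n1), 0L, 0)
  best
}

# random multi-cell instance whose ground-truth correspondence is the unique
# feasible linking: cells tethered to grid anchors spaced 3x the bound, with
# per-frame offsets inside 0.45x the bound (steps <= 0.9x bound, spacing
# always > 2x bound)
random_instance <- function(n_cells, n_frames, bound = 10) {
  anchors <- expand.grid(x = (1:3) * 3 * bound, y = (1:3) * 3 * bound)
  anchors <- anchors[sample(nrow(anchors), n_cells), , drop = FALSE]
  det <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    r <- 0.45 * bound * sqrt(runif(n_frames))
    th <- runif(n_frames, 0, 2 * pi)
    data.frame(cell = i, frame = seq_len(n_frames) - 1L,
               x_um = anchors$x[i] + r * cos(th),
               y_um = anchors$y[i] + r * sin(th))
  }))
  det[order(det$frame, det$cell), ]
}

# a 2-D Gaussian spot frame built directly from the intensity formula
# (independent of render_frames)
spot_frame <- function(nr, nc, cx_um, cy_um, area_um2, amplitude = 200,
                       background = 20, mpp = 1) {
  sigma <- sqrt(area_um2 / pi) / sqrt(2 * log(2)) / mpp
  xs <- (seq_len(nc) - 0.5) * mpp
  ys <- (seq_len(nr) - 0.5) * mpp
  m <- matrix(background, nr, nc)
  for (k in seq_along(cx_um)) {
    gx <- exp(-(xs - cx_um[k])^2 / (2 * (sigma * mpp)^2))
    gy <- exp(-(ys - cy_um[k])^2 / (2 * (sigma * mpp)^2))
    m <- m + amplitude * outer(gy, gx)
  }
  m
}

# per-track classification table joined against ground truth
truth_vs_pipeline_classes <- function(truth, settings = casa_settings()) {
  k <- track_kinematics(truth_to_tracks(truth), settings)
  merge(k, truth$cells[, c("track_id", "class")], by = "track_id")
}
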