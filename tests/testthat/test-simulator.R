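test_that("mixture validation enforces fractions, bins and concentration", {
  expect_error(motility_mixture(fraction_static = 0.5), "sum to 1")
  expect_error(motility_mixture(speed_ranges = list(
    slow = c(5, 25), motile = c(25, 75), progressive = c(85, 150))),
    "outside its class bin")
  expect_error(motility_mixture(speed_ranges = list(
    slow = c(8, 18), motile = c(25, 85), progressive = c(85, 150))),
    "outside its class bin")
  expect_error(motility_mixture(speed_ranges = list(
    slow = c(8, 18), motile = c(25, 75), progressive = c(80, 150))),
    "outside its class bin")
  expect_error(motility_mixture(concentration = 0), "positive")
  # the 20 and 80 um/s edges belong to the motile bin
  expect_silent(motility_mixture(speed_ranges = list(
    slow = c(0, 19.9), motile = c(20, 80), progressive = c(80.1, 300))))
})

test_that("simulate_tracks rejects degenerate geometry and duration", {
  mix <- motility_mixture(seed = 1)
  expect_error(field_geometry(0, 480, 20), "positive area")
  expect_error(field_geometry(640, 480, 0), "depth")
  expect_error(simulate_tracks(mix, duration_s = -1), "positive")
})

test_that("same seed gives bit-identical ground truth and fert records", {
  mix <- motility_mixture(concentration = 5e6, bloom_count = 1, seed = 11)
  expect_identical(simulate_tracks(mix), simulate_tracks(mix))
  p <- fert_params(seed = 11)
  expect_identical(synth_fert_dataset(p), synth_fert_dataset(p))
})

test_that("all-static mixtures never move 0.8 head diameters", {
  mix <- motility_mixture(fraction_static = 1, fraction_slow = 0,
                          fraction_motile = 0, fraction_progressive = 0,
                          concentration = 2e7, seed = 5)
  truth <- simulate_tracks(mix)
  expect_gt(nrow(truth$cells), 50)
  expect_true(all(truth$cells$n_frames == truth$n_frames))
  by_track <- split(truth$positions, truth$positions$track_id)
  for (tr in by_track) {
    excursion <- max(sqrt((tr$x_um - tr$x_um[1])^2 +
                          (tr$y_um - tr$y_um[1])^2))
    hd <- head_diameter(
      truth$cells$head_area_um2[truth$cells$track_id == tr$track_id[1]])
    expect_lt(excursion, 0.8 * hd)
  }
})

test_that("in-field counts are Poisson with the unit-converted mean", {
  # 2e7 cells/mL x (640 x 480 x 20 um^3) = 122.88 expected cells per field;
  # all-static mixture so the placement process is cheap to replicate
  mix0 <- motility_mixture(fraction_static = 1, fraction_slow = 0,
                           fraction_motile = 0, fraction_progressive = 0,
                           concentration = 2e7)
  lambda <- 2e7 * field_volume_ml(field_geometry())
  expect_equal(lambda, 122.88, tolerance = 1e-12)
  counts <- vapply(1:500, function(s) {
    m <- mix0; m$seed <- s
    truth_frame_counts(simulate_tracks(m))[1]
  }, numeric(1))
  se <- sqrt(lambda / 500)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.7)
  expect_lt(var(counts) / mean(counts), 1.3)
})

test_that("per-frame occupancy stays stationary despite boundary exits", {
  # buffered spawning: cells leave AND enter, so late frames hold as many
  # cells as frame 0 on average
  counts <- Reduce(`+`, lapply(1:40, function(s) {
    mix <- motility_mixture(concentration = 2e7, seed = 300 + s)
    truth_frame_counts(simulate_tracks(mix))
  }))
  first_third <- mean(counts[1:15]); last_third <- mean(counts[31:45])
  expect_lt(abs(last_third - first_third) / first_third, 0.05)
})

test_that("swimming classes move and drift displaces everything", {
  mix <- motility_mixture(concentration = 5e6,
                          drift_velocity = c(30, 0), seed = 9)
  truth <- simulate_tracks(mix)
  tr <- truth_to_tracks(truth)
  steps <- do.call(rbind, lapply(split(tr[, c("x_um", "y_um")], tr$track_id),
                                 function(p) diff(as.matrix(p))))
  # median x-step reflects the 0.5 um/frame drift
  expect_gt(median(steps[, 1]) * truth$frame_rate_hz, 20)
  expect_lt(abs(median(steps[, 2])) * truth$frame_rate_hz, 10)
})

test_that("rendered frames honour spot, bloom and calibration contracts", {
  one <- motility_mixture(fraction_static = 1, fraction_slow = 0,
                          fraction_motile = 0, fraction_progressive = 0,
                          concentration = 5e6, seed = 21)
  truth <- simulate_tracks(one, field_geometry(100, 100, 20))
  # make it exactly one cell for the component count to be meaningful
  skip_count <- 0
  while (nrow(truth$cells) != 1) {
    skip_count <- skip_count + 1
    one$seed <- 21 + skip_count
    truth <- simulate_tracks(one, field_geometry(100, 100, 20))
  }
  st <- render_frames(truth, casa_optics(noise_sd = 0))
  for (f in st$frames) {
    lab <- coralcasa:::label_components_cpp(f > 30)
    expect_identical(max(lab), 1L)
  }
  # blooms: static saturated components at identical positions in all frames
  mixb <- motility_mixture(concentration = 2e6, bloom_count = 2, seed = 4)
  tb <- simulate_tracks(mixb)
  stb <- render_frames(tb, casa_optics(noise_sd = 0))
  sat0 <- which(stb$frames[[1]] == 255)
  expect_length(unique(tb$blooms$x_um), 2)
  for (f in stb$frames) expect_identical(which(f == 255), sat0)
  # calibration too coarse for the smallest head
  expect_error(render_frames(tb, casa_optics(microns_per_pixel = 4)),
               "calibration too coarse")
  expect_error(casa_optics(spot_amplitude = 5, background = 20),
               "at least the background")
})

test_that("synthetic fertilisation data follow the stated dose-response", {
  p0 <- fert_params(noise_sd = 0, slope = 20, intercept = 10,
                    ratio_range_log10 = c(3, 4.2), n_records = 20, seed = 2)
  d0 <- synth_fert_dataset(p0)
  ratio <- egg_sperm_ratio(d0$motile_concentration, d0$sperm_volume_ul,
                           d0$n_eggs)
  expect_equal(log10(ratio), d0$log10_cells_per_egg, tolerance = 1e-12)
  success <- 10 + 20 * d0$log10_cells_per_egg
  expect_true(all(success > 0 & success < 100))  # clipping inactive
  expect_gt(cor(d0$log10_cells_per_egg, success), 1 - 1e-12)
  # slope 0, noisy, n = 1000: correlation concentrates near zero
  pn <- fert_params(slope = 0, intercept = 50, noise_sd = 10,
                    n_records = 1000, seed = 3)
  dn <- synth_fert_dataset(pn)
  r <- cor(dn$log10_cells_per_egg,
           fertilisation_rate(dn$n_cleaved, dn$n_uncleaved))
  expect_lt(abs(r), 0.1)
  expect_error(fert_params(ratio_range_log10 = c(3, 3)), "non-empty")
  expect_error(fert_params(n_records = 2), "at least 3")
})
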