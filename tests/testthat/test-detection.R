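test_that("head_diameter matches the circular-equivalent closed form", {
  expect_equal(head_diameter(pi), 2)
  expect_equal(head_diameter(78.54), 10, tolerance = 1e-3)
  expect_equal(head_diameter(5), 2.52, tolerance = 1e-2)
  expect_error(head_diameter(0), "positive")
  expect_error(head_diameter(-3), "positive")
})

test_that("a rendered spot is detected at its centre with its area", {
  s <- casa_settings(fixed_threshold = 120)  # background 20 + 200 / 2
  fr <- spot_frame(60, 80, cx_um = 40, cy_um = 30, area_um2 = 20)
  d <- segment_frame(fr, s)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$x_um - 40), 0.5)
  expect_lt(abs(d$y_um - 30), 0.5)
  # area at the half-maximum threshold equals the nominal head area, up to
  # pixel quantisation
  expect_lt(abs(d$area_um2 - 20), 4.5)
})

test_that("the head-size gate discards oversized and undersized blobs", {
  s <- casa_settings(fixed_threshold = 120)
  big <- spot_frame(80, 80, 40, 40, area_um2 = 200)
  expect_identical(nrow(segment_frame(big, s)), 0L)
  tiny <- spot_frame(40, 40, 20, 20, area_um2 = 2)
  expect_identical(nrow(segment_frame(tiny, s)), 0L)
  # widening the gate recovers the big one
  s2 <- casa_settings(fixed_threshold = 120, max_head_area_um2 = 400)
  expect_identical(nrow(segment_frame(big, s2)), 1L)
})

test_that("two spots 50 um apart give two detections 50 um apart", {
  s <- casa_settings(fixed_threshold = 120)
  fr <- spot_frame(60, 100, cx_um = c(25, 75), cy_um = c(30, 30),
                   area_um2 = 20)
  d <- segment_frame(fr, s)
  expect_identical(nrow(d), 2L)
  expect_lt(abs(dist(cbind(d$x_um, d$y_um))[1] - 50), 1)
})

test_that("blank frames warn instead of erroring", {
  d <- segment_frame(matrix(7, 40, 40), casa_settings())
  expect_identical(nrow(d), 0L)
  expect_identical(attr(d, "warning"), "blank_frame")
})

test_that("shrinking the area gate never increases the detection count", {
  set.seed(42)
  for (rep in 1:5) {
    truth <- simulate_tracks(
      motility_mixture(concentration = 1e7, seed = 40 + rep))
    fr <- render_frames(truth, casa_optics(noise_sd = 3,
                                           seed = rep))$frames[[1]]
    gates <- list(c(1, 300), c(5, 150), c(8, 100), c(10, 50))
    n <- vapply(gates, function(g) {
      s <- casa_settings(min_head_area_um2 = g[1], max_head_area_um2 = g[2])
      nrow(segment_frame(fr, s))
    }, numeric(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("noise-free detection counts equal truth counts per frame", {
  truth <- simulate_tracks(motility_mixture(concentration = 3e6, seed = 8))
  st <- render_frames(truth, casa_optics(noise_sd = 0))
  det <- segment_stack(st, casa_settings())
  got <- tabulate(det$frame + 1L, nbins = truth$n_frames)
  expect_identical(got, truth_frame_counts(truth))
})

test_that("the artefact mask covers blooms, spares cells, handles flat stacks", {
  s <- casa_settings()
  mixb <- motility_mixture(concentration = 5e6, bloom_count = 2, seed = 3)
  tb <- simulate_tracks(mixb)
  stb <- render_frames(tb, casa_optics(noise_sd = 3, seed = 3))
  mask <- build_artifact_mask(stb, s)
  for (b in seq_len(nrow(tb$blooms)))
    expect_true(mask[round(tb$blooms$y_um[b]), round(tb$blooms$x_um[b])])
  # masked detections never sit on the mask, and no bloom-sized blob remains
  det <- segment_stack(stb, s, mask)
  expect_true(all(det$area_um2 <= s$max_head_area_um2))
  # a bloom-free capture of moving cells yields a near-empty mask
  mixm <- motility_mixture(fraction_static = 0, fraction_slow = 1 / 3,
                           fraction_motile = 1 / 3,
                           fraction_progressive = 1 / 3,
                           concentration = 1e7, seed = 5)
  stm <- render_frames(simulate_tracks(mixm), casa_optics(noise_sd = 3,
                                                          seed = 5))
  expect_lt(mean(build_artifact_mask(stm, s)), 0.01)
  # all-black stack -> empty mask
  flat <- frame_stack(replicate(6, matrix(0, 30, 30), simplify = FALSE),
                      1, 60)
  expect_false(any(build_artifact_mask(flat, s)))
  expect_error(build_artifact_mask(
    frame_stack(replicate(3, matrix(0, 5, 5), simplify = FALSE), 1, 60), s),
    "at least 5 frames")
})

test_that("masking is idempotent", {
  truth <- simulate_tracks(motility_mixture(concentration = 5e6,
                                            bloom_count = 1, seed = 12))
  st <- render_frames(truth, casa_optics(noise_sd = 3, seed = 12))
  mask <- build_artifact_mask(st, casa_settings())
  once <- segment_stack(st, casa_settings(), mask)
  twice <- segment_stack(st, casa_settings(), mask | mask)
  expect_identical(once, twice)
})
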