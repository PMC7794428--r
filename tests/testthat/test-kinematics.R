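test_that("collinear, zigzag and stationary tracks hit their closed forms", {
  s <- casa_settings()
  line <- data.frame(frame = 0:44, x_um = (0:44) * (100 / 60), y_um = 5)
  k <- compute_kinematics(line, s)
  expect_equal(k$vcl, 100, tolerance = 1e-6)
  expect_equal(k$vap, 100, tolerance = 1e-6)
  expect_equal(k$vsl, 100, tolerance = 1e-6)
  # square-wave zigzag at 5 um steps, 60 Hz: VCL 300, VSL 300/sqrt(2)
  kz <- compute_kinematics(zigzag_track(step = 5, n_frames = 45), s)
  expect_equal(kz$vcl, 300, tolerance = 1e-9)
  expect_equal(kz$vsl, 300 / sqrt(2), tolerance = 1e-9)
  expect_lte(kz$vsl, kz$vap + 1e-9)
  expect_lte(kz$vap, kz$vcl + 1e-9)
  still <- data.frame(frame = 0:44, x_um = 3, y_um = 3)
  ks <- compute_kinematics(still, s)
  expect_identical(c(ks$vcl, ks$vap, ks$vsl, ks$max_excursion_um),
                   c(0, 0, 0, 0))
})

test_that("degenerate tracks are rejected", {
  s <- casa_settings()
  expect_error(compute_kinematics(data.frame(frame = 0, x_um = 1, y_um = 1),
                                  s), "at least 2 frames")
  gap <- data.frame(frame = c(0, 2), x_um = c(0, 1), y_um = 0)
  expect_error(compute_kinematics(gap, s), "consecutive")
})

test_that("VSL <= VAP <= VCL holds on 1000 random tracks", {
  set.seed(99)
  for (rep in 1:1000) {
    n <- sample(5:45, 1)
    tr <- data.frame(frame = seq_len(n) - 1L,
                     x_um = cumsum(rnorm(n, 0, 2)),
                     y_um = cumsum(rnorm(n, 0, 2)))
    w <- sample(c(3, 5, 7), 1)
    k <- compute_kinematics(tr, casa_settings(smoothing_frames = w))
    expect_lte(k$vsl, k$vap + 1e-9)
    expect_lte(k$vap, k$vcl + 1e-9)
  }
})

test_that("classification follows the static rule and velocity bins", {
  s <- casa_settings()
  kin <- function(vap, exc) structure(
    list(vcl = vap + 10, vap = vap, vsl = vap / 2, max_excursion_um = exc),
    class = "track_kinematics")
  # 0.8 x 10 um head diameter = 8 um excursion boundary
  expect_identical(classify_track(kin(10, 7.9), 10, s), "static")
  expect_identical(classify_track(kin(10, 8.1), 10, s), "slow")
  expect_identical(classify_track(kin(50, 20), 10, s), "motile")
  expect_identical(classify_track(kin(100, 50), 10, s), "progressive")
  # both bin edges map to motile: "less than 20" is slow, "greater than 80"
  # is progressive
  expect_identical(classify_track(kin(20, 20), 10, s), "motile")
  expect_identical(classify_track(kin(80, 50), 10, s), "motile")
  expect_identical(classify_track(kin(19.999, 20), 10, s), "slow")
  expect_identical(classify_track(kin(80.001, 50), 10, s), "progressive")
  expect_error(classify_track(kin(10, 5), 0, s), "positive")
  # classification velocity is configurable
  svcl <- casa_settings(classification_velocity = "vcl")
  expect_identical(classify_track(kin(15, 20), 10, svcl), "motile")  # vcl 25
})

test_that("raising velocity never demotes a non-static track", {
  s <- casa_settings()
  lvl <- c(slow = 1, motile = 2, progressive = 3)
  kin <- function(vap) structure(
    list(vcl = vap, vap = vap, vsl = vap, max_excursion_um = 50),
    class = "track_kinematics")
  cls <- vapply(seq(1, 150, by = 0.5),
                function(v) classify_track(kin(v), 8, s), character(1))
  expect_true(all(diff(lvl[cls]) >= 0))
})

test_that("every classified track gets exactly one class and counts add up", {
  truth <- simulate_tracks(motility_mixture(concentration = 1e7, seed = 17))
  k <- track_kinematics(truth_to_tracks(truth), casa_settings())
  expect_true(all(k$motility_class %in%
                  c("static", "slow", "motile", "progressive")))
  expect_identical(nrow(k), sum(table(k$motility_class)))
})

test_that("conforming motion is classified as intended >= 95% of the time", {
  # default speed ranges sit >= 5 um/s inside the bins; accuracy is checked
  # on full-length truth tracks
  hits <- 0; total <- 0
  for (s in 1:3) {
    truth <- simulate_tracks(
      motility_mixture(concentration = 1e7, seed = 60 + s),
      field_geometry(1200, 1200, 20))
    cmp <- truth_vs_pipeline_classes(truth)
    cmp <- cmp[cmp$n_frames == truth$n_frames, ]
    hits <- hits + sum(cmp$motility_class == cmp$class)
    total <- total + nrow(cmp)
  }
  expect_gt(total, 600)
  expect_gte(hits / total, 0.95)
})
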