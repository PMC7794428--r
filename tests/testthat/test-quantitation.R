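test_that("field_concentration converts counts through chamber geometry", {
  # 61.44 cells/frame over 640x480x20 um^3 (6.144e-6 mL) = 1e7 cells/mL
  expect_equal(field_concentration(61.44, 640 * 480, 20), 1e7)
  expect_identical(field_concentration(0, 640 * 480, 20), 0)
  c1 <- field_concentration(10, 640 * 480, 20, dilution = 1)
  expect_equal(field_concentration(10, 640 * 480, 20, dilution = 2), 2 * c1)
  expect_error(field_concentration(10, 0, 20), "positive")
})

test_that("haemocytometer formula is the literal printed product", {
  expect_identical(haemocytometer_concentration(1, 3, 1, 1) / 3, 1)
  expect_equal(haemocytometer_concentration(50, 3, 1e4, 2), 3e6)
  # linear in every factor
  base <- haemocytometer_concentration(10, 4, 100, 1)
  expect_equal(haemocytometer_concentration(20, 4, 100, 1), 2 * base)
  expect_equal(haemocytometer_concentration(10, 8, 100, 1), 2 * base)
  expect_equal(haemocytometer_concentration(10, 4, 200, 1), 2 * base)
  expect_equal(haemocytometer_concentration(10, 4, 100, 2), 2 * base)
  # the conventional mean-per-cell reading divides by N instead
  expect_equal(haemocytometer_concentration(50, 5, 1e4, 1,
                                            mode = "mean_per_cell"), 1e5)
  expect_error(haemocytometer_concentration(0, 3, 1, 1), "positive")
  expect_warning(haemocytometer_concentration(5, 2, 1, 1), "fewer than 3")
})

test_that("flow-cytometer scaling gives the x100 per-mL factor at 10 uL", {
  expect_equal(flow_concentration(1e4, 2), 2e6)
  expect_identical(flow_concentration(0, 5), 0)
  expect_equal(flow_concentration(1, 1, 10), 100)
  expect_equal(flow_concentration(1e4, 2, 20), 1e6)
  expect_error(flow_concentration(10, 1, 0), "positive")
})

test_that("dilution planning picks the smallest serial factor into range", {
  p <- dilution_plan(1e9, c(1e7, 3e7))
  expect_identical(p$status, "ok")
  expect_equal(p$factor, 100)
  expect_equal(p$resulting_conc, 1e7)
  expect_equal(dilution_plan(2e7, c(1e7, 3e7))$factor, 1)
  expect_identical(dilution_plan(5e6, c(8e6, 5e7))$status, "below_range")
  # continuous mode returns the exact minimal factor
  expect_equal(dilution_plan(1e9, c(1e7, 3e7), series = NULL)$factor,
               1e9 / 3e7)
  # a band narrower than one series step falls back to the exact factor
  narrow <- dilution_plan(2e7, c(1e7, 1.5e7))
  expect_identical(narrow$status, "no_series_factor")
  expect_equal(narrow$resulting_conc, 1.5e7)
  expect_error(dilution_plan(1e7, c(3e7, 1e7)), "increasing")
})

test_that("aggregate_sample computes percentages, flags and motile conc", {
  s <- casa_settings()
  mk <- function(counts, conc = 2e7) {
    structure(list(field_id = 1, class_counts = counts,
                   n_tracks = sum(counts), mean_cells_per_frame = 10,
                   concentration = conc), class = "field_result")
  }
  cc <- function(st, sl, mo, pr) c(static = st, slow = sl, motile = mo,
                                   progressive = pr)
  # 100 cells all progressive -> 100% motility on both measures
  r <- aggregate_sample(rep(list(mk(cc(0, 0, 0, 50))), 5), s)
  expect_equal(r$total_motility_pct, 100)
  expect_equal(r$progressive_motility_pct, 100)
  expect_equal(r$motile_concentration, r$total_concentration)
  # 4 fields, 250 cells -> insufficient fields only
  r4 <- aggregate_sample(rep(list(mk(cc(20, 10, 20, 13))), 4), s)
  expect_true("insufficient_fields" %in% r4$qc_flags)
  expect_false("insufficient_cells" %in% r4$qc_flags)
  # 6 fields, 150 cells -> insufficient cells only
  r6 <- aggregate_sample(rep(list(mk(cc(10, 5, 5, 5))), 6), s)
  expect_true("insufficient_cells" %in% r6$qc_flags)
  expect_false("insufficient_fields" %in% r6$qc_flags)
  # mixed classes: static excluded from total motility
  rm <- aggregate_sample(rep(list(mk(cc(25, 10, 10, 5))), 5), s)
  expect_equal(rm$total_motility_pct, 50)
  expect_equal(rm$progressive_motility_pct, 10)
  expect_equal(rm$motile_concentration,
               rm$total_concentration * 0.5)
  expect_lte(rm$motile_concentration, rm$total_concentration)
  # zero cells: percentages missing (not 0) and flagged
  r0 <- aggregate_sample(rep(list(mk(cc(0, 0, 0, 0))), 5), s)
  expect_true(is.na(r0$total_motility_pct))
  expect_true(is.na(r0$motile_concentration))
  expect_true("no_cells" %in% r0$qc_flags)
})

test_that("simulated concentration is recovered through the full chain", {
  geom <- field_geometry()
  ests <- vapply(1:8, function(f) {
    truth <- simulate_tracks(
      motility_mixture(concentration = 2e7, seed = 500 + f), geom)
    field_concentration(mean(truth_frame_counts(truth)),
                        geom$width_um * geom$height_um, geom$depth_um)
  }, numeric(1))
  lambda <- 2e7 * field_volume_ml(geom)
  se_conc <- sqrt(8 * lambda) / (8 * field_volume_ml(geom))
  expect_lt(abs(mean(ests) - 2e7), 2 * se_conc)
})

test_that("chamber and cytometer agree when fed the same truth", {
  # the cytometer sees est/100 events in 10 uL of the same suspension
  truth <- simulate_tracks(motility_mixture(concentration = 2e7, seed = 77))
  est <- field_concentration(mean(truth_frame_counts(truth)),
                             640 * 480, 20)
  events_in_10ul <- est * 0.01  # cells/mL x 10 uL = 0.01 mL
  expect_lt(abs(flow_concentration(events_in_10ul, 1) - est) / est, 0.01)
})
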