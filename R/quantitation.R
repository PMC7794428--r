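#' Concentration from per-field cell counts and chamber geometry
#'
#' The imaged field observes a volume of `area x depth`; the mean number of
#' cells per frame divided by that volume (times the dilution factor) is the
#' sample concentration.  The mean per-frame detection count is used rather
#' than the track count because it is robust to track fragmentation.
#'
#' @param n_cells_mean_per_frame mean detections per frame.
#' @param field_area_um2 field area, um^2.
#' @param chamber_depth_um chamber depth, um.
#' @param dilution dilution factor (>= 1 for diluted samples).
#' @return concentration, cells/mL.
#' @examples
#' field_concentration(61.44, 640 * 480, 20)  # 1e7 cells/mL
#' @export
field_concentration <- function(n_cells_mean_per_frame, field_area_um2,
                                chamber_depth_um, dilution = 1) {
  if (field_area_um2 <= 0 || chamber_depth_um <= 0)
    stopf("field area and chamber depth must be positive")
  if (n_cells_mean_per_frame < 0) stopf("cell count must be >= 0")
  volume_ml <- field_area_um2 * chamber_depth_um * 1e-12
  n_cells_mean_per_frame / volume_ml * dilution
}

#' Summarise one analysed field
#'
#' Collects per-class track counts and the geometry-based concentration for
#' a single captured field.
#'
#' @param kinematics a [track_kinematics()] table for the field.
#' @param detections the field's detections (per-frame counts drive the
#'   concentration).
#' @param n_frames number of frames captured.
#' @param field_area_um2 field area, um^2.
#' @param settings a [casa_settings()].
#' @param field_id identifier.
#' @return list of class `field_result`: `field_id`, `class_counts`,
#'   `n_tracks`, `mean_cells_per_frame`, `concentration` (cells/mL).
#' @export
field_result <- function(kinematics, detections, n_frames,
                         field_area_um2, settings = casa_settings(),
                         field_id = 1L) {
  classes <- c("static", "slow", "motile", "progressive")
  counts <- vapply(classes,
                   function(cl) sum(kinematics$motility_class == cl),
                   integer(1))
  mean_per_frame <- nrow(detections) / n_frames
  structure(list(
    field_id = field_id,
    class_counts = counts,
    n_tracks = sum(counts),
    mean_cells_per_frame = mean_per_frame,
    concentration = field_concentration(mean_per_frame, field_area_um2,
                                        settings$chamber_depth_um,
                                        settings$dilution)),
    class = "field_result")
}

#' Aggregate fields into a sample result
#'
#' Total motility is the percentage of classified tracks that are not
#' static (slow + motile + progressive); progressive motility is the
#' progressive percentage.  Total concentration is the mean of the field
#' concentrations, and motile concentration is
#' `total_concentration x total_motility / 100` -- the headline metric,
#' since a motility percentage is only meaningful in the context of
#' concentration.  Captures with fewer than `min_fields` fields (default 5)
#' or `min_cells` classified cells (default 200) are flagged rather than
#' rejected.  With zero classified cells the percentages are reported as
#' missing (`NA`), not 0.
#'
#' @param fields list of [field_result()]s (at least one).
#' @param settings a [casa_settings()].
#' @param sample_id,treatment metadata carried into the result.
#' @param qc optional [qc_report()] to embed (capture-sufficiency flags are
#'   always recomputed here).
#' @return list of class `sample_result`: `sample_id`, `treatment`,
#'   `n_fields`, `n_cells`, `class_counts`, `total_motility_pct`,
#'   `progressive_motility_pct`, `total_concentration`,
#'   `motile_concentration`, `qc_flags`.
#' @export
aggregate_sample <- function(fields, settings = casa_settings(),
                             sample_id = "sample", treatment = NA_character_,
                             qc = NULL) {
  stopifnot(length(fields) >= 1,
            all(vapply(fields, inherits, logical(1), "field_result")))
  counts <- Reduce(`+`, lapply(fields, `[[`, "class_counts"))
  n_cells <- sum(counts)
  total_conc <- mean(vapply(fields, `[[`, numeric(1), "concentration"))
  flags <- check_capture(length(fields), n_cells, settings)
  if (n_cells == 0) {
    flags <- union(flags, "no_cells")
    total_mot <- prog_mot <- NA_real_
    motile_conc <- NA_real_
  } else {
    total_mot <- 100 * (n_cells - counts[["static"]]) / n_cells
    prog_mot <- 100 * counts[["progressive"]] / n_cells
    motile_conc <- total_conc * total_mot / 100
  }
  flags <- union(flags, check_working_range(total_conc, settings))
  if (!is.null(qc)) flags <- union(flags, qc$flags)
  structure(list(sample_id = sample_id,
                 treatment = treatment,
                 n_fields = length(fields),
                 n_cells = n_cells,
                 class_counts = counts,
                 total_motility_pct = total_mot,
                 progressive_motility_pct = prog_mot,
                 total_concentration = total_conc,
                 motile_concentration = motile_conc,
                 qc_flags = sort(flags)),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("sample '%s'%s: %d fields, %d cells\n", x$sample_id,
              if (is.na(x$treatment)) "" else paste0(" [", x$treatment, "]"),
              x$n_fields, x$n_cells))
  cat(sprintf("  total motility        %s %%\n",
              format(round(x$total_motility_pct, 1))))
  cat(sprintf("  progressive motility  %s %%\n",
              format(round(x$progressive_motility_pct, 1))))
  cat(sprintf("  total concentration   %s cells/mL\n",
              format(signif(x$total_concentration, 3))))
  cat(sprintf("  motile concentration  %s cells/mL\n",
              format(signif(x$motile_concentration, 3))))
  if (length(x$qc_flags))
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Haemocytometer concentration
#'
#' Implements the counting-chamber equation literally as
#' `Concentration = CC x N x CD x D` cells/mL, with `CC` the cell count,
#' `N` the number of haemocytometer cells counted (each a grouping of 16
#' smallest squares; at least 3 recommended), `CD` the chamber-depth
#' factor and `D` the dilution.  Multiplying (rather than averaging over)
#' `N` is unusual for a total count; the conventional reading, with `CC`
#' the total count averaged over the `N` chamber cells, is available as
#' `mode = "mean_per_cell"` (`CC / N x CD x D`).  Neither is silently
#' corrected.
#'
#' @param cc cell count.
#' @param n number of haemocytometer cells counted (>= 3 recommended).
#' @param cd chamber-depth factor.
#' @param d dilution factor.
#' @param mode `"literal"` (default) or `"mean_per_cell"`.
#' @return concentration, cells/mL.
#' @examples
#' haemocytometer_concentration(50, 3, 1e4, 2)  # 3e6
#' @export
haemocytometer_concentration <- function(cc, n, cd, d,
                                         mode = c("literal",
                                                  "mean_per_cell")) {
  mode <- match.arg(mode)
  if (any(c(cc, n, cd, d) <= 0))
    stopf("all haemocytometer factors must be strictly positive")
  if (n < 3)
    warning("fewer than 3 haemocytometer cells counted", call. = FALSE)
  if (mode == "literal") cc * n * cd * d else cc / n * cd * d
}

#' Flow-cytometer concentration
#'
#' Converts a gated event count from a fixed acquisition volume into
#' cells/mL: `events x dilution x (1000 / acquisition volume in uL)`.  At
#' the default 10 uL acquisition the per-mL factor is exactly 100.
#'
#' @param gated_events events inside the sperm gate (debris excluded).
#' @param dilution dilution factor of the analysed aliquot.
#' @param acquisition_volume_ul acquired volume, uL (default 10).
#' @return concentration, cells/mL.
#' @examples
#' flow_concentration(1e4, 2)  # 2e6 cells/mL
#' @export
flow_concentration <- function(gated_events, dilution = 1,
                               acquisition_volume_ul = 10) {
  if (acquisition_volume_ul <= 0)
    stopf("acquisition volume must be positive")
  if (gated_events < 0 || dilution <= 0)
    stopf("events must be >= 0 and dilution positive")
  gated_events * dilution * (1000 / acquisition_volume_ul)
}

#' Plan a dilution into the instrument working range
#'
#' Finds the smallest dilution factor (>= 1) bringing a sample into a
#' target concentration range.  By default factors are restricted to serial
#' ten-fold dilutions (`series = 10`), matching bench practice; pass
#' `series = NULL` for the exact minimal factor.  A sample already in range
#' needs factor 1; a sample below range cannot be concentrated and is
#' reported as such.
#'
#' @param current_conc current concentration, cells/mL.
#' @param target_range length-2 range, cells/mL (e.g. the ideal CASA band
#'   `c(1e7, 3e7)`).
#' @param series base of the dilution series (default 10), or `NULL` for a
#'   continuous factor.
#' @return list of class `dilution_plan`: `status` (`"ok"`,
#'   `"below_range"` or `"no_series_factor"`), `factor`, `resulting_conc`.
#' @examples
#' dilution_plan(1e9, c(1e7, 3e7))$factor  # 100
#' @export
dilution_plan <- function(current_conc, target_range, series = 10) {
  if (current_conc <= 0) stopf("concentration must be positive")
  if (length(target_range) != 2 || target_range[1] <= 0 ||
      target_range[1] >= target_range[2])
    stopf("target_range must be a non-empty increasing positive range")
  mk <- function(status, factor) {
    structure(list(status = status, factor = factor,
                   resulting_conc = if (is.na(factor)) NA_real_
                                    else current_conc / factor),
              class = "dilution_plan")
  }
  if (current_conc < target_range[1]) return(mk("below_range", NA_real_))
  if (current_conc <= target_range[2]) return(mk("ok", 1))
  f_min <- current_conc / target_range[2]
  if (is.null(series)) return(mk("ok", f_min))
  f <- series^ceiling(log(f_min, base = series) - 1e-12)
  if (current_conc / f >= target_range[1]) return(mk("ok", f))
  # the series overshoots past the bottom of the band; report the exact
  # minimal factor instead of silently leaving the sample out of range
  mk("no_series_factor", f_min)
}

#' @export
print.dilution_plan <- function(x, ...) {
  if (x$status == "below_range")
    cat("sample is below the target range and cannot be concentrated\n")
  else
    cat(sprintf("dilute 1:%s -> %s cells/mL%s\n",
                format(x$factor, digits = 4),
                format(signif(x$resulting_conc, 3)),
                if (x$status == "no_series_factor")
                  " (no serial-dilution factor lands in range)" else ""))
  invisible(x)
}
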