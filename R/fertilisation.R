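#' Motile sperm added per egg
#'
#' The dose statistic of a fertilisation cross: motile cells delivered in
#' the sperm aliquot divided by the number of eggs,
#' `motile_concentration x volume(mL) / n_eggs`.
#'
#' @param motile_concentration motile sperm concentration, cells/mL.
#' @param sperm_volume_ul sperm aliquot volume, uL.
#' @param n_eggs number of eggs (>= 1).
#' @return motile cells per egg.
#' @examples
#' egg_sperm_ratio(2.4e7, 50, 100)  # 1.2e4 cells/egg
#' @export
egg_sperm_ratio <- function(motile_concentration, sperm_volume_ul, n_eggs) {
  if (any(n_eggs < 1)) stopf("n_eggs must be at least 1")
  if (any(sperm_volume_ul <= 0)) stopf("sperm volume must be positive")
  if (any(motile_concentration < 0))
    stopf("motile concentration must be >= 0")
  motile_concentration * sperm_volume_ul * 1e-3 / n_eggs
}

#' Sperm volume required for a target dose
#'
#' Inverse of [egg_sperm_ratio()]: the aliquot volume delivering a target
#' number of motile cells per egg.  Standardising the motile dose is the
#' practical lever for reliable fertilisation with frozen-thawed sperm,
#' whose motile concentration is typically an order of magnitude below
#' fresh samples.
#'
#' @param target_ratio desired motile cells per egg.
#' @param motile_concentration motile sperm concentration, cells/mL (> 0).
#' @param n_eggs number of eggs.
#' @return required volume, uL.
#' @examples
#' required_volume(5e3, 2e6, 100)  # 250 uL
#' @export
required_volume <- function(target_ratio, motile_concentration, n_eggs) {
  if (any(motile_concentration <= 0))
    stopf("motile concentration must be positive")
  if (any(n_eggs < 1)) stopf("n_eggs must be at least 1")
  if (any(target_ratio < 0)) stopf("target ratio must be >= 0")
  target_ratio * n_eggs / motile_concentration * 1e3
}

#' Fertilisation rate from cleavage counts
#'
#' @param n_cleaved,n_uncleaved counts of cleaved and uncleaved eggs
#'   (total >= 1).
#' @return percentage of eggs cleaved.
#' @export
fertilisation_rate <- function(n_cleaved, n_uncleaved) {
  if (any(n_cleaved < 0) || any(n_uncleaved < 0))
    stopf("egg counts must be non-negative")
  total <- n_cleaved + n_uncleaved
  if (any(total < 1)) stopf("at least one scored egg is required")
  100 * n_cleaved / total
}

#' Correlation between fertilisation success and log motile dose
#'
#' Fertilisation success plotted against motile sperm per egg follows a
#' logarithmic trend, so the dose is log10-transformed before a Pearson
#' correlation and least-squares line are computed.  Records must carry
#' cleavage outcomes and a strictly positive dose; zero-dose records are
#' rejected with an error (they have no logarithm and belong in a no-sperm
#' control, not a dose-response fit).
#'
#' @param records data.frame with `motile_concentration`, `sperm_volume_ul`,
#'   `n_eggs`, `n_cleaved`, `n_uncleaved` (the [synth_fert_dataset()]
#'   layout).
#' @return list of class `fert_correlation`: `r`, `p_value`, `intercept`,
#'   `slope` (success points per log10 cells/egg), `n`.
#' @export
fert_correlation <- function(records) {
  req <- c("motile_concentration", "sperm_volume_ul", "n_eggs",
           "n_cleaved", "n_uncleaved")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(records) < 3)
    stopf("at least 3 records with outcomes are required")
  ratio <- egg_sperm_ratio(records$motile_concentration,
                           records$sperm_volume_ul, records$n_eggs)
  if (any(ratio <= 0))
    stopf("all records must have a positive motile dose (cells/egg)")
  x <- log10(ratio)
  y <- fertilisation_rate(records$n_cleaved, records$n_uncleaved)
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(list(r = unname(ct$estimate),
                 p_value = ct$p.value,
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 n = length(x)),
            class = "fert_correlation")
}

#' @export
print.fert_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.4f (p = %.3g, n = %d)\nfit: success = %.2f %+.2f x log10(motile cells/egg)\n",
    x$r, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}
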