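#' Double-logarithmic binding isotherm fit
#'
#' Estimates the binding constant Kb and the number of binding sites n from
#' quenching data via base-10 OLS of log10((F0 - F)/F) on log10([Q]):
#' the intercept gives log10(Kb) and the slope gives n. Points with F >= F0
#' (no quenching, so (F0 - F)/F <= 0) are excluded with a warning.
#'
#' @param points A data frame with columns `quencher_M` and `F0_over_F`
#'   (e.g. from [stern_volmer_points()]). All concentrations must be
#'   strictly positive.
#' @param temperature_K Temperature of the titration, stored in the result.
#'
#' @return An object of class `"binding_fit"`: list with `Kb` (reported in
#'   the customary 1/M convention even when n != 1, in which case Kb is
#'   dimensionally 1/M^n -- see Details), `n_sites`, `log10_Kb`,
#'   `stderr_log10_Kb`, `stderr_n`, `r2`, `points_used`, `points_excluded`,
#'   `temperature_K` and the regression data. Supports [generics::tidy()]
#'   and [generics::glance()].
#'
#' @details Concentrations enter the regression in molar; because Kb's
#'   magnitude depends on the concentration unit whenever n != 1, the fitted
#'   Kb is only comparable across studies that use the same unit. This is
#'   the convention of the quenching literature and is flagged in the
#'   object's `unit_caveat` field.
#' @examples
#' tr <- generate_titration(ground_truth(), model = "binding_isotherm",
#'                          rel_sigma = 0)
#' fit_double_log(stern_volmer_points(tr))
#' @export
fit_double_log <- function(points, temperature_K = NULL) {
  df <- as_tibble(points)
  names(df)[names(df) == "Q"] <- "quencher_M"
  names(df)[names(df) == "ratio"] <- "F0_over_F"
  if (is.null(temperature_K)) {
    temperature_K <- attr(points, "temperature_K") %||% NA_real_
  }
  if (any(df$quencher_M <= 0)) {
    abort("zero or negative quencher concentration in binding fit input.")
  }
  quenched <- df$F0_over_F > 1
  excluded <- sum(!quenched)
  if (excluded > 0) {
    warn(sprintf("%d point(s) with F >= F0 excluded from the double-log fit.",
                 excluded))
  }
  df <- df[quenched, , drop = FALSE]
  if (nrow(df) < 3) {
    abort("fewer than 3 admissible (quenched) points for the double-log fit.")
  }
  x <- log10(df$quencher_M)
  y <- log10(df$F0_over_F - 1)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless data: 'perfect fit' warning is expected
  log10_Kb <- unname(coef(fit)[1])
  structure(
    list(Kb = 10^log10_Kb,
         n_sites = unname(coef(fit)[2]),
         log10_Kb = log10_Kb,
         stderr_log10_Kb = unname(sm$coefficients[1, 2]),
         stderr_n = unname(sm$coefficients[2, 2]),
         r2 = sm$r.squared,
         points_used = nrow(df),
         points_excluded = excluded,
         temperature_K = temperature_K,
         unit_caveat = "Kb reported in 1/M; dimensionally 1/M^n when n != 1.",
         data = tibble(log10_Q = x, log10_dF_over_F = y)),
    class = "binding_fit"
  )
}
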