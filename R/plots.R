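#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_vline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a titration series
#'
#' Overlays every scan of a spectral titration, coloured by quencher
#' concentration (in micromolar).
#'
#' @param object A [titration_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.titration_series <- function(object, ...) {
  if (isTRUE(attr(object, "peak_only"))) {
    return(ggplot(as_tibble(object),
                  aes(x = .data$quencher_M * 1e6, y = .data$intensity)) +
             geom_point() + geom_line() +
             labs(x = "[Q] (uM)", y = "Peak intensity (a.u.)") +
             theme_minimal())
  }
  df <- dplyr::mutate(as_tibble(object), Q_uM = .data$quencher_M * 1e6)
  ggplot(df, aes(x = .data$wavelength_nm, y = .data$intensity,
                 group = .data$Q_uM, colour = .data$Q_uM)) +
    geom_line() +
    labs(x = "Wavelength (nm)", y = "Intensity (a.u.)",
         colour = "[Q] (uM)",
         title = sprintf("%s titration at %g K", attr(object, "mode"),
                         attr(object, "temperature_K"))) +
    theme_minimal()
}

#' Plot a Stern-Volmer fit
#'
#' F0/F against quencher concentration with the fitted line of each regime
#' and the breakpoint marked.
#'
#' @param object An `sv_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_fit <- function(object, ...) {
  pts <- dplyr::mutate(object$points, Q_uM = .data$quencher_M * 1e6)
  seg <- purrr::pmap_dfr(object$regimes, function(conc_lo, conc_hi, K_SV,
                                                  intercept, ...) {
    q <- seq(conc_lo, conc_hi, length.out = 20)
    tibble(Q_uM = q * 1e6, fit = intercept + K_SV * q)
  })
  p <- ggplot(pts, aes(x = .data$Q_uM, y = .data$F0_over_F)) +
    geom_point() +
    geom_line(data = seg, aes(x = .data$Q_uM, y = .data$fit),
              colour = "steelblue", inherit.aes = FALSE) +
    labs(x = "[Q] (uM)", y = "F0/F", title = "Stern-Volmer plot") +
    theme_minimal()
  if (is.finite(object$breakpoint)) {
    p <- p + geom_vline(xintercept = object$breakpoint * 1e6,
                        linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a van't Hoff fit
#'
#' ln(Kb) against 1/T with the fitted line.
#'
#' @param object A `vant_hoff_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vant_hoff_fit <- function(object, ...) {
  slope <- -object$dH / R_GAS
  intercept <- object$dS / R_GAS
  ggplot(object$data, aes(x = .data$inv_T, y = .data$ln_Kb)) +
    geom_point() +
    ggplot2::geom_abline(slope = slope, intercept = intercept,
                         colour = "steelblue") +
    labs(x = "1/T (1/K)", y = "ln Kb", title = "van't Hoff plot") +
    theme_minimal()
}

#' Plot a melting analysis
#'
#' The smoothed first derivative dF/dT with the refined Tm marked.
#'
#' @param object A `tm_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tm_result <- function(object, ...) {
  ggplot(object$derivative, aes(x = .data$temperature_C, y = .data$dF_dT)) +
    geom_line() +
    geom_vline(xintercept = object$Tm_C, linetype = "dashed",
               colour = "firebrick") +
    labs(x = "Temperature (C)", y = "dF/dT",
         title = sprintf("First-derivative melt, Tm = %.2f C", object$Tm_C)) +
    theme_minimal()
}

#' Plot a synchronous shift series
#'
#' Peak shift against quencher concentration with the verdict threshold.
#'
#' @param object A `shift_series` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.shift_series <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot(as_tibble(object),
         aes(x = .data$quencher_M * 1e6, y = .data$shift_nm)) +
    geom_point() + geom_line() +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted",
                        colour = "grey50") +
    labs(x = "[Q] (uM)", y = "Peak shift (nm)",
         title = sprintf("Synchronous shift (verdict: %s)",
                         attr(object, "verdict"))) +
    theme_minimal()
}
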