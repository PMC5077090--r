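#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Stern-Volmer fit
#'
#' One row per regime with its concentration range, K_SV, standard error,
#' intercept (and its deviation from the theoretical value 1) and R^2.
#'
#' @param x An `sv_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sv_fit <- function(x, ...) {
  dplyr::mutate(x$regimes,
                regime = dplyr::row_number(),
                kq = bimolecular_rate(.data$K_SV, x$tau0),
                intercept_dev = .data$intercept - 1,
                .before = 1)
}

#' Glance at a Stern-Volmer fit
#' @inheritParams tidy.sv_fit
#' @return One-row tibble with the breakpoint, point count, single- and
#'   two-line residual sums of squares and tau0.
#' @exportS3Method generics::glance
glance.sv_fit <- function(x, ...) {
  tibble(n_points = x$n_points, n_regimes = nrow(x$regimes),
         breakpoint_M = x$breakpoint, rss_single = x$rss_single,
         rss_two = x$rss_two, tau0_s = x$tau0,
         force_unit_intercept = x$force_unit_intercept)
}

#' Tidy a double-log binding fit
#' @param x A `binding_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`log10_Kb`, `n_sites`).
#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("log10_Kb", "n_sites"),
         estimate = c(x$log10_Kb, x$n_sites),
         std.error = c(x$stderr_log10_Kb, x$stderr_n))
}

#' Glance at a double-log binding fit
#' @inheritParams tidy.binding_fit
#' @return One-row tibble with Kb, n, R^2, the point counts and the unit
#'   caveat.
#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(temperature_K = x$temperature_K, Kb = x$Kb, n_sites = x$n_sites,
         r.squared = x$r2, points_used = x$points_used,
         points_excluded = x$points_excluded)
}

#' Tidy a van't Hoff fit
#' @param x A `vant_hoff_fit` object.
#' @param ... Unused.
#' @return A tibble with rows `dH` (J/mol) and `dS` (J/(mol K)).
#' @exportS3Method generics::tidy
tidy.vant_hoff_fit <- function(x, ...) {
  tibble(term = c("dH", "dS"),
         estimate = c(x$dH, x$dS),
         std.error = c(x$stderr_dH, x$stderr_dS))
}

#' Glance at a van't Hoff fit
#' @inheritParams tidy.vant_hoff_fit
#' @return One-row tibble with R^2 and the number of temperatures.
#' @exportS3Method generics::glance
glance.vant_hoff_fit <- function(x, ...) {
  tibble(r.squared = x$r2, n_temperatures = x$n_temperatures)
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%d points, %s)\n", x$n_points,
              if (is.na(x$breakpoint)) "single regime"
              else sprintf("breakpoint %g M", x$breakpoint)))
  print(tidy(x))
  invisible(x)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %s K: Kb = %.4g 1/M, n = %.3g (R^2 = %.4f)\n",
              format(x$temperature_K), x$Kb, x$n_sites, x$r2))
  cat(" ", x$unit_caveat, "\n")
  invisible(x)
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit over %d temperatures: dH = %.4g kJ/mol, dS = %.4g J/(mol K) (R^2 = %.4f)\n",
              x$n_temperatures, x$dH / 1e3, x$dS, x$r2))
  invisible(x)
}

#' @export
print.quench_class <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (linear SV plot: %s)\n",
              x$mechanism, x$linear))
  print(x$kq)
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("First-derivative melting temperature: Tm = %.2f C\n", x$Tm_C))
  invisible(x)
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Thermodynamic profile: dH = %.4g kJ/mol, dS = %.4g J/(mol K), %s\n",
              x$dH / 1e3, x$dS, x$force_class))
  print(x$dG_by_T)
  invisible(x)
}
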