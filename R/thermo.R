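#' van't Hoff fit of binding constants across temperature
#'
#' OLS of ln(Kb) on 1/T. Assuming temperature-independent enthalpy and
#' entropy, the slope equals -dH/R and the intercept dS/R, so
#' dH = -slope * R and dS = intercept * R with R = 8.314 J/(mol K).
#'
#' @param kb_by_T A data frame with columns `temperature_K` and `Kb` (1/M),
#'   at least two distinct temperatures, all Kb > 0. A warning is issued
#'   with exactly two temperatures (zero residual degrees of freedom).
#' @return An object of class `"vant_hoff_fit"`: list with `dH` (J/mol),
#'   `dS` (J/(mol K)), `stderr_dH`, `stderr_dS`, `r2`, `n_temperatures` and
#'   the regression `data`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' kb <- generate_temperature_series(
#'   ground_truth(thermo = list(dH = -50e3, dS = -100)))
#' vant_hoff_fit(kb)
#' @export
vant_hoff_fit <- function(kb_by_T) {
  df <- as_tibble(kb_by_T)
  names(df)[names(df) %in% c("T", "T_K")] <- "temperature_K"
  if (!all(c("temperature_K", "Kb") %in% names(df))) {
    abort("`kb_by_T` needs `temperature_K` and `Kb` columns.")
  }
  if (any(!is.finite(df$Kb)) || any(df$Kb <= 0)) {
    abort("all binding constants must be positive and finite.")
  }
  df <- dplyr::distinct(df)
  if (length(unique(df$temperature_K)) < 2) {
    abort("need at least 2 distinct temperatures for a van't Hoff fit.")
  }
  if (length(unique(df$temperature_K)) == 2) {
    warn("only 2 temperatures: van't Hoff fit has no residual degrees of freedom.")
  }
  x <- 1 / df$temperature_K
  y <- log(df$Kb)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless data: 'perfect fit' warning is expected
  se <- sm$coefficients[, 2]
  structure(
    list(dH = -unname(coef(fit)[2]) * R_GAS,
         dS = unname(coef(fit)[1]) * R_GAS,
         stderr_dH = unname(se[2]) * R_GAS,
         stderr_dS = unname(se[1]) * R_GAS,
         r2 = sm$r.squared,
         n_temperatures = nrow(df),
         data = tibble(temperature_K = df$temperature_K,
                       inv_T = x, ln_Kb = y)),
    class = "vant_hoff_fit"
  )
}

#' Gibbs free energy from the Gibbs-Helmholtz relation
#'
#' dG = dH - T * dS. A negative dG marks spontaneous binding.
#'
#' @param dH Enthalpy change, J/mol.
#' @param dS Entropy change, J/(mol K).
#' @param temperature_K Temperature(s) in kelvin, all positive.
#' @return dG in J/mol, vectorised over `temperature_K`.
#' @examples
#' gibbs_free_energy(-90.89e3, -282.11, c(298, 310, 315)) / 1e3  # kJ/mol
#' @export
gibbs_free_energy <- function(dH, dS, temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    abort("`temperature_K` must be positive.")
  }
  dH - temperature_K * dS
}

#' Classify the dominant interaction forces from thermodynamic signs
#'
#' Sign-based (Ross-Subramanian) assignment: dH < 0 and dS < 0 indicate
#' hydrogen bonding and van der Waals contacts; dH > 0 and dS > 0 indicate
#' hydrophobic interactions; dH < 0 with dS > 0 indicates electrostatic
#' forces. Any other pattern (including magnitudes inside the noise guard
#' `epsilon`) is `"unclassified"`.
#'
#' @param dH Enthalpy change, J/mol.
#' @param dS Entropy change, J/(mol K).
#' @param epsilon Noise guard in J/mol: |dH| must exceed `epsilon` and |dS|
#'   must exceed `epsilon / 298.15` (the same energy scale spread over a
#'   room-temperature kelvin) before a sign is trusted. Default 100 J/mol.
#' @return One of `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"unclassified"`, vectorised over the inputs.
#' @examples
#' classify_forces(-90.89e3, -282.11)  # "hbond_vdw"
#' @export
classify_forces <- function(dH, dS, epsilon = 100) {
  eps_S <- epsilon / 298.15
  dplyr::case_when(
    !is.finite(dH) | !is.finite(dS) ~ "unclassified",
    dH < -epsilon & dS < -eps_S ~ "hbond_vdw",
    dH > epsilon & dS > eps_S ~ "hydrophobic",
    dH < -epsilon & dS > eps_S ~ "electrostatic",
    .default = "unclassified"
  )
}

#' Full thermodynamic profile from binding constants
#'
#' Runs [vant_hoff_fit()], evaluates [gibbs_free_energy()] at each input
#' temperature, flags spontaneity (dG < 0) and classifies the dominant
#' forces.
#'
#' @inheritParams vant_hoff_fit
#' @param temperatures_K Temperatures at which to report dG; default the
#'   temperatures of `kb_by_T`.
#' @param epsilon Passed to [classify_forces()].
#' @return An object of class `"thermo_result"`: list with the
#'   `vant_hoff` fit, `dH`, `dS`, `dG_by_T` (tibble `temperature_K`, `dG`,
#'   `spontaneous`), `force_class` and `r2`.
#' @export
thermo_profile <- function(kb_by_T, temperatures_K = NULL, epsilon = 100) {
  fit <- vant_hoff_fit(kb_by_T)
  if (is.null(temperatures_K)) temperatures_K <- fit$data$temperature_K
  dG <- gibbs_free_energy(fit$dH, fit$dS, temperatures_K)
  structure(
    list(vant_hoff = fit, dH = fit$dH, dS = fit$dS,
         dG_by_T = tibble(temperature_K = temperatures_K, dG = dG,
                          spontaneous = dG < 0),
         force_class = classify_forces(fit$dH, fit$dS, epsilon = epsilon),
         r2 = fit$r2),
    class = "thermo_result"
  )
}

#' Compare a van't Hoff fit against externally reported dH/dS
#'
#' Diagnostic for reconciling fitted thermodynamic parameters with values
#' quoted elsewhere (e.g. a publication or an earlier analysis): reports the
#' relative differences and warns when either parameter disagrees beyond
#' `rel_tol`, since that means the quoted values cannot have come from an
#' OLS van't Hoff fit of the same binding constants.
#'
#' @param fit A [vant_hoff_fit()] result.
#' @param dH_ref,dS_ref Reference values, J/mol and J/(mol K).
#' @param rel_tol Relative tolerance for agreement, default 0.05.
#' @return A tibble with one row per parameter (`estimate`, `reference`,
#'   `rel_diff`, `consistent`), with attribute `"consistent"` summarising
#'   both rows. A warning is emitted on inconsistency.
#' @export
vant_hoff_consistency <- function(fit, dH_ref, dS_ref, rel_tol = 0.05) {
  if (!inherits(fit, "vant_hoff_fit")) abort("`fit` must be a vant_hoff_fit.")
  est <- c(dH = fit$dH, dS = fit$dS)
  ref <- c(dH = dH_ref, dS = dS_ref)
  rel <- abs(est - ref) / pmax(abs(ref), .Machine$double.eps)
  out <- tibble(parameter = names(est), estimate = unname(est),
                reference = unname(ref), rel_diff = unname(rel),
                consistent = unname(rel <= rel_tol))
  ok <- all(out$consistent)
  if (!ok) {
    warn(sprintf(
      paste0("van't Hoff discrepancy: OLS estimates (dH = %.4g J/mol, ",
             "dS = %.4g J/(mol K)) do not reproduce the reference values ",
             "(dH = %.4g, dS = %.4g) within %.0f%%."),
      fit$dH, fit$dS, dH_ref, dS_ref, 100 * rel_tol))
  }
  structure(out, consistent = ok)
}
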