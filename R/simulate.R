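#' Ground-truth parameter set for the synthetic-data generator
#'
#' Bundles every parameter the generators draw on, so that a generated
#' dataset always travels with the truth that produced it and recovery can
#' be tested exactly. Call with nested lists to override any subset; the
#' rest keep their defaults.
#'
#' Defaults describe a lysozyme-like titration: a two-regime Stern-Volmer
#' law with K_SV1 = 2.925e4 1/M up to 15 uM and K_SV2 = 3.492e3 1/M above, a
#' weak isotherm Kb = 105.07 1/M with n = 0.56 binding sites, exothermic
#' binding (dH = -90.89 kJ/mol, dS = -282.11 J/(mol K)), a Gaussian
#' tryptophan emission band at 340 nm (sigma 25 nm, 300-450 nm grid),
#' narrower synchronous bands (sigma 15 nm at 280/290 nm for the 60/15 nm
#' offsets), a 5 nm red drift of the tryptophan band at the highest
#' quencher concentration, a two-state melt with Tm = 71.25 C and a van't
#' Hoff enthalpy of 400 kJ/mol over linear baselines, an ANS response
#' plateauing at 300% of control above 15 uM, a far-UV CD target MRE208 of
#' -15000 deg cm^2/dmol, and 1% multiplicative intensity noise.
#'
#' @param ... Named nested lists (`sv`, `binding`, `thermo`, `band`,
#'   `sync`, `drift`, `melting`, `ans`, `cd`, `noise`) merged over the
#'   defaults with [utils::modifyList()].
#' @return A list of class `"ground_truth"`.
#' @examples
#' ground_truth(melting = list(Tm = 65.48))$melting$Tm
#' @export
ground_truth <- function(...) {
  defaults <- list(
    sv = list(K_SV = c(29.25e3, 34.92e2), breakpoints = 15e-6),
    binding = list(Kb = 105.07, n = 0.56),
    thermo = list(dH = -90.89e3, dS = -282.11),
    band = list(center = 340, width = 25, amplitude = 1000,
                grid = c(300, 450), step = 1),
    sync = list(center60 = 280, center15 = 290, width = 15,
                grid = c(250, 400), step = 1),
    drift = 5,
    melting = list(Tm = 71.25, dH_m = 4e5,
                   F_f = 1000, m_f = -2, F_u = 250, m_u = -0.5),
    ans = list(onset = 15e-6, plateau_pct = 300,
               center = 480, width = 40, grid = c(400, 600), step = 1),
    cd = list(MRE208 = -15000),
    noise = list(rel_sigma = 0.01)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf("unknown ground-truth component(s): %s",
                  paste(bad, collapse = ", ")))
  }
  truth <- modifyList(defaults, overrides)
  structure(truth, class = "ground_truth")
}

## Piecewise-continuous two-regime Stern-Volmer law: F0/F as a function of Q.
.sv_ratio_law <- function(Q, K, breaks) {
  edges <- c(0, breaks, Inf)
  base <- 1 + cumsum(c(0, K[-length(K)] * diff(edges[seq_along(K)])))
  seg <- findInterval(Q, edges, left.open = TRUE, rightmost.closed = FALSE)
  seg[Q == 0] <- 1L
  base[seg] + K[seg] * (Q - edges[seg])
}

.maybe_seeded <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

## Gaussian band scan over a grid, with multiplicative noise already applied
## by the caller through `noise_mult`.
.band_scan <- function(grid, center, width, peak) {
  peak * exp(-(grid - center)^2 / (2 * width^2))
}

.grid_of <- function(spec) seq(spec$grid[1], spec$grid[2], by = spec$step)

.noise_factors <- function(n, rel_sigma) {
  if (rel_sigma == 0) rep(1, n) else 1 + stats::rnorm(n, 0, rel_sigma)
}

#' Generate a synthetic quenching titration
#'
#' Builds a full spectral titration whose peak intensities obey either the
#' piecewise two-regime Stern-Volmer law F0/F = 1 + K_SV,j (Q - b_j) + ...
#' (continuous across breakpoints) or the binding isotherm
#' (F0 - F)/F = Kb * Q^n. Each scan is a Gaussian emission band on the
#' truth's grid; multiplicative Gaussian noise of relative width
#' `rel_sigma` is applied per grid point.
#'
#' @param truth A [ground_truth()].
#' @param concentrations Quencher concentrations in molar, including 0.
#' @param temperature_K Temperature stored in the series.
#' @param model `"sv_two_regime"` or `"binding_isotherm"`.
#' @param rel_sigma Relative noise; default from `truth$noise$rel_sigma`.
#' @param seed Optional integer; fixes every stochastic draw (the RNG state
#'   is restored afterwards).
#' @return A [titration_series()] with the truth attached as attribute
#'   `"ground_truth"`.
#' @export
generate_titration <- function(truth,
                               concentrations = c(0, 2, 4, 8, 15, 30, 50, 100) * 1e-6,
                               temperature_K = 298,
                               model = c("sv_two_regime", "binding_isotherm"),
                               rel_sigma = truth$noise$rel_sigma,
                               seed = NULL) {
  model <- match.arg(model)
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth.")
  if (!any(concentrations == 0)) {
    abort("`concentrations` must include the zero-quencher control.")
  }
  ratio <- switch(
    model,
    sv_two_regime = {
      if (is.null(truth$sv$K_SV)) abort("truth lacks `sv` parameters for sv_two_regime.")
      .sv_ratio_law(concentrations, truth$sv$K_SV, truth$sv$breakpoints)
    },
    binding_isotherm = {
      if (is.null(truth$binding$Kb)) abort("truth lacks `binding` parameters.")
      1 + truth$binding$Kb * concentrations^truth$binding$n
    }
  )
  peaks <- truth$band$amplitude / ratio
  grid <- .grid_of(truth$band)
  .maybe_seeded(seed, {
    df <- purrr::map2_dfr(concentrations, peaks, function(q, pk) {
      tibble(quencher_M = q, wavelength_nm = grid,
             intensity = .band_scan(grid, truth$band$center, truth$band$width, pk) *
               .noise_factors(length(grid), rel_sigma))
    })
    out <- titration_series(df, mode = "emission",
                            temperature_K = temperature_K,
                            excitation_nm = 285)
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Generate van't Hoff-consistent binding constants across temperature
#'
#' Kb(T) = exp(-dH/(R T) + dS/R) from the truth's thermodynamic parameters.
#'
#' @param truth A [ground_truth()].
#' @param temperatures_K Temperatures in kelvin, all positive.
#' @return A tibble with columns `temperature_K` and `Kb`.
#' @export
generate_temperature_series <- function(truth,
                                        temperatures_K = c(298, 310, 315)) {
  if (any(temperatures_K <= 0)) abort("temperatures must be positive.")
  tibble(temperature_K = temperatures_K,
         Kb = exp(-truth$thermo$dH / (R_GAS * temperatures_K) +
                    truth$thermo$dS / R_GAS))
}

#' Generate a two-state thermal melting curve
#'
#' F(T) = (F_f + m_f T + (F_u + m_u T) K(T)) / (1 + K(T)) with the two-state
#' equilibrium K(T) = exp(-dH_m/R (1/T - 1/Tm)) (temperatures in kelvin
#' inside K), i.e. folded and unfolded linear baselines mixed by the
#' unfolded fraction. Multiplicative noise as in [generate_titration()].
#'
#' @param truth A [ground_truth()]; `truth$melting` supplies Tm (deg C),
#'   dH_m (J/mol) and the baseline parameters.
#' @param t_range Scan range in degrees Celsius; must contain Tm.
#' @param step Scan step in degrees Celsius.
#' @inheritParams generate_titration
#' @return A [melting_curve()] with the truth attached as attribute
#'   `"ground_truth"`.
#' @export
generate_melting_curve <- function(truth, t_range = c(25, 90), step = 1,
                                   rel_sigma = truth$noise$rel_sigma,
                                   seed = NULL) {
  m <- truth$melting
  if (m$Tm <= t_range[1] || m$Tm >= t_range[2]) {
    abort("Tm must lie inside `t_range`.")
  }
  tc <- seq(t_range[1], t_range[2], by = step)
  tk <- tc + 273.15
  K <- exp(-m$dH_m / R_GAS * (1 / tk - 1 / (m$Tm + 273.15)))
  f <- ((m$F_f + m$m_f * tc) + (m$F_u + m$m_u * tc) * K) / (1 + K)
  .maybe_seeded(seed, {
    out <- melting_curve(tc, f * .noise_factors(length(f), rel_sigma))
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Generate a synchronous-scan titration with an optional band drift
#'
#' At the tryptophan offset (delta_lambda = 60 nm) the band centre moves
#' linearly in concentration from the truth's centre to centre + drift at
#' the highest concentration; at the tyrosine offset (15 nm) it stays
#' fixed. Peak intensities are quenched by the truth's Stern-Volmer law.
#'
#' @param truth A [ground_truth()]; `truth$drift` is the total centre
#'   displacement in nm at the maximum concentration (negative for a blue
#'   drift).
#' @param delta_lambda Scan offset, 15 or 60 nm.
#' @inheritParams generate_titration
#' @return A [titration_series()] in the matching synchronous mode.
#' @export
generate_sync_series <- function(truth, delta_lambda = 60,
                                 concentrations = c(0, 2, 4, 8, 10, 15, 30, 50, 100) * 1e-6,
                                 rel_sigma = truth$noise$rel_sigma,
                                 seed = NULL) {
  if (!delta_lambda %in% c(15, 60)) abort("`delta_lambda` must be 15 or 60.")
  if (!any(concentrations == 0)) {
    abort("`concentrations` must include the zero-quencher control.")
  }
  center0 <- if (delta_lambda == 60) truth$sync$center60 else truth$sync$center15
  drift <- if (delta_lambda == 60) truth$drift else 0
  centers <- center0 + drift * concentrations / max(concentrations)
  ratio <- .sv_ratio_law(concentrations, truth$sv$K_SV, truth$sv$breakpoints)
  peaks <- truth$band$amplitude / ratio
  grid <- .grid_of(truth$sync)
  .maybe_seeded(seed, {
    df <- purrr::pmap_dfr(list(concentrations, centers, peaks),
                          function(q, ct, pk) {
      tibble(quencher_M = q, wavelength_nm = grid,
             intensity = .band_scan(grid, ct, truth$sync$width, pk) *
               .noise_factors(length(grid), rel_sigma))
    })
    out <- titration_series(df,
                            mode = paste0("synchronous", delta_lambda),
                            temperature_K = 298)
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Generate an ANS probe titration with a saturation plateau
#'
#' The percent-of-control response rises linearly from 100% at zero
#' quencher to `plateau_pct` at the plateau onset and stays constant beyond
#' it. Scans are Gaussian ANS emission bands (centre ~480 nm) scaled to
#' that response.
#'
#' @param truth A [ground_truth()]; `truth$ans` supplies `onset` (molar),
#'   `plateau_pct` and the band shape.
#' @inheritParams generate_titration
#' @return A [titration_series()] in `"ans"` mode.
#' @export
generate_ans_series <- function(truth,
                                concentrations = c(0, 2, 4, 8, 10, 15, 30, 50, 100) * 1e-6,
                                rel_sigma = truth$noise$rel_sigma,
                                seed = NULL) {
  if (!any(concentrations == 0)) {
    abort("`concentrations` must include the zero-quencher control.")
  }
  a <- truth$ans
  pct <- ifelse(concentrations >= a$onset, a$plateau_pct,
                100 + (a$plateau_pct - 100) * concentrations / a$onset)
  peaks <- truth$band$amplitude * pct / 100
  grid <- .grid_of(a)
  .maybe_seeded(seed, {
    df <- purrr::map2_dfr(concentrations, peaks, function(q, pk) {
      tibble(quencher_M = q, wavelength_nm = grid,
             intensity = .band_scan(grid, a$center, a$width, pk) *
               .noise_factors(length(grid), rel_sigma))
    })
    out <- titration_series(df, mode = "ans", temperature_K = 298,
                            excitation_nm = 350)
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Generate a far-UV CD spectrum with a prescribed MRE at 208 nm
#'
#' A fixed helical double-minimum template (negative bands at 208 and 222
#' nm, positive band near 193 nm) is scaled so that the observed
#' ellipticity at 208 nm equals exactly
#' MRE208 * Cp * n_residues * path_length * 10 millidegrees, inverting the
#' mean-residue-ellipticity relation.
#'
#' @param truth A [ground_truth()]; `truth$cd$MRE208` is the target in
#'   deg cm^2/dmol.
#' @param protein_conc_M,n_residues,path_length_cm Far-UV scan conditions.
#' @inheritParams generate_titration
#' @return A [spectrum()] in `"cd_far"` mode (intensities in millidegrees).
#' @export
generate_cd_spectrum <- function(truth, protein_conc_M = 15e-6,
                                 n_residues = 129, path_length_cm = 0.2,
                                 rel_sigma = 0, seed = NULL) {
  grid <- seq(190, 260, by = 1)
  template <- function(wl) {
    -(exp(-(wl - 208)^2 / (2 * 6.5^2)) + 0.92 * exp(-(wl - 222)^2 / (2 * 8^2))) +
      0.7 * exp(-(wl - 193)^2 / (2 * 4.5^2))
  }
  theta208 <- truth$cd$MRE208 * protein_conc_M * n_residues * path_length_cm * 10
  scale <- theta208 / template(208)
  .maybe_seeded(seed, {
    th <- scale * template(grid) * .noise_factors(length(grid), rel_sigma)
    out <- spectrum(grid, th, mode = "cd_far")
    attr(out, "ground_truth") <- truth
    out
  })
}
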