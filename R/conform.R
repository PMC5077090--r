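#' Track synchronous-fluorescence peak shifts across a titration
#'
#' For a synchronous-scan titration (fixed excitation/emission offset of 15
#' nm for tyrosine or 60 nm for tryptophan) this computes, per quencher
#' concentration, the displacement of the emission maximum relative to the
#' zero-quencher control, lambda_max(Q) - lambda_max(0). The verdict at the
#' highest concentration is `"red"` (solvent exposure) when the final shift
#' exceeds `threshold`, `"blue"` when below `-threshold`, else `"none"`.
#'
#' @param series A spectral [titration_series()] in a synchronous (or
#'   near-UV CD) mode, with the control present and a detectable peak at
#'   every concentration.
#' @param threshold Shift magnitude in nm required for a red/blue verdict;
#'   default 1 nm, below which sub-grid peak refinement is not trusted.
#' @param window Optional wavelength window passed to [peak_intensity()].
#' @return A tibble of class `"shift_series"` with columns `quencher_M`,
#'   `lambda_max` and `shift_nm` (0 at the control by definition);
#'   attributes `delta_lambda` (nm offset of the scan mode, NA for non
#'   synchronous modes), `verdict` and `threshold`.
#' @examples
#' tr <- generate_sync_series(ground_truth(), delta_lambda = 60,
#'                            rel_sigma = 0)
#' shift_series(tr)
#' @export
shift_series <- function(series, threshold = 1, window = NULL) {
  peaks <- series_peaks(series, window = window)
  if (all(is.na(peaks$lambda_max))) {
    abort("shift analysis needs spectral (not peak-only) data.")
  }
  lam0 <- peaks$lambda_max[peaks$quencher_M == 0]
  out <- dplyr::mutate(peaks[, c("quencher_M", "lambda_max")],
                       shift_nm = .data$lambda_max - lam0)
  final <- out$shift_nm[which.max(out$quencher_M)]
  verdict <- if (final > threshold) "red" else if (final < -threshold) "blue" else "none"
  mode <- attr(series, "mode")
  delta <- switch(mode, synchronous15 = 15, synchronous60 = 60, NA_real_)
  structure(out, delta_lambda = delta, verdict = verdict,
            threshold = threshold,
            class = c("shift_series", class(out)))
}

#' Normalise an ANS titration to percent of control
#'
#' ANS (8-anilino-1-naphthalenesulfonate) fluorescence reports exposed
#' hydrophobic protein surface. Each point's peak intensity is expressed as
#' a percentage of the zero-quencher control: pct = 100 * F(Q) / F(0).
#'
#' @param series A [titration_series()] (spectral or peak-only) with a
#'   positive control intensity.
#' @param window Optional wavelength window passed to [peak_intensity()].
#' @return A tibble with columns `quencher_M` and `pct_of_control`
#'   (100 at the control).
#' @export
normalize_ans <- function(series, window = NULL) {
  peaks <- series_peaks(series, window = window)
  f0 <- peaks$f_max[peaks$quencher_M == 0]
  if (length(f0) != 1 || !is.finite(f0) || f0 <= 0) {
    abort("nonpositive control intensity: cannot normalise ANS series.")
  }
  tibble(quencher_M = peaks$quencher_M,
         pct_of_control = 100 * peaks$f_max / f0)
}

#' Detect the onset of a saturation plateau
#'
#' Finds the smallest concentration after which every successive relative
#' increment |p_i - p_(i-1)| / |p_(i-1)| stays below `rel_tol`; returns `NA`
#' when the series never flattens before its last point.
#'
#' @param values A data frame with columns `quencher_M` and
#'   `pct_of_control` (or `pct`), at least 4 points.
#' @param rel_tol Relative increment below which the series counts as flat;
#'   default 0.05.
#' @return The plateau-onset concentration in molar, or `NA_real_`.
#' @export
detect_plateau <- function(values, rel_tol = 0.05) {
  df <- as_tibble(values)
  names(df)[names(df) == "pct"] <- "pct_of_control"
  names(df)[names(df) == "Q"] <- "quencher_M"
  if (nrow(df) < 4) abort("plateau detection needs at least 4 points.")
  df <- dplyr::arrange(df, .data$quencher_M)
  p <- df$pct_of_control
  q <- df$quencher_M
  n <- length(p)
  inc <- abs(diff(p)) / pmax(abs(p[-n]), .Machine$double.eps)
  for (k in seq_len(n - 1)) {
    if (q[k] <= 0) next
    if (all(inc[k:(n - 1)] < rel_tol)) return(q[k])
  }
  NA_real_
}

# ---- thermal denaturation ---------------------------------------------------

#' Construct a melting curve
#'
#' Intensity versus temperature from a thermal scan (typically 1 degree
#' C/min), used to locate the unfolding midpoint Tm.
#'
#' @param temperature_C Strictly increasing temperatures in degrees Celsius,
#'   at least 7 points.
#' @param intensity Finite intensities, arbitrary units.
#' @return A tibble of class `"melting_curve"`.
#' @export
melting_curve <- function(temperature_C, intensity) {
  temperature_C <- as.double(temperature_C)
  intensity <- as.double(intensity)
  if (length(temperature_C) != length(intensity)) {
    abort("`temperature_C` and `intensity` must have the same length.")
  }
  if (length(temperature_C) < 7) abort("a melting curve needs >= 7 points.")
  if (any(diff(temperature_C) <= 0)) {
    abort("temperatures must be strictly increasing.")
  }
  if (any(!is.finite(intensity))) abort("all intensities must be finite.")
  out <- tibble(temperature_C = temperature_C, intensity = intensity)
  structure(out, class = c("melting_curve", class(out)))
}

#' Melting temperature by the first-derivative method
#'
#' Smooths the intensity trace with a Savitzky-Golay local polynomial
#' filter, takes the central-difference first derivative dF/dT, and locates
#' Tm as the temperature of the extremum of |dF/dT|, refined to sub-grid
#' precision with a least-squares parabola over the points around the
#' extremum. A curve with no transition (flat or purely linear, so the
#' derivative has no pronounced extremum) is an error.
#'
#' @param curve A [melting_curve()] or data frame with `temperature_C` and
#'   `intensity` columns.
#' @param smooth_window Savitzky-Golay window length (odd, greater than
#'   `smooth_degree`); default 7.
#' @param smooth_degree Polynomial degree of the filter; default 2.
#' @return An object of class `"tm_result"`: list with `Tm_C`,
#'   `derivative` (tibble `temperature_C`, `dF_dT`), the smoothing
#'   parameters and the input curve. Supports [ggplot2::autoplot()].
#' @examples
#' mc <- generate_melting_curve(ground_truth(), rel_sigma = 0)
#' melting_tm(mc)$Tm_C
#' @export
melting_tm <- function(curve, smooth_window = 7, smooth_degree = 2) {
  df <- as_tibble(curve)
  if (!all(c("temperature_C", "intensity") %in% names(df))) {
    abort("`curve` needs `temperature_C` and `intensity` columns.")
  }
  n <- nrow(df)
  if (smooth_window %% 2 != 1 || smooth_window <= smooth_degree) {
    abort("`smooth_window` must be odd and greater than `smooth_degree`.")
  }
  if (n < smooth_window) abort("fewer points than the smoothing window.")
  tc <- df$temperature_C
  sm <- signal::sgolayfilt(df$intensity, p = smooth_degree, n = smooth_window)
  d <- (sm[3:n] - sm[1:(n - 2)]) / (tc[3:n] - tc[1:(n - 2)])
  td <- tc[2:(n - 1)]
  ad <- abs(d)
  i <- which.max(ad)
  # transition check: the derivative extremum must stand out from the bulk
  # of the trace and from the numerical noise floor of the signal itself
  floor_d <- max(1.5 * median(ad), 1e-10 * max(abs(df$intensity)),
                 .Machine$double.eps)
  if (max(ad) <= floor_d) {
    abort("no transition: derivative has no pronounced extremum.")
  }
  hw <- max(3L, (smooth_window - 1L) %/% 2L + 1L)
  lo <- max(1L, i - hw)
  hi <- min(length(d), i + hw)
  v <- .quad_vertex(td[lo:hi], ad[lo:hi])
  tm <- if (is.null(v)) td[i] else min(max(v$x, td[lo]), td[hi])
  structure(
    list(Tm_C = tm,
         derivative = tibble(temperature_C = td, dF_dT = d),
         smooth_window = smooth_window, smooth_degree = smooth_degree,
         curve = df),
    class = "tm_result"
  )
}

# ---- circular dichroism -----------------------------------------------------

#' Mean residue ellipticity
#'
#' Converts an observed CD signal (millidegrees) to mean residue
#' ellipticity: MRE = theta / (Cp * n_residues * path_length * 10), in
#' deg cm^2/dmol.
#'
#' @param theta Observed ellipticity in millidegrees; vectorised.
#' @param protein_conc_M Molar protein concentration Cp (> 0).
#' @param n_residues Number of amino-acid residues (> 0).
#' @param path_length_cm Cuvette path length in cm (> 0).
#' @return MRE in deg cm^2/dmol.
#' @examples
#' mean_residue_ellipticity(-100, 15e-6, 129, 0.2)
#' @export
mean_residue_ellipticity <- function(theta, protein_conc_M, n_residues,
                                     path_length_cm) {
  if (any(!is.finite(c(protein_conc_M, n_residues, path_length_cm))) ||
      protein_conc_M <= 0 || n_residues <= 0 || path_length_cm <= 0) {
    abort("`protein_conc_M`, `n_residues` and `path_length_cm` must be positive.")
  }
  theta / (protein_conc_M * n_residues * path_length_cm * 10)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' helix% = (-MRE208 - 4000) / (33000 - 4000) * 100, where 4000 is the MRE
#' of beta/random-coil structure at 208 nm and 33000 that of pure
#' alpha-helix. Both the raw value and a \[0, 100\]-clamped value are
#' returned.
#'
#' @param MRE208 Mean residue ellipticity at 208 nm, deg cm^2/dmol;
#'   vectorised.
#' @return A tibble with columns `MRE208`, `helix_pct_raw` and `helix_pct`
#'   (clamped).
#' @examples
#' helix_fraction(c(-33000, -4000, -18500))
#' @export
helix_fraction <- function(MRE208) {
  raw <- (-MRE208 - 4000) / (33000 - 4000) * 100
  tibble(MRE208 = MRE208, helix_pct_raw = raw,
         helix_pct = pmin(pmax(raw, 0), 100))
}

#' Assemble a CD record from an observed 208 nm signal
#'
#' Convenience wrapper combining [mean_residue_ellipticity()] and
#' [helix_fraction()] for the far-UV conditions of a scan.
#'
#' @inheritParams mean_residue_ellipticity
#' @param theta208 Observed ellipticity at 208 nm, millidegrees.
#' @return A one-row tibble with the inputs, `MRE208`, `helix_pct_raw` and
#'   `helix_pct`.
#' @export
cd_record <- function(theta208, protein_conc_M, n_residues, path_length_cm) {
  mre <- mean_residue_ellipticity(theta208, protein_conc_M, n_residues,
                                  path_length_cm)
  hx <- helix_fraction(mre)
  tibble(theta208 = theta208, protein_conc_M = protein_conc_M,
         n_residues = n_residues, path_length_cm = path_length_cm,
         MRE208 = mre, helix_pct_raw = hx$helix_pct_raw,
         helix_pct = hx$helix_pct)
}

#' Ellipticity of a CD spectrum at a given wavelength
#'
#' Linear interpolation of the stored trace; used to pull the 208 nm value
#' out of a far-UV scan.
#'
#' @param x A [spectrum()] in a CD mode (intensities in millidegrees).
#' @param at Wavelength in nm.
#' @return Ellipticity in millidegrees.
#' @export
theta_at <- function(x, at = 208) {
  df <- as_tibble(x)
  if (at < min(df$wavelength_nm) || at > max(df$wavelength_nm)) {
    abort("`at` lies outside the scanned wavelength range.")
  }
  stats::approx(df$wavelength_nm, df$intensity, xout = at)$y
}

#' Colloidal stability class from a zeta potential
#'
#' Standard rule of thumb on the magnitude of the zeta potential:
#' above 30 mV particles are well stabilised (`"good"`), between 5 and 30 mV
#' (inclusive) they are only short-term stable (`"short_term"`), and below
#' 5 mV they aggregate quickly (`"fast_aggregation"`).
#'
#' @param zeta_mV Zeta potential(s) in millivolts; the sign is ignored.
#' @return Character vector of classes.
#' @examples
#' classify_colloidal_stability(c(17.33, 35, 3))
#' @export
classify_colloidal_stability <- function(zeta_mV) {
  if (any(!is.finite(zeta_mV))) abort("`zeta_mV` must be finite.")
  a <- abs(zeta_mV)
  dplyr::case_when(
    a > 30 ~ "good",
    a >= 5 ~ "short_term",
    .default = "fast_aggregation"
  )
}
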