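#' Stern-Volmer quenching points
#'
#' Computes the quenching ratio F0/F for every nonzero quencher concentration
#' of a titration, where F0 and F are the peak intensities (via
#' [peak_intensity()]) of the control and quenched scans. The ratio at zero
#' quencher is 1 by construction and is not returned; the control intensity
#' is kept as the `"F0"` attribute for diagnostics.
#'
#' @param series A [titration_series()] containing the zero-quencher control.
#' @param window Optional wavelength window (nm) passed to [peak_intensity()].
#' @return A tibble with columns `quencher_M`, `F0_over_F` and `enhanced`
#'   (TRUE where F > F0, i.e. enhancement rather than quenching; a warning is
#'   raised when any point is enhanced). Attribute `"F0"` holds the control
#'   peak intensity, `"temperature_K"` the series temperature.
#' @examples
#' tr <- generate_titration(ground_truth(), model = "sv_two_regime",
#'                          rel_sigma = 0)
#' stern_volmer_points(tr)
#' @export
stern_volmer_points <- function(series, window = NULL) {
  peaks <- series_peaks(series, window = window)
  f0 <- peaks$f_max[peaks$quencher_M == 0]
  if (length(f0) != 1 || !is.finite(f0) || f0 <= 0) {
    abort("control intensity F0 must be a single positive value.")
  }
  quenched <- peaks[peaks$quencher_M > 0, , drop = FALSE]
  if (any(quenched$f_max <= 0)) {
    abort("nonpositive fluorescence intensity F at a quenched point.")
  }
  out <- tibble(
    quencher_M = quenched$quencher_M,
    F0_over_F = f0 / quenched$f_max,
    enhanced = quenched$f_max > f0
  )
  if (any(out$enhanced)) {
    warn("fluorescence enhancement (F > F0) at one or more concentrations.")
  }
  structure(out, F0 = f0, temperature_K = attr(series, "temperature_K"))
}

#' Fit a one- or two-regime Stern-Volmer model
#'
#' Ordinary least squares of F0/F on quencher concentration, either as a
#' single line or as two independent lines split at a breakpoint
#' concentration (the breakpoint itself belongs to the first regime). With
#' `breakpoint = "auto"` every interior split leaving at least 3 points per
#' side is tried and the split minimising the total residual sum of squares
#' is kept; if no admissible split exists a single-regime fit is returned.
#'
#' @param points A data frame with columns `quencher_M` and `F0_over_F`
#'   (as returned by [stern_volmer_points()]).
#' @param breakpoint `"auto"`, a concentration in molar, or `NULL` for a
#'   single-regime fit.
#' @param force_unit_intercept If TRUE, regress (F0/F - 1) on concentration
#'   through the origin, fixing the intercept at the theoretical value 1.
#'   Default FALSE: unconstrained OLS, with the deviation of the intercept
#'   from 1 reported as a diagnostic.
#' @param tau0 Unquenched fluorophore lifetime in seconds (default 6 ns, the
#'   accepted tryptophan value); stored for [classify_quenching()].
#'
#' @return An object of class `"sv_fit"`: a list with `regimes` (tibble of
#'   per-regime `conc_lo`, `conc_hi`, `n_points`, `K_SV`, `stderr`,
#'   `intercept`, `r2`, `rss`), `breakpoint`, `tau0`, `rss_single`,
#'   `rss_two`, `tss`, `n_points` and the input `points`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_two_regime_sv <- function(points, breakpoint = "auto",
                              force_unit_intercept = FALSE, tau0 = 6e-9) {
  df <- as_tibble(points)
  names(df)[names(df) == "Q"] <- "quencher_M"
  names(df)[names(df) == "ratio"] <- "F0_over_F"
  df <- dplyr::arrange(df[, c("quencher_M", "F0_over_F")], .data$quencher_M)
  q <- df$quencher_M
  r <- df$F0_over_F
  n <- length(q)
  if (n < 3) abort("at least 3 quenching points are required.")
  if (length(unique(q)) == 1) {
    abort("singular fit: all quencher concentrations are identical.")
  }
  single <- .sv_segment(q, r, force_unit_intercept)
  tss <- sum((r - mean(r))^2)

  split_fit <- function(bp) {
    lo <- q <= bp
    if (sum(lo) < 3 || sum(!lo) < 3) return(NULL)
    list(bp = bp,
         seg = list(.sv_segment(q[lo], r[lo], force_unit_intercept),
                    .sv_segment(q[!lo], r[!lo], force_unit_intercept)))
  }

  fit <- NULL
  if (is.null(breakpoint)) {
    fit <- NULL
  } else if (identical(breakpoint, "auto")) {
    cands <- purrr::compact(purrr::map(unique(q)[-length(unique(q))], split_fit))
    if (length(cands) > 0) {
      rss_tot <- purrr::map_dbl(cands, ~ .x$seg[[1]]$rss + .x$seg[[2]]$rss)
      # ties (e.g. a continuous kink lying on both lines) resolve to the
      # largest breakpoint: the kink concentration belongs to the first regime
      tol <- min(rss_tot) + 1e-10 * max(tss, .Machine$double.eps)
      fit <- cands[[max(which(rss_tot <= tol))]]
    }
  } else {
    fit <- split_fit(as.double(breakpoint))
    if (is.null(fit)) {
      abort("breakpoint leaves fewer than 3 points in a segment.")
    }
  }

  if (is.null(fit)) {
    regimes <- .sv_regime_row(single, 0, max(q), sum(q <= max(q)))
    bp <- NA_real_
    rss_two <- single$rss
  } else {
    lo_n <- sum(q <= fit$bp)
    regimes <- dplyr::bind_rows(
      .sv_regime_row(fit$seg[[1]], 0, fit$bp, lo_n),
      .sv_regime_row(fit$seg[[2]], fit$bp, max(q), n - lo_n)
    )
    bp <- fit$bp
    rss_two <- fit$seg[[1]]$rss + fit$seg[[2]]$rss
  }
  structure(
    list(regimes = regimes, breakpoint = bp, tau0 = tau0,
         rss_single = single$rss, rss_two = rss_two, tss = tss,
         n_points = n, force_unit_intercept = force_unit_intercept,
         points = df),
    class = "sv_fit"
  )
}

.sv_segment <- function(q, r, through_one) {
  if (through_one) {
    y <- r - 1
    slope <- sum(q * y) / sum(q^2)
    res <- y - slope * q
    dfree <- length(q) - 1L
    se <- if (dfree > 0) sqrt(sum(res^2) / dfree / sum(q^2)) else NA_real_
    list(slope = slope, intercept = 1,
         stderr = se, rss = sum(res^2),
         r2 = if (sum(y^2) > 0) 1 - sum(res^2) / sum(y^2) else NA_real_)
  } else {
    fit <- lm(r ~ q)
    sm <- suppressWarnings(summary(fit))  # noiseless data: 'perfect fit' warning is expected
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         stderr = unname(sm$coefficients[2, 2]),
         rss = sum(fit$residuals^2), r2 = sm$r.squared)
  }
}

.sv_regime_row <- function(seg, lo, hi, n) {
  tibble(conc_lo = lo, conc_hi = hi, n_points = n,
         K_SV = seg$slope, stderr = seg$stderr,
         intercept = seg$intercept, r2 = seg$r2, rss = seg$rss)
}

#' Bimolecular quenching rate constant
#'
#' kq = K_SV / tau0, the collisional rate constant implied by a Stern-Volmer
#' constant and the unquenched fluorophore lifetime.
#'
#' @param K_SV Stern-Volmer constant(s), 1/M.
#' @param tau0 Fluorophore lifetime in seconds; must be positive.
#' @return kq in 1/(M s), vectorised over `K_SV`.
#' @examples
#' bimolecular_rate(29.25e3)  # 4.875e12, far above the diffusion limit
#' @export
bimolecular_rate <- function(K_SV, tau0 = 6e-9) {
  if (!is.finite(tau0) || tau0 <= 0) abort("`tau0` must be positive.")
  K_SV / tau0
}

#' Classify the quenching mechanism of a Stern-Volmer fit
#'
#' Converts each regime's K_SV into a bimolecular rate kq = K_SV/tau0 and
#' compares it with the diffusion-controlled collisional limit (~1e10
#' 1/(M s)). A regime whose kq exceeds `static_factor` times the limit is
#' called static (ground-state complex formation); a regime at or above the
#' limit but below that factor is dynamic (collisional); kq below the limit
#' is reported as dynamic with a sub-collisional note. A first static regime
#' followed by a dynamic one yields the combined verdict
#' `"mixed_static_then_dynamic"`. A linearity diagnostic compares the
#' single-line and two-line residuals by an F-ratio: curvature (`linear =
#' FALSE`) is declared when splitting improves the fit by more than
#' `f_threshold`.
#'
#' @param fit An [fit_two_regime_sv()] result.
#' @param static_factor Multiple of the diffusion limit above which quenching
#'   is called static; default 100 (i.e. 1e12 1/(M s)).
#' @param diffusion_limit Maximum diffusion-controlled collisional rate,
#'   1/(M s).
#' @param f_threshold F-ratio above which the Stern-Volmer plot is declared
#'   non-linear.
#' @return An object of class `"quench_class"`: list with `kq` (per-regime
#'   tibble with `K_SV`, `kq`, `mechanism`, `note`), overall `mechanism`
#'   (`"static"`, `"dynamic"` or `"mixed_static_then_dynamic"`), `linear`
#'   flag, the thresholds used, and a text `rationale`.
#' @export
classify_quenching <- function(fit, static_factor = 100,
                               diffusion_limit = 1e10, f_threshold = 10) {
  if (!inherits(fit, "sv_fit")) abort("`fit` must be an sv_fit object.")
  kq <- bimolecular_rate(fit$regimes$K_SV, fit$tau0)
  ratio <- kq / diffusion_limit
  mech <- ifelse(ratio >= static_factor, "static", "dynamic")
  note <- dplyr::case_when(
    ratio >= static_factor ~ "kq above static threshold",
    ratio >= 1 ~ "kq at the diffusion-controlled order",
    .default = "kq below the diffusion-controlled limit (sub-collisional)"
  )
  kq_tbl <- dplyr::mutate(
    fit$regimes[, c("conc_lo", "conc_hi", "K_SV")],
    kq = kq, mechanism = mech, note = note
  )
  overall <- if (length(mech) == 1) {
    mech
  } else if (all(mech == "static")) {
    "static"
  } else if (all(mech == "dynamic")) {
    "dynamic"
  } else {
    "mixed_static_then_dynamic"
  }
  linear <- .sv_linearity(fit, f_threshold)
  rationale <- sprintf(
    paste0("kq/%0.0e per regime = %s; static threshold %g x diffusion limit; ",
           "SV plot %s (F-ratio criterion %g)."),
    diffusion_limit, paste(sprintf("%.3g", ratio), collapse = ", "),
    static_factor, if (linear) "linear" else "non-linear", f_threshold
  )
  structure(
    list(kq = kq_tbl, mechanism = overall, linear = linear,
         static_factor = static_factor, diffusion_limit = diffusion_limit,
         f_threshold = f_threshold, tau0 = fit$tau0, rationale = rationale),
    class = "quench_class"
  )
}

.sv_linearity <- function(fit, f_threshold) {
  # single line already essentially perfect -> linear
  if (fit$rss_single <= 1e-12 * max(fit$tss, .Machine$double.eps)) return(TRUE)
  if (nrow(fit$regimes) < 2) return(TRUE)
  df2 <- fit$n_points - 4L
  if (df2 <= 0) return(TRUE)
  if (fit$rss_two <= 0) return(FALSE)
  f_stat <- ((fit$rss_single - fit$rss_two) / 2) / (fit$rss_two / df2)
  f_stat <= f_threshold
}
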