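# Closed-form simple-regression oracle, independent of stats::lm:
# slope = S_xy / S_xx, intercept = ybar - slope * xbar.
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# Gaussian band helper for spectra built directly in tests.
gaussian_spectrum <- function(center, width = 25, amplitude = 1000,
                              grid = 300:450, mode = "emission") {
  spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * width^2)),
           mode = mode)
}

# Peak-only titration with ratios prescribed exactly.
ratio_series <- function(quencher_M, ratio, F0 = 1000, ...) {
  titration_series(
    tibble::tibble(quencher_M = c(0, quencher_M),
                   intensity = c(F0, F0 / ratio)),
    ...
  )
}

titration_concs_uM <- c(2, 4, 8, 15, 30, 50, 100)
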