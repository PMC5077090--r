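test_that("quenching ratios follow the generating law exactly at zero noise", {
  # single-regime law: ratio = 1 + K * Q to machine precision
  truth <- ground_truth(sv = list(K_SV = 1e4, breakpoints = NULL))
  tr <- generate_titration(truth, model = "sv_two_regime", rel_sigma = 0)
  pts <- stern_volmer_points(tr)
  expect_equal(pts$F0_over_F, 1 + 1e4 * pts$quencher_M, tolerance = 1e-12)
  # hand-computed ratios for the weak-binder first regime
  ser <- ratio_series(c(2, 4, 8) * 1e-6, c(1.0585, 1.1170, 1.2340))
  expect_equal(stern_volmer_points(ser)$F0_over_F,
               c(1.0585, 1.1170, 1.2340), tolerance = 1e-12)
})

test_that("a control-only series yields no quenching points", {
  ser <- titration_series(tibble::tibble(quencher_M = 0, intensity = 1000))
  expect_equal(nrow(stern_volmer_points(ser)), 0)
})

test_that("nonpositive intensities error and enhancement is flagged", {
  ser <- ratio_series(c(2, 4, 8) * 1e-6, c(1.1, 1.2, 0.5))
  expect_warning(pts <- stern_volmer_points(ser), "enhancement")
  expect_identical(pts$enhanced, c(FALSE, FALSE, TRUE))
  bad <- titration_series(tibble::tibble(quencher_M = c(0, 2e-6),
                                         intensity = c(1000, -5)))
  expect_error(stern_volmer_points(bad), "nonpositive")
})

test_that("two-regime fit recovers both generator slopes to machine precision", {
  tr <- generate_titration(ground_truth(), model = "sv_two_regime",
                           rel_sigma = 0)
  fit <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = 15e-6)
  expect_equal(fit$regimes$K_SV[1], 29.25e3, tolerance = 1e-8)
  expect_equal(fit$regimes$K_SV[2], 34.92e2, tolerance = 1e-8)
  # regimes tile the concentration range, breakpoint in the first segment
  expect_equal(fit$regimes$conc_lo, c(0, 15e-6))
  expect_equal(fit$regimes$conc_hi, c(15e-6, 100e-6))
  expect_equal(fit$regimes$n_points, c(4L, 3L))
})

test_that("automatic breakpoint search finds the generator changepoint", {
  withr::with_seed(21, {
    for (i in 1:10) {
      k1 <- runif(1, 1e4, 5e4)
      k2 <- runif(1, 5e2, 5e3)
      truth <- ground_truth(sv = list(K_SV = c(k1, k2), breakpoints = 15e-6))
      tr <- generate_titration(truth, model = "sv_two_regime", rel_sigma = 0)
      fit <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = "auto")
      expect_equal(fit$breakpoint, 15e-6)
      expect_equal(fit$regimes$K_SV, c(k1, k2), tolerance = 1e-8)
    }
  })
})

test_that("perfectly linear data give matching segment slopes and a linear verdict", {
  q <- titration_concs_uM * 1e-6
  pts <- tibble::tibble(quencher_M = q, F0_over_F = 1 + 2e4 * q)
  fit <- fit_two_regime_sv(pts, breakpoint = "auto")
  expect_equal(fit$regimes$K_SV[1], fit$regimes$K_SV[2], tolerance = 1e-6)
  expect_true(classify_quenching(fit)$linear)
})

test_that("degenerate quenching inputs are rejected", {
  expect_error(
    fit_two_regime_sv(tibble::tibble(quencher_M = c(1e-6, 2e-6),
                                     F0_over_F = c(1.1, 1.2))),
    "at least 3")
  expect_error(
    fit_two_regime_sv(tibble::tibble(quencher_M = rep(2e-6, 4),
                                     F0_over_F = c(1.1, 1.2, 1.3, 1.4))),
    "singular")
  expect_error(
    fit_two_regime_sv(tibble::tibble(quencher_M = c(1, 2, 3, 4) * 1e-6,
                                     F0_over_F = 1 + (1:4) / 10),
                      breakpoint = 1e-6),
    "fewer than 3")
})

test_that("fitted slopes agree with the closed-form regression oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      q <- sort(runif(6, 1e-6, 1e-4))
      r <- 1 + runif(1, 1e3, 1e5) * q + rnorm(6, 0, 0.01)
      fit <- fit_two_regime_sv(tibble::tibble(quencher_M = q, F0_over_F = r),
                               breakpoint = NULL)
      orc <- ols_oracle(q, r)
      expect_equal(fit$regimes$K_SV, unname(orc["slope"]), tolerance = 1e-9)
      expect_equal(fit$regimes$intercept, unname(orc["intercept"]),
                   tolerance = 1e-9)
    }
  })
})

test_that("fit is equivariant under uniform intensity scaling", {
  truth <- ground_truth(noise = list(rel_sigma = 0.01))
  tr <- generate_titration(truth, model = "sv_two_regime", seed = 5)
  scaled <- titration_series(
    dplyr::mutate(tibble::as_tibble(tr), intensity = intensity * 3.7),
    mode = attr(tr, "mode"), temperature_K = attr(tr, "temperature_K"))
  f1 <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = 15e-6)
  f2 <- fit_two_regime_sv(stern_volmer_points(scaled), breakpoint = 15e-6)
  expect_equal(f1$regimes$K_SV, f2$regimes$K_SV, tolerance = 1e-9)
})

test_that("forcing the unit intercept pins the intercept at 1", {
  tr <- generate_titration(ground_truth(), model = "sv_two_regime",
                           rel_sigma = 0)
  fit <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = 15e-6,
                           force_unit_intercept = TRUE)
  expect_equal(fit$regimes$intercept, c(1, 1))
  expect_equal(fit$regimes$K_SV[1], 29.25e3, tolerance = 1e-8)
})

test_that("kq is exactly K_SV / tau0 and matches the headline rates", {
  expect_equal(bimolecular_rate(29.25e3, 6e-9), 4.875e12)
  expect_equal(bimolecular_rate(34.92e2, 6e-9), 5.82e11)
  expect_equal(bimolecular_rate(0, 6e-9), 0)
  expect_error(bimolecular_rate(1e4, 0), "positive")
  # algebraic identity per regime
  tr <- generate_titration(ground_truth(), model = "sv_two_regime",
                           rel_sigma = 0)
  fit <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = 15e-6)
  cls <- classify_quenching(fit)
  expect_equal(cls$kq$kq * fit$tau0, cls$kq$K_SV)
})

test_that("mechanism classification follows the kq thresholds", {
  tr <- generate_titration(ground_truth(), model = "sv_two_regime",
                           rel_sigma = 0)
  fit <- fit_two_regime_sv(stern_volmer_points(tr), breakpoint = 15e-6)
  cls <- classify_quenching(fit)
  expect_identical(cls$mechanism, "mixed_static_then_dynamic")
  expect_false(cls$linear)
  expect_identical(cls$kq$mechanism, c("static", "dynamic"))

  # single regime below the diffusion limit: dynamic with a sub-collisional note
  q <- c(2, 4, 8, 15) * 1e-6
  lo <- fit_two_regime_sv(
    tibble::tibble(quencher_M = q, F0_over_F = 1 + 5e9 * 6e-9 * q),
    breakpoint = NULL)
  cls_lo <- classify_quenching(lo)
  expect_identical(cls_lo$mechanism, "dynamic")
  expect_match(cls_lo$kq$note, "sub-collisional")

  # single regime far above the static threshold
  hi <- fit_two_regime_sv(
    tibble::tibble(quencher_M = q, F0_over_F = 1 + 1e13 * 6e-9 * q),
    breakpoint = NULL)
  expect_identical(classify_quenching(hi)$mechanism, "static")
})
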