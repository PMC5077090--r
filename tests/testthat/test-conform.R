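test_that("synchronous shift tracking recovers the injected band drift", {
  # 5 nm red drift on the Trp channel
  sy <- generate_sync_series(ground_truth(), delta_lambda = 60, rel_sigma = 0)
  sh <- shift_series(sy)
  expect_equal(sh$shift_nm[sh$quencher_M == 0], 0)
  final <- sh$shift_nm[which.max(sh$quencher_M)]
  expect_equal(final, 5, tolerance = 0.25 / 5)
  expect_identical(attr(sh, "verdict"), "red")
  expect_equal(attr(sh, "delta_lambda"), 60)

  # no drift on the Tyr channel
  sh15 <- shift_series(generate_sync_series(ground_truth(), delta_lambda = 15,
                                            rel_sigma = 0))
  expect_true(all(abs(sh15$shift_nm) < 0.25))
  expect_identical(attr(sh15, "verdict"), "none")

  # negative drift -> blue verdict
  shb <- shift_series(generate_sync_series(ground_truth(drift = -3),
                                           delta_lambda = 60, rel_sigma = 0))
  expect_identical(attr(shb, "verdict"), "blue")
})

test_that("shift recovery is the identity on the injected drift across magnitudes", {
  for (drift in c(-4, 2, 8)) {
    sy <- generate_sync_series(ground_truth(drift = drift), delta_lambda = 60,
                               rel_sigma = 0)
    sh <- shift_series(sy)
    expect_equal(sh$shift_nm[which.max(sh$quencher_M)], drift,
                 tolerance = 0.25 / abs(drift))
  }
})

test_that("ANS normalisation references the control at 100%", {
  ctrl <- titration_series(tibble::tibble(quencher_M = 0, intensity = 812),
                           mode = "ans")
  expect_equal(normalize_ans(ctrl)$pct_of_control, 100)
  ser <- ratio_series(2e-6, 0.5, mode = "ans")  # F = 2 F0
  expect_equal(normalize_ans(ser)$pct_of_control, c(100, 200))
  bad <- titration_series(tibble::tibble(quencher_M = c(0, 2e-6),
                                         intensity = c(0, 10)), mode = "ans")
  expect_error(normalize_ans(bad), "control")
})

test_that("plateau detection finds the generator onset and handles edge shapes", {
  an <- generate_ans_series(ground_truth(), rel_sigma = 0)
  norm <- normalize_ans(an)
  expect_equal(detect_plateau(norm, rel_tol = 0.05), 15e-6)

  # strictly rising series never plateaus
  rising <- tibble::tibble(quencher_M = c(0, 1, 2, 3, 4) * 1e-5,
                           pct_of_control = c(100, 200, 300, 400, 500))
  expect_true(is.na(detect_plateau(rising)))

  # constant series plateaus at the first nonzero concentration
  flat <- tibble::tibble(quencher_M = c(0, 1, 2, 3) * 1e-5,
                         pct_of_control = rep(100, 4))
  expect_equal(detect_plateau(flat), 1e-5)

  expect_error(detect_plateau(flat[1:3, ]), "at least 4")
})

test_that("first-derivative Tm recovers generator midpoints within a grid step", {
  for (tm in c(55, 65.48, 71.25, 84.3)) {
    mc <- generate_melting_curve(ground_truth(melting = list(Tm = tm)),
                                 rel_sigma = 0)
    expect_equal(melting_tm(mc)$Tm_C, tm, tolerance = 1 / tm)
  }
  # narrower transition (smaller enthalpy) still within a grid step
  mc <- generate_melting_curve(
    ground_truth(melting = list(Tm = 60, dH_m = 2e5)), rel_sigma = 0)
  expect_equal(melting_tm(mc)$Tm_C, 60, tolerance = 1 / 60)
})

test_that("curves without a transition are rejected", {
  flat <- melting_curve(25:90, rep(500, 66))
  expect_error(melting_tm(flat), "no transition")
  linear <- melting_curve(25:90, 1000 - 2 * (25:90))
  expect_error(melting_tm(linear), "no transition")
  expect_error(melting_tm(generate_melting_curve(ground_truth(), rel_sigma = 0),
                          smooth_window = 6), "odd")
})

test_that("a sharper unfolding enthalpy sharpens the derivative peak", {
  peak_height <- function(dHm) {
    mc <- generate_melting_curve(
      ground_truth(melting = list(Tm = 70, dH_m = dHm)), rel_sigma = 0)
    max(abs(melting_tm(mc)$derivative$dF_dT))
  }
  expect_true(peak_height(2e5) < peak_height(4e5))
  expect_true(peak_height(4e5) < peak_height(8e5))
})

test_that("mean residue ellipticity follows the definition and its scaling laws", {
  expect_equal(mean_residue_ellipticity(-100, 15e-6, 129, 0.2),
               -100 / (15e-6 * 129 * 0.2 * 10))
  expect_equal(mean_residue_ellipticity(0, 1e-5, 100, 1), 0)
  # doubling the path length halves the MRE
  expect_equal(mean_residue_ellipticity(-100, 15e-6, 129, 0.4),
               mean_residue_ellipticity(-100, 15e-6, 129, 0.2) / 2)
  expect_error(mean_residue_ellipticity(-100, 0, 129, 0.2), "positive")
})

test_that("helix fraction maps the canonical MRE endpoints and is monotone", {
  hx <- helix_fraction(c(-33000, -4000, -18500))
  expect_equal(hx$helix_pct_raw, c(100, 0, 50))
  # strictly decreasing in MRE208
  mre <- seq(-40000, 5000, by = 500)
  expect_true(all(diff(helix_fraction(mre)$helix_pct_raw) < 0))
  # clamping
  expect_equal(helix_fraction(-40000)$helix_pct, 100)
  expect_equal(helix_fraction(0)$helix_pct, 0)
})

test_that("helix content is invariant under joint scaling of signal and concentration", {
  cd <- generate_cd_spectrum(ground_truth(), rel_sigma = 0)
  th <- theta_at(cd, 208)
  h1 <- helix_fraction(mean_residue_ellipticity(th, 15e-6, 129, 0.2))
  h2 <- helix_fraction(mean_residue_ellipticity(th * 3, 45e-6, 129, 0.2))
  expect_equal(h1$helix_pct_raw, h2$helix_pct_raw)
})

test_that("generated CD spectra invert the MRE relation at 208 nm", {
  for (target in c(-33000, -4000, -18500)) {
    cd <- generate_cd_spectrum(ground_truth(cd = list(MRE208 = target)),
                               rel_sigma = 0)
    mre <- mean_residue_ellipticity(theta_at(cd, 208), 15e-6, 129, 0.2)
    expect_equal(mre, target, tolerance = 1e-10)
  }
})

test_that("zeta-potential stability classes have closed boundaries at 5 and 30 mV", {
  expect_identical(classify_colloidal_stability(17.33), "short_term")
  expect_identical(classify_colloidal_stability(35), "good")
  expect_identical(classify_colloidal_stability(3), "fast_aggregation")
  # boundaries belong to short_term; sign is ignored
  expect_identical(classify_colloidal_stability(c(5, 30, -5, -30)),
                   rep("short_term", 4))
  expect_identical(classify_colloidal_stability(c(30.001, -31, 4.999)),
                   c("good", "good", "fast_aggregation"))
  expect_error(classify_colloidal_stability(NaN), "finite")
})
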