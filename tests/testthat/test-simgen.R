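test_that("generators are deterministic given a seed and leave the RNG alone", {
  t1 <- generate_titration(ground_truth(), model = "sv_two_regime", seed = 99)
  t2 <- generate_titration(ground_truth(), model = "sv_two_regime", seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  m1 <- generate_melting_curve(ground_truth(), seed = 99)
  m2 <- generate_melting_curve(ground_truth(), seed = 99)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  # different seeds differ
  t3 <- generate_titration(ground_truth(), model = "sv_two_regime", seed = 100)
  expect_false(identical(t1$intensity, t3$intensity))
})

test_that("ground-truth overrides merge over defaults and reject unknown parts", {
  gt <- ground_truth(melting = list(Tm = 65.48))
  expect_equal(gt$melting$Tm, 65.48)
  expect_equal(gt$melting$dH_m, 4e5)  # untouched default
  expect_error(ground_truth(bogus = list(a = 1)), "unknown")
})

test_that("analysis of noiseless generator output is the identity on the truth", {
  withr::with_seed(61, {
    for (i in 1:8) {
      k1 <- runif(1, 5e3, 8e4)
      k2 <- runif(1, 3e2, 4e3)
      kb <- runif(1, 20, 5e3)
      nn <- runif(1, 0.2, 1.4)
      dH <- runif(1, -120e3, -20e3)
      dS <- runif(1, -350, -50)
      tm <- runif(1, 50, 85)
      truth <- ground_truth(sv = list(K_SV = c(k1, k2), breakpoints = 15e-6),
                            binding = list(Kb = kb, n = nn),
                            thermo = list(dH = dH, dS = dS),
                            melting = list(Tm = tm))
      sv <- fit_two_regime_sv(
        stern_volmer_points(generate_titration(truth, model = "sv_two_regime",
                                               rel_sigma = 0)),
        breakpoint = 15e-6)
      expect_equal(sv$regimes$K_SV, c(k1, k2), tolerance = 1e-8)
      bf <- fit_double_log(
        stern_volmer_points(generate_titration(truth,
                                               model = "binding_isotherm",
                                               rel_sigma = 0)))
      expect_equal(bf$Kb, kb, tolerance = 1e-8)
      expect_equal(bf$n_sites, nn, tolerance = 1e-8)
      vh <- vant_hoff_fit(generate_temperature_series(truth))
      expect_equal(vh$dH, dH, tolerance = 1e-8)
      expect_equal(vh$dS, dS, tolerance = 1e-8)
      tmr <- melting_tm(generate_melting_curve(truth, rel_sigma = 0))
      expect_equal(tmr$Tm_C, tm, tolerance = 1 / tm)
    }
  })
})

test_that("recovered parameters stay within 3 standard errors at 1% noise", {
  truth <- ground_truth()
  ok_k <- ok_kb <- logical(100)
  tm_err <- numeric(100)
  for (s in 1:100) {
    sv <- fit_two_regime_sv(
      stern_volmer_points(generate_titration(truth, model = "sv_two_regime",
                                             rel_sigma = 0.01, seed = s)),
      breakpoint = 15e-6)
    ok_k[s] <- abs(sv$regimes$K_SV[1] - 29.25e3) <= 3 * sv$regimes$stderr[1]
    bf <- fit_double_log(
      stern_volmer_points(generate_titration(truth, model = "binding_isotherm",
                                             rel_sigma = 0.01, seed = s)))
    ok_kb[s] <- abs(bf$log10_Kb - log10(105.07)) <= 3 * bf$stderr_log10_Kb
    tm_err[s] <- melting_tm(generate_melting_curve(truth, rel_sigma = 0.01,
                                                   seed = s))$Tm_C - 71.25
  }
  # per-regime fits leave only 2 residual degrees of freedom, so the
  # +/- 3 SE band has t-coverage pt(3, 2) - pt(-3, 2) ~ 0.90, less the
  # effect of the shared control-intensity noise correlating residuals
  expect_gte(mean(ok_k), 0.8)
  expect_gte(mean(ok_kb), 0.8)
  expect_gte(mean(abs(tm_err) <= 0.5), 0.95)
})

test_that("generator guards reject inconsistent requests", {
  expect_error(generate_titration(ground_truth(),
                                  concentrations = c(2, 4, 8) * 1e-6,
                                  model = "sv_two_regime"),
               "zero-quencher")
  expect_error(generate_melting_curve(ground_truth(melting = list(Tm = 95))),
               "inside")
  expect_error(generate_sync_series(ground_truth(), delta_lambda = 30),
               "15 or 60")
  expect_error(generate_titration(list(), model = "sv_two_regime"),
               "ground_truth")
})

test_that("the ANS generator saturates exactly at its plateau settings", {
  an <- generate_ans_series(ground_truth(ans = list(plateau_pct = 100)),
                            rel_sigma = 0)
  norm <- normalize_ans(an)
  expect_equal(norm$pct_of_control, rep(100, nrow(norm)), tolerance = 1e-9)
  # onset beyond the scanned range: strictly rising, no plateau
  an2 <- generate_ans_series(ground_truth(ans = list(onset = 2e-4)),
                             rel_sigma = 0)
  expect_true(is.na(detect_plateau(normalize_ans(an2))))
})
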