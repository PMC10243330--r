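test_that("log-linear step recovers a noiseless mono-exponential exactly", {
  mono <- perfusion_regime(1e-3, 10e-3, 0, "mono")
  cur <- noiseless_curve(mono, lib[["b-lin(13b)"]])
  hb <- fit_high_b(cur)
  expect_lt(abs(hb$D - 1e-3) / 1e-3, 1e-10)
  expect_equal(hb$intercept, 0, tolerance = 1e-12)
})

test_that("a (1-f)-scaled mono-exponential moves only the intercept", {
  sch <- lib[["b-lin(13b)"]]
  # S(b) = (1-f) e^{-bD} for b > 0, with S(0) = 1 so normalization is a no-op
  y <- 0.95 * exp(-sch$bvalues * 1e-3)
  y[1] <- 1
  hb <- fit_high_b(signal_curve(sch$bvalues, y))
  expect_equal(hb$D, 1e-3, tolerance = 1e-10)
  expect_equal(hb$intercept, log(0.95), tolerance = 1e-10)
  expect_equal(estimate_f(hb$intercept)$f, 0.05, tolerance = 1e-10)
})

test_that("high-b fit matches the closed-form OLS oracle under contamination", {
  # Medium-regime perfusion term contaminates the high segment: D comes out
  # slightly above truth, exactly as the textbook OLS formula predicts
  sch <- lib[["b-opt(13b)-Medium"]]
  cur <- noiseless_curve(regimes$Medium, sch)
  cfg <- fit_config()
  hb <- fit_high_b(cur, cfg)
  sel <- sch$bvalues >= cfg$threshold
  oracle <- ols_oracle(sch$bvalues[sel], log(cur$intensities[sel]))
  expect_equal(hb$D, -unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(hb$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
  expect_gt(hb$D, regimes$Medium$D)
  expect_lt(hb$D, 1.05 * regimes$Medium$D)
})

test_that("perfusion fraction follows the intercept and flags negatives", {
  expect_equal(estimate_f(0), list(f = 0, discarded = FALSE))
  f <- estimate_f(0.01)
  expect_equal(f$f, 1 - exp(0.01))
  expect_equal(f$f, -0.01005, tolerance = 1e-4)
  expect_true(f$discarded)
})

test_that("D* step recovers truth and agrees with the grid-search oracle", {
  cur <- noiseless_curve(regimes$Low, lib[["b-opt(13b)-Low"]])
  ds <- fit_dstar(cur, regimes$Low$D, regimes$Low$f)
  expect_lt(abs(ds$Dstar - 10e-3), 1e-6)
  expect_false(ds$at_bound)
  oracle <- grid_search_dstar(cur, regimes$Low$D, regimes$Low$f)
  expect_lt(abs(ds$Dstar - oracle), 1e-5)
})

test_that("D* oracle agreement holds on noisy curves too", {
  sch <- lib[["b-opt(13b)-Medium"]]
  for (seed in 1:8) {
    cur <- generate_noisy_curve(regimes$Medium, sch, snr = 30, seed = seed)
    hb <- fit_high_b(cur)
    fe <- estimate_f(hb$intercept)
    if (fe$discarded) next
    ds <- fit_dstar(cur, hb$D, fe$f)
    oracle <- grid_search_dstar(cur, hb$D, fe$f)
    expect_lt(abs(ds$Dstar - oracle), 1e-5)
  }
})

test_that("degenerate and clamped D* fits are flagged at-bound", {
  sch <- lib[["b-opt(13b)-Low"]]
  # f = 0: residuals independent of D*, estimate stays at the start 0
  cur <- noiseless_curve(perfusion_regime(1e-3, 10e-3, 0), sch)
  ds <- fit_dstar(cur, 1e-3, 0)
  expect_identical(ds$Dstar, 0)
  expect_true(ds$at_bound)
  # a decay steeper than the upper bound allows clamps at 0.1
  fast <- perfusion_regime(1e-3, 0.5, 0.3, "fast")
  cur2 <- noiseless_curve(fast, sch)
  ds2 <- fit_dstar(cur2, 1e-3, 0.3)
  expect_equal(ds2$Dstar, 0.1, tolerance = 1e-6)
  expect_true(ds2$at_bound)
})

test_that("segmented fit composes the three steps", {
  mono <- perfusion_regime(1e-3, 10e-3, 0, "mono")
  fit <- fit_segmented(noiseless_curve(mono, lib[["b-lin(13b)"]]))
  expect_equal(fit$D, 1e-3, tolerance = 1e-10)
  expect_equal(fit$f, 0, tolerance = 1e-10)
  expect_false(fit$f_discarded)
  expect_true(fit$dstar_at_bound)

  # noiseless Low-regime curve: small but nonzero deterministic bias from
  # perfusion contamination of the high segment, close to truth
  fit2 <- fit_segmented(noiseless_curve(regimes$Low, lib[["b-opt(13b)-Low"]]))
  expect_lt(abs(fit2$D - regimes$Low$D), 0.03e-3)
  expect_lt(abs(fit2$f - regimes$Low$f), 0.01)
  expect_lt(abs(fit2$Dstar - regimes$Low$Dstar), 2e-3)
  expect_gt(abs(fit2$f - regimes$Low$f), 0) # bias nonzero
})

test_that("segmented fit is deterministic and scale-equivariant", {
  sch <- lib[["b-opt(13b)-Medium"]]
  cur <- generate_noisy_curve(regimes$Medium, sch, snr = 30, seed = 3)
  f1 <- fit_segmented(cur)
  f2 <- fit_segmented(cur)
  expect_identical(f1, f2)
  scaled <- signal_curve(cur$bvalues, 37.2 * cur$intensities)
  expect_equal(fit_segmented(scaled), f1, tolerance = 1e-6)
})

test_that("batch fitting equals the per-curve path", {
  sch <- lib[["b-opt(13b)-Low"]]
  m <- simulate_curves(regimes$Low, sch, snr = 30, n_curves = 40, seed = 8)
  batch <- fit_ivim_batch(m)
  for (j in c(1, 7, 23, 40)) {
    single <- fit_segmented(signal_curve(sch$bvalues, m[, j]))
    expect_equal(batch$D[j], single$D, tolerance = 1e-10)
    expect_equal(batch$f[j], single$f, tolerance = 1e-10)
    expect_equal(batch$f_discarded[j], single$f_discarded)
    if (!single$f_discarded)
      expect_lt(abs(batch$Dstar[j] - single$Dstar), 1e-8)
  }
  # discard bookkeeping: flagged rows carry no D* estimate
  expect_identical(is.na(batch$Dstar), batch$f_discarded)
})

test_that("segment-inclusion flags reproduce the strict threshold reading", {
  sch <- lib[["b-lin(13b)"]]
  cfg <- fit_config(high_inclusive = FALSE, low_inclusive = FALSE)
  cur <- noiseless_curve(regimes$Medium, sch)
  hb_strict <- fit_high_b(cur, cfg)
  sel <- sch$bvalues > 200
  oracle <- ols_oracle(sch$bvalues[sel], log(cur$intensities[sel]))
  expect_equal(hb_strict$D, -unname(oracle["slope"]), tolerance = 1e-12)
  expect_gt(abs(hb_strict$D - fit_high_b(cur)$D), 0)
})
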