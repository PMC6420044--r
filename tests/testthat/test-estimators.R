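test_that("per-time-point I-V regression recovers exact linear data", {
  t <- seq(0, 10, 0.1)
  k0 <- 3e-3; b0 <- 0.05
  V <- c(-20, -10, 0, 10, 20)
  I <- outer(rep(b0, length(t)), rep(1, 5)) - outer(rep(k0, length(t)), V)
  iv <- fit_iv_per_timepoint(holding_series(t, V, I))
  expect_equal(iv$k, rep(k0, length(t)), tolerance = 1e-12)
  expect_equal(iv$b, rep(b0, length(t)), tolerance = 1e-12)
  expect_true(all(iv$r_squared == 1))

  # two levels: exact interpolation
  iv2 <- fit_iv_per_timepoint(holding_series(t, c(-10, 10), I[, c(2, 4)]))
  expect_equal(iv2$k, rep(k0, length(t)), tolerance = 1e-12)

  expect_error(holding_series(t, c(5, 5), I[, 1:2]), "distinct")
})

test_that("point-neuron clamp traces give k = gE+gI and b = gE*epsE + gI*epsI", {
  m <- fx_point()
  ev <- list(syn_event(1, 5, 2.5e-3, "E"), syn_event(1, 8, 4e-3, "I"))
  h <- synclamp:::clamp_series(m, ev, c(-20, -10, 0, 10, 20), 80, 0.1,
                               settle = 0)
  iv <- fit_iv_per_timepoint(h)
  gE <- double_exp_conductance(h$time, 5, 2.5e-3, 5, 7.8)
  gI <- double_exp_conductance(h$time, 8, 4e-3, 6, 18)
  expect_equal(iv$k, gE + gI, tolerance = 1e-10)
  expect_equal(iv$b, gE * 70 + gI * (-10), tolerance = 1e-10)

  # SIM inverts exactly in this regime
  est <- sim_estimate(iv, 70, -10)
  expect_equal(est$E$g, gE, tolerance = 1e-8)
  expect_equal(est$I$g, gI, tolerance = 1e-8)
})

test_that("the I-V relation stays linear across levels on the cable fixture", {
  pr <- fx_protocol_100()
  peak_idx <- which.max(pr$iv$b)
  expect_gt(pr$iv$r_squared[peak_idx], 0.999)
  # and through most of the transient
  active <- which(pr$iv$b > 0.2 * max(pr$iv$b))
  expect_gt(min(pr$iv$r_squared[active]), 0.999)
})

test_that("per-level conductances expose the clamp/synapse interaction", {
  # point neuron: all levels agree with the injected conductance
  m <- fx_point()
  evE <- list(syn_event(1, 5, 2.5e-3, "E"))
  h <- synclamp:::clamp_series(m, evE, c(-20, -10, 0, 10, 20), 80, 0.1,
                               settle = 0)
  tr <- per_level_conductance(h, 70)
  expect_length(tr, 5)
  gth <- double_exp_conductance(h$time, 5, 2.5e-3, 5, 7.8)
  for (x in tr) expect_equal(x$g, gth, tolerance = 1e-8)

  # dendritic input: per-level traces differ well beyond numerical noise
  mod <- fx_stick()
  s <- site_at_distance(mod, 100)
  hd <- synclamp:::clamp_series(mod, list(syn_event(s, 5, 2.5e-3, "E")),
                                c(-20, -10, 0, 10, 20), 80, 0.1, settle = 0)
  trd <- per_level_conductance(hd, 70)
  peaks <- vapply(trd, function(x) max(x$g), numeric(1))
  expect_gt(diff(range(peaks)) / mean(peaks), 0.01)

  # a level at the reversal is dropped with a warning
  hI <- holding_series(h$time, c(-10, 0, 10), h$syn_current[, 2:4])
  expect_warning(tr2 <- per_level_conductance(hI, -10), "reversal")
  expect_length(tr2, 2)
})

test_that("double-exponential fitting recovers kernel parameters", {
  t <- seq(0, 80, 0.1)
  g <- double_exp_conductance(t, 10, 2.5e-3, 5, 7.8)
  f <- fit_double_exponential(g, t)
  expect_equal(f$peak, 2.5e-3, tolerance = 0.01)
  expect_equal(f$tau_rise, 5, tolerance = 0.01)
  expect_equal(f$tau_decay, 7.8, tolerance = 0.01)
  expect_equal(f$onset, 10, tolerance = 0.01)

  set.seed(7)
  gn <- g + rnorm(length(g), 0, 0.05 * max(g))
  fn <- fit_double_exponential(gn, t)
  expect_equal(fn$peak, 2.5e-3, tolerance = 0.05)

  expect_error(fit_double_exponential(numeric(length(t)), t), "fit failure")
})

test_that("point-model reference inverts the somatic balance equation", {
  m <- fx_point()
  ev <- list(syn_event(1, 20, 2.5e-3, "E"))
  tr <- simulate_cable(m, ev, duration = 100, dt = 0.005)
  ref <- reference_from_point_model(tr$time, tr$voltage[, 1],
                                    m$capacitance[1], m$g_leak[1], 70)
  gth <- double_exp_conductance(tr$time, 20, 2.5e-3, 5, 7.8)
  expect_lt(max(abs(ref$g - gth)) / max(gth), 1e-3)

  # resting trace: zero conductance
  rest <- reference_from_point_model(tr$time, numeric(length(tr$time)),
                                     m$capacitance[1], m$g_leak[1], 70)
  expect_equal(rest$g, numeric(length(tr$time)))
})

test_that("point-model and intercept references agree on the cable fixture", {
  mod <- fx_stick()
  s <- site_at_distance(mod, 100)
  ev <- list(syn_event(s, 20, 2.5e-3, "E"))
  h <- synclamp:::clamp_series(mod, ev, c(-20, -10, 0, 10, 20), 140, 0.1,
                               settle = 0)
  ref_b <- reference_from_intercept(fit_iv_per_timepoint(h), 70)
  tr <- simulate_cable(mod, ev, duration = 140, dt = 0.1)
  pp <- effective_point_params(mod)
  ref_p <- reference_from_point_model(tr$time, tr$voltage[, 1], pp$c, pp$g_L,
                                      70)
  # the point integrator is an approximation of the cable soma; peaks agree
  # to better than 10%
  expect_lt(abs(max(ref_p$g) - max(ref_b$g)) / max(ref_b$g), 0.10)
})

test_that("intercept reference equals the injected conductance on a point neuron", {
  m <- fx_point()
  ev <- list(syn_event(1, 5, 2.5e-3, "E"))
  h <- synclamp:::clamp_series(m, ev, c(-20, 0, 20), 80, 0.1, settle = 0)
  iv <- fit_iv_per_timepoint(h)
  ref <- reference_from_intercept(iv, 70)
  expect_equal(ref$g, double_exp_conductance(h$time, 5, 2.5e-3, 5, 7.8),
               tolerance = 1e-8)
  # zero input gives a zero trace
  h0 <- synclamp:::clamp_series(m, list(), c(-20, 0, 20), 20, 0.1, settle = 0)
  expect_equal(max(abs(reference_from_intercept(fit_iv_per_timepoint(h0),
                                                70)$g)), 0)
  expect_error(reference_from_intercept(iv, 0), "nonzero")
})

test_that("error summary separates peak and time-averaged discrepancies", {
  t <- seq(0, 50, 0.1)
  g <- double_exp_conductance(t, 5, 1e-3, 5, 7.8)
  ref <- conductance_trace(t, g, "E", "reference")
  expect_equal(unlist(error_summary(ref, ref)), c(0, 0),
               ignore_attr = TRUE)

  est <- conductance_trace(t, 1.1 * g, "E", "IM")
  es <- error_summary(est, ref)
  expect_equal(es$peak_relative_error, 0.1, tolerance = 1e-10)
  expect_equal(es$time_averaged_relative_error, 0.1, tolerance = 1e-10)

  shifted <- conductance_trace(t, c(g[-1], 0), "E", "IM")
  es2 <- error_summary(shifted, ref)
  expect_lt(es2$peak_relative_error, 1e-3)
  expect_gt(es2$time_averaged_relative_error, 0.005)
})
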