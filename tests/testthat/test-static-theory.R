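test_that("effective conductance is exact at the soma and prefactor-scaled for small g", {
  # somatic input: local and effective conductances are identical
  for (g in c(1e-4, 2e-3, 0.05)) {
    expect_equal(effective_conductance_exact(g, 100, 100, 100, 70), g,
                 tolerance = 1e-12)
  }
  expect_equal(effective_conductance_exact(0, 50, 100, 300, 70), 0)

  # small-g limit of g_eff / g is K_qS / K_SS, by finite-difference slope
  r1 <- effective_conductance_exact(1e-6, 50, 100, 300, 70) / 1e-6
  r2 <- effective_conductance_exact(1e-7, 50, 100, 300, 70) / 1e-7
  expect_equal(r1, 0.5, tolerance = 1e-3)
  expect_equal(r2, 0.5, tolerance = 1e-4)
  expect_equal(round(r1, 4), round(r2, 4) , tolerance = 2e-4)
})

test_that("first-order expansion error is x squared", {
  expect_equal(first_order_expansion_error(0.3), 0.09)
  expect_equal(first_order_expansion_error(0), 0)
  expect_equal(first_order_expansion_error(0.1), 0.01)
  xs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(first_order_expansion_error(xs), xs^2)
  expect_error(first_order_expansion_error(1), "< 1")
})

test_that("closed-form voltage and current match the brute-force linear solve", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_two_port()
    gE <- runif(1, 0, 5e-3); gI <- runif(1, 0, 8e-3); I <- rnorm(1, 0, 0.5)
    o <- oracle_three_site(p, gE, gI, I)
    expect_equal(exact_soma_voltage(p, gE, gI, I), o$V_S,
                 tolerance = 1e-10)
    expect_equal(exact_syn_current(p, gE, gI, I), o$I_syn,
                 tolerance = 1e-10)
  }
  # printed reductions
  p <- random_two_port()
  expect_equal(exact_soma_voltage(p, 2e-3, 0, 0),
               2e-3 * p$K_ES * p$eps_E / (1 + 2e-3 * p$K_EE),
               tolerance = 1e-12)
  expect_equal(exact_soma_voltage(p, 0, 0, 0.3), p$K_SS * 0.3,
               tolerance = 1e-12)
  expect_equal(exact_syn_current(p, 0, 0, 0.7), 0, tolerance = 1e-14)
  expect_equal(exact_syn_current(p, 2e-3, 0, 0),
               2e-3 * p$eps_E * p$K_ES / ((1 + 2e-3 * p$K_EE) * p$K_SS),
               tolerance = 1e-12)
})

test_that("the exact I-V line is the I_inj-elimination of the exact solution", {
  set.seed(33)
  for (i in 1:50) {
    p <- random_two_port()
    gE <- runif(1, 0, 4e-3); gI <- runif(1, 0, 6e-3)
    line <- iv_line_exact(p, gE, gI)
    # five holding currents, as in the five-level protocol
    for (I in c(-0.4, -0.2, 0, 0.2, 0.4)) {
      V <- exact_soma_voltage(p, gE, gI, I)
      expect_equal(exact_syn_current(p, gE, gI, I), -line$k * V + line$b,
                   tolerance = 1e-9)
    }
  }
  p <- random_two_port()
  z <- iv_line_exact(p, 0, 0)
  expect_equal(c(z$k, z$b), c(0, 0))
})

test_that("first-order line reduces correctly and converges at O(g^2)", {
  # soma-located inputs: the traditional relations
  p1 <- colocated_two_port(1, K_SS = 120)
  l <- iv_line_first_order(p1, 2e-3, 4e-3)
  expect_equal(l$k, 6e-3)
  expect_equal(l$b, 2e-3 * 70 + 4e-3 * (-10))

  # printed arithmetic example: ratios 0.5
  p5 <- two_port_params(200, 200, 100, 50, 50, 200)
  l5 <- iv_line_first_order(p5, 2e-3, 4e-3)
  expect_equal(l5$k, 1.5e-3)
  expect_equal(l5$b, 0.05)

  # halving g quarters the gap between exact and first-order slope
  p <- colocated_two_port(0.4, K_SS = 100)
  gap <- function(s) abs(iv_line_exact(p, 1e-4 * s, 1.6e-4 * s)$k -
                         iv_line_first_order(p, 1e-4 * s, 1.6e-4 * s)$k)
  expect_equal(gap(1) / gap(0.5), 4, tolerance = 0.15)

  # co-located small-g slope: k ~ alpha^2 (gE + gI), Fig-style 0.2 prefactor
  p02 <- colocated_two_port(0.2, K_SS = 100)
  l02 <- iv_line_exact(p02, 1e-5, 1e-5)
  expect_equal(l02$k, 0.04 * 2e-5, tolerance = 1e-2)
})

test_that("sim_solve and im_solve invert their defining linear systems", {
  s <- sim_solve(6e-3, 0.1, 70, -10)
  expect_equal(s$gE, 2e-3); expect_equal(s$gI, 4e-3)
  expect_false(s$negative)
  s2 <- sim_solve(2e-3, 2e-3 * 70, 70, -10)   # pure somatic E input
  expect_equal(s2$gE, 2e-3); expect_equal(s2$gI, 0)
  expect_error(sim_solve(1e-3, 0.1, 70, 70), "differ")

  i1 <- im_solve(0.1, 0.06, 70, -10, -20)
  expect_equal(i1$gI_eff, 4e-3); expect_equal(i1$gE_eff, 2e-3)
  i2 <- im_solve(0.07, 0.07, 70, -10, -20)    # equal intercepts: pure E
  expect_equal(i2$gI_eff, 0); expect_equal(i2$gE_eff, 1e-3)
  expect_error(im_solve(0.1, 0.06, 70, -10, -10), "differ")
})

test_that("SIM applied to exact lines yields negative inhibition at small prefactor", {
  # Fig 1c-style setting: co-located inputs with K_ES = K_IS = 0.2 K_SS
  p <- colocated_two_port(0.2, K_SS = 100)
  found_negative <- FALSE
  for (gE in c(0.5, 1, 2, 4) * 1e-3) {
    for (gI in c(0.5, 1, 2, 4) * 1e-3) {
      l <- iv_line_exact(p, gE, gI)
      s <- sim_solve(l$k, l$b, p$eps_E, p$eps_I)
      if (s$gI < 0) found_negative <- TRUE
    }
  }
  expect_true(found_negative)
})

test_that("SIM error predictions match their closed form and sign structure", {
  z <- sim_error_prediction(1e-3, 1, 70, -10)
  expect_equal(c(z$dgE, z$dgI), c(0, 0))

  e <- sim_error_prediction(1e-3, 0.2, 70, -10)
  expect_equal(e$dgE, -0.5e-3, tolerance = 1e-12)
  expect_equal(e$dgI, -3.5e-3, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    k <- runif(1, 1e-4, 5e-3); a <- runif(1, 0.05, 1)
    eE <- runif(1, 50, 90); eI <- runif(1, -25, -5)
    d <- sim_error_prediction(k, a, eE, eI)
    expect_lte(d$dgE, 0); expect_lte(d$dgI, 0)
    expect_equal(d$dgE / d$dgI, -eI / eE, tolerance = 1e-12)
  }
  expect_error(sim_error_prediction(1e-3, 0), "alpha")
})

test_that("no transform exists between local and traditionally measured conductance", {
  # somatic inputs: both Taylor-coefficient requirements agree (all ones)
  p1 <- colocated_two_port(1, K_SS = 100)
  w1 <- no_transform_witness(p1)
  expect_equal(unlist(w1[1:4]), c(F1_slope = 1, F1_intercept = 1,
                                  G1_slope = 1, G1_intercept = 1))
  expect_false(w1$contradiction)

  p <- colocated_two_port(0.5, K_SS = 100)
  w <- no_transform_witness(p)
  expect_equal(w$F1_slope, 0.25); expect_equal(w$F1_intercept, 0.5)
  expect_true(w$contradiction)

  # on a measured prefactor map, the slope requirement is strictly below the
  # intercept requirement at every dendritic site
  pm <- prefactor_map(fx_stick())
  dend <- pm$ratio[pm$site != 1]
  expect_true(all(dend^2 < dend))
})
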