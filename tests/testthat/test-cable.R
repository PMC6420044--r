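test_that("discretization reproduces textbook compartment quantities", {
  # soma-only: one compartment, C = Cm * sphere area
  m1 <- fx_point()
  expect_equal(m1$n, 1L)
  expect_equal(m1$capacitance, 1 * (pi * 20^2) * 1e-8 * 1e3, tolerance = 1e-12)

  # halving the segment length doubles the compartment count (within 1)
  m <- build_ball_and_stick(20, 400, 2)
  n10 <- discretize(m, 10)$n
  n5 <- discretize(m, 5)$n
  expect_lte(abs(n5 - 1 - 2 * (n10 - 1)), 1)

  # axial conductance between equal adjacent segments: pi a^2 / (Ra l)
  mod <- fx_stick()
  a_cm <- 1e-4          # 1 um radius
  l_cm <- 10e-4         # 10 um pieces
  g_expect <- pi * a_cm^2 / (150 * l_cm) * 1e6   # uS
  expect_equal(unname(mod$g_axial[2]), g_expect, tolerance = 1e-12)
})

test_that("single-compartment step response matches RC charging closed form", {
  m1 <- fx_point()
  tr <- simulate_cable(m1, injections = list(current_injection(1, 0.1)),
                       duration = 100, dt = 0.01)
  R <- 1 / m1$g_leak
  tau <- m1$capacitance / m1$g_leak
  Vth <- 0.1 * R * (1 - exp(-tr$time / tau))
  expect_lt(max(abs(tr$voltage[, 1] - Vth)) / max(Vth), 1e-3)
})

test_that("clamp is exact and the point-neuron clamp identity holds", {
  m1 <- fx_point()
  ev <- list(syn_event(1, 10, 2.5e-3, "E"))
  tr <- simulate_cable(m1, ev, clamp = clamp_spec(-10, 1, settle = 5),
                       duration = 80, dt = 0.1)
  # clamped-site voltage equals holding at every sample, by construction
  expect_true(all(tr$voltage[, 1] == -10))
  # at the soma there is no space clamp: I_syn = g(t) (eps_E - V_h) exactly
  gth <- double_exp_conductance(tr$time, 10, 2.5e-3, 5, 7.8)
  expect_equal(tr$syn_current, gth * (70 - (-10)), tolerance = 1e-12)
})

test_that("dendritic input under clamp is attenuated at the soma", {
  mod <- fx_stick()
  s <- site_at_distance(mod, 100)
  tr <- simulate_cable(mod, list(syn_event(s, 10, 2.5e-3, "E")),
                       clamp = clamp_spec(0, 1, settle = 5),
                       duration = 100, dt = 0.1)
  local_peak <- 2.5e-3 * 70
  expect_lt(max(tr$syn_current), local_peak)
  expect_gt(max(tr$syn_current), 0)
})

test_that("double-exponential kernel has its analytic peak and integral", {
  t <- seq(0, 200, 0.01)
  expect_equal(double_exp_conductance(t, 5, 0, 5, 7.8), numeric(length(t)))

  g <- double_exp_conductance(t, 5, 2.5e-3, 5, 7.8)
  expect_true(all(g >= 0))
  expect_equal(max(g), 2.5e-3, tolerance = 1e-6)
  tstar <- log(7.8 / 5) * 5 * 7.8 / (7.8 - 5) + 5
  expect_equal(t[which.max(g)], tstar, tolerance = 1e-2)

  gi <- double_exp_conductance(t, 0, 4e-3, 6, 18)
  norm <- synclamp:::dexp_norm(6, 18)
  expect_equal(sum(gi) * 0.01, 4e-3 * (18 - 6) / norm, tolerance = 1e-3)

  expect_error(double_exp_conductance(t, 0, 1e-3, 5, 5), "degenerate")
})

test_that("steady-state solve is exact and matches analytic cable theory", {
  m1 <- fx_point()
  ss <- steady_state_solve(m1, injections = list(current_injection(1, 0.2)))
  expect_equal(ss$V[1], 0.2 / m1$g_leak, tolerance = 1e-12)
  expect_equal(steady_state_solve(m1)$V, 0)

  # finite sealed-end cable with lumped soma: input resistance from lambda
  mod <- discretize(build_ball_and_stick(20, 400, 2), 2)
  ss <- steady_state_solve(mod, injections = list(current_injection(1, 0.1)))
  Rm <- 20000; Ra <- 150; d <- 2e-4
  lambda <- sqrt(Rm * d / (4 * Ra))
  Rinf <- (2 / pi) * sqrt(Rm * Ra) * d^(-1.5)
  g_soma <- pi * (20e-4)^2 / Rm
  Rin_MOhm <- 1 / (g_soma + tanh(400e-4 / lambda) / Rinf) / 1e6
  expect_equal(ss$V[1] / 0.1, Rin_MOhm, tolerance = 1e-2)

  # nodal current balance residual at the solution
  G <- synclamp:::conductance_matrix(mod)
  inj <- numeric(mod$n); inj[1] <- 0.1
  resid <- G %*% ss$V - inj
  expect_lt(max(abs(resid)) / 0.1, 1e-10)
})

test_that("passive dynamics are linear and conserve charge per step", {
  mod <- fx_stick()
  s1 <- site_at_distance(mod, 100); s2 <- site_at_distance(mod, 300)
  run <- function(injs) simulate_cable(mod, injections = injs,
                                       duration = 60, dt = 0.1,
                                       record = seq_len(mod$n))
  a <- run(list(current_injection(s1, 0.05)))
  b <- run(list(current_injection(s2, 0.02)))
  ab <- run(list(current_injection(s1, 0.05), current_injection(s2, 0.02)))
  expect_lt(max(abs(ab$voltage - a$voltage - b$voltage)) /
              max(abs(ab$voltage)), 1e-8)

  # Kirchhoff residual of the trapezoid update at an arbitrary step
  M0 <- synclamp:::conductance_matrix(mod)
  Cdt <- mod$capacitance / 0.1
  inj <- numeric(mod$n); inj[s1] <- 0.05; inj[s2] <- 0.02
  i <- 200
  Vn <- ab$voltage[i, ]; Vn1 <- ab$voltage[i + 1, ]
  lhs <- Cdt * (Vn1 - Vn) + 0.5 * as.numeric(M0 %*% (Vn1 + Vn))
  expect_lt(max(abs(lhs - inj)) / max(abs(inj)), 1e-8)
})

test_that("halving dt changes the peak clamp-mode synaptic current < 0.5%", {
  mod <- fx_stick()
  s <- site_at_distance(mod, 100)
  ev <- list(syn_event(s, 5, 2.5e-3, "E"), syn_event(s, 5, 4e-3, "I"))
  pk <- function(dt) {
    tr <- simulate_cable(mod, ev, clamp = clamp_spec(-20, 1, settle = 2),
                         duration = 60, dt = dt)
    max(abs(tr$syn_current))
  }
  p1 <- pk(0.1); p2 <- pk(0.05)
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("bad inputs are rejected with informative errors", {
  m1 <- fx_point()
  expect_error(simulate_cable(m1, duration = 10, dt = -0.1), "dt")
  expect_error(
    simulate_cable(m1, injections = list(current_injection(1, 1e6)),
                   duration = 50, dt = 0.1),
    "instability")
  expect_error(clamp_spec(0, settle = -1), "settle")
  expect_error(discretize(build_ball_and_stick(), 0), "max_segment_length")
})
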