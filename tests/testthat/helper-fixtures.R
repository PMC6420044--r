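# Shared fixtures, built once per test run and cached. All are synthetic
# morphologies constructed in code; the heavier clamp-protocol results are
# memoized because several test files assert different properties of the
# same runs.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# soma-only point neuron
fx_point <- function() fx("point", function() {
  discretize(build_ball_and_stick(20, 0, 2), 10)
})

# ball-and-stick, 400 um x 2 um dendrite: the proximal-input fixture
fx_stick <- function() fx("stick", function() {
  discretize(build_ball_and_stick(20, 400, 2), 10)
})

# long thin stick, 1500 um x 1.5 um: strong space clamp at distal sites
fx_long_stick <- function() fx("long_stick", function() {
  discretize(build_ball_and_stick(20, 1500, 1.5, step = 25), 25)
})

# branched random tree
fx_tree <- function() fx("tree", function() {
  discretize(build_random_tree(3, 0.7, seed = 11, section_length = 150,
                               points_per_section = 6), 25)
})

# co-located transient E+I pair at a given distance
fx_pair_events <- function(model, distance,
                           peak_E = 2.5e-3, peak_I = 4e-3) {
  s <- site_at_distance(model, distance)
  list(syn_event(s, 0, peak_E, "E"), syn_event(s, 0, peak_I, "I"))
}

# full clamp protocol on the 100 um proximal fixture
fx_protocol_100 <- function() fx("protocol_100", function() {
  run_protocol(fx_stick(), fx_pair_events(fx_stick(), 100), dt = 0.1)
})

# full clamp protocol on the distal long-stick fixture (1300 um)
fx_protocol_distal <- function() fx("protocol_distal", function() {
  run_protocol(fx_long_stick(), fx_pair_events(fx_long_stick(), 1300),
               dt = 0.1)
})

# clamp protocol with all inputs at the clamped soma, on the point neuron
fx_protocol_soma <- function() fx("protocol_soma", function() {
  m <- fx_point()
  ev <- list(syn_event(m$soma, 0, 2.5e-3, "E"), syn_event(m$soma, 0, 4e-3, "I"))
  run_protocol(m, ev, dt = 0.1, point_reference = TRUE)
})

# brute-force solve of the static three-site linear system (the independent
# oracle for the closed-form two-port expressions): unknowns (IE, II, VE,
# VI, VS) from Ohm's law at each synapse plus superposition at each site
oracle_three_site <- function(p, gE, gI, I_inj) {
  A <- rbind(
    c(1, 0, gE, 0, 0),
    c(0, 1, 0, gI, 0),
    c(-p$K_EE, -p$K_EI, 1, 0, 0),
    c(-p$K_EI, -p$K_II, 0, 1, 0),
    c(-p$K_ES, -p$K_IS, 0, 0, 1))
  b <- c(gE * p$eps_E, gI * p$eps_I,
         p$K_ES * I_inj, p$K_IS * I_inj, p$K_SS * I_inj)
  x <- solve(A, b)
  list(V_S = x[5], I_syn = x[5] / p$K_SS - I_inj)
}

# random symmetric positive-definite transfer parameters (MOhm scale)
random_two_port <- function() {
  M <- matrix(stats::rnorm(9), 3)
  S <- crossprod(M) * 50 + diag(3) * 20
  two_port_params(K_EE = S[1, 1], K_II = S[2, 2], K_SS = S[3, 3],
                  K_ES = S[1, 3], K_IS = S[2, 3], K_EI = S[1, 2],
                  eps_E = 70, eps_I = stats::runif(1, -25, -5))
}
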