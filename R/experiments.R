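#' Default synaptic waveform parameters
#'
#' AMPA-type excitation (rise/decay 5/7.8 ms, peak 2.5 nS, reversal +70 mV
#' relative to a -70 mV rest) and GABA-A-type inhibition (6/18 ms, 4 nS,
#' -10 mV relative).
#'
#' @return Named list with `E` and `I` waveform parameter lists.
#' @export
default_waveforms <- function() {
  list(E = list(peak = 2.5e-3, tau_rise = 5, tau_decay = 7.8, reversal = 70),
       I = list(peak = 4e-3, tau_rise = 6, tau_decay = 18, reversal = -10))
}

#' Generate a distributed synaptic input schedule
#'
#' Assigns `n_E` excitatory and `n_I` inhibitory sites uniformly over the
#' dendritic compartments and gives each site `round(rate * window / 1000)`
#' onset times drawn uniformly on `[0, window]`. Fixed event count per site
#' (rather than a Poisson draw) keeps totals reproducible. Deterministic for
#' a fixed seed.
#'
#' @param model A `cable_model`.
#' @param n_E,n_I Numbers of E and I input sites.
#' @param rate Event rate per site (Hz).
#' @param window Scheduling window (ms).
#' @param seed Integer seed.
#' @param waveforms Per-polarity kernel parameters, see [default_waveforms()].
#' @return An `input_schedule`: list with `events` (list of [syn_event()]),
#'   `sites_E`, `sites_I`, `rate`, `window`, `seed`.
#' @export
gen_schedule <- function(model, n_E, n_I, rate, window, seed,
                         waveforms = default_waveforms()) {
  dend <- setdiff(seq_len(model$n), model$soma)
  if (!length(dend)) stop("no dendritic compartments available", call. = FALSE)
  n_ev <- round(rate * window / 1000)
  if (n_ev < 1) warning("rate * window below one event: empty schedule",
                        call. = FALSE)
  with_seed(seed, {
    sites_E <- sample(dend, n_E, replace = n_E > length(dend))
    sites_I <- sample(dend, n_I, replace = n_I > length(dend))
    events <- list()
    add <- function(sites, pol, wf, events) {
      for (s in sites) {
        if (n_ev < 1) next
        onsets <- stats::runif(n_ev, 0, window)
        for (o in onsets) {
          events[[length(events) + 1L]] <- syn_event(
            s, o, wf$peak, polarity = pol, tau_rise = wf$tau_rise,
            tau_decay = wf$tau_decay, reversal = wf$reversal)
        }
      }
      events
    }
    events <- add(sites_E, "E", waveforms$E, events)
    events <- add(sites_I, "I", waveforms$I, events)
    structure(list(events = events, sites_E = sites_E, sites_I = sites_I,
                   rate = rate, window = window, seed = seed),
              class = "input_schedule")
  })
}

#' @export
print.input_schedule <- function(x, ...) {
  cat(sprintf("Input schedule: %d events (%d E sites, %d I sites), %g Hz over %g ms, seed %d\n",
              length(x$events), length(x$sites_E), length(x$sites_I),
              x$rate, x$window, x$seed))
  invisible(x)
}

# replace the reversal of all I events (the inhibitory-reversal shift at the
# heart of the intercept method)
set_I_reversal <- function(events, eps_I) {
  lapply(events, function(e) {
    if (e$polarity == "I") e$reversal <- eps_I
    e
  })
}

# clamp-protocol core: run one clamp simulation per holding level and stack
# the synaptic currents into a holding_series
clamp_series <- function(model, events, holding_levels, duration, dt,
                         settle = 20, eps_tag = NULL) {
  runs <- lapply(holding_levels, function(h) {
    simulate_cable(model, synapses = events,
                   clamp = clamp_spec(h, model$soma, settle = settle),
                   duration = duration, dt = dt)
  })
  holding_series(runs[[1]]$time, holding_levels,
                 vapply(runs, `[[`, numeric(length(runs[[1]]$time)),
                        "syn_current"),
                 eps_tag = eps_tag)
}

#' Run the full intercept-method clamp protocol
#'
#' Orchestrates the measurement pipeline: (1) clamp the soma at each holding
#' level with the full E+I input schedule and record the synaptic currents;
#' (2) repeat with the inhibitory reversal shifted to its second value;
#' (3) single-polarity clamp runs (E only, I only) whose I-V intercepts give
#' the reference effective conductances; (4) optionally, unclamped
#' single-polarity runs for the point-model reference. Per-time-point I-V
#' regression, SIM and IM estimates are computed from the assembled series.
#'
#' @param model A `cable_model`.
#' @param schedule An `input_schedule` (or plain list of [syn_event()]).
#' @param holding_levels Holding potentials (mV relative to rest). Default
#'   `c(-20, -10, 0, 10, 20)`, the five levels -90 to -50 mV absolute at a
#'   -70 mV rest.
#' @param eps_E Excitatory reversal (mV relative to rest).
#' @param eps_I_variants The two inhibitory reversals (mV relative to rest);
#'   default `c(-10, -20)` (absolute -80 and -90 mV).
#' @param duration Simulation length (ms); default covers the schedule window
#'   plus a 60 ms tail.
#' @param dt Time step (ms).
#' @param settle Pre-stimulus settle time (ms); event onsets are shifted by
#'   this amount.
#' @param point_reference Also run the unclamped single-polarity simulations
#'   and compute the point-model reference traces.
#' @return A `protocol_result` list: `holding`, `holding_prime`
#'   ([holding_series()]), `iv`, `iv_prime`, `sim`, `im` (estimate pairs),
#'   `reference` (intercept-based E and I traces), optionally
#'   `reference_point`, and the reversals used.
#' @export
run_protocol <- function(model, schedule, holding_levels = c(-20, -10, 0, 10, 20),
                         eps_E = 70, eps_I_variants = c(-10, -20),
                         duration = NULL, dt = 0.1, settle = 20,
                         point_reference = FALSE) {
  events <- if (inherits(schedule, "input_schedule")) schedule$events else schedule
  if (length(eps_I_variants) != 2 || eps_I_variants[1] == eps_I_variants[2]) {
    stop("need two distinct inhibitory reversal variants", call. = FALSE)
  }
  events <- lapply(events, function(e) { e$onset <- e$onset + settle; e })
  if (is.null(duration)) {
    duration <- max(vapply(events, `[[`, numeric(1), "onset")) + 60
  }
  ev_E <- Filter(function(e) e$polarity == "E", events)
  ev_I <- Filter(function(e) e$polarity == "I", events)
  if (!length(ev_E) || !length(ev_I)) {
    stop("schedule must contain both E and I events", call. = FALSE)
  }
  ev1 <- set_I_reversal(events, eps_I_variants[1])
  ev2 <- set_I_reversal(events, eps_I_variants[2])
  ev_I1 <- set_I_reversal(ev_I, eps_I_variants[1])

  h1 <- clamp_series(model, ev1, holding_levels, duration, dt, settle,
                     eps_tag = eps_I_variants[1])
  h2 <- clamp_series(model, ev2, holding_levels, duration, dt, settle,
                     eps_tag = eps_I_variants[2])
  hE <- clamp_series(model, ev_E, holding_levels, duration, dt, settle)
  hI <- clamp_series(model, ev_I1, holding_levels, duration, dt, settle)

  iv1 <- fit_iv_per_timepoint(h1)
  iv2 <- fit_iv_per_timepoint(h2)
  ref_E <- reference_from_intercept(fit_iv_per_timepoint(hE), eps_E)
  ref_I <- reference_from_intercept(fit_iv_per_timepoint(hI),
                                    eps_I_variants[1])

  out <- list(
    holding = h1, holding_prime = h2, iv = iv1, iv_prime = iv2,
    sim = sim_estimate(iv1, eps_E, eps_I_variants[1]),
    im = im_estimate(iv1, iv2, eps_E, eps_I_variants[1], eps_I_variants[2]),
    reference = list(E = ref_E, I = ref_I),
    eps_E = eps_E, eps_I_variants = eps_I_variants,
    holding_levels = holding_levels
  )
  if (point_reference) {
    pp <- effective_point_params(model, dt = dt)
    trE <- simulate_cable(model, synapses = ev_E, duration = duration, dt = dt)
    trI <- simulate_cable(model, synapses = ev_I1, duration = duration, dt = dt)
    out$reference_point <- list(
      E = reference_from_point_model(trE$time, trE$voltage[, 1], pp$c, pp$g_L,
                                     eps_E),
      I = reference_from_point_model(trI$time, trI$voltage[, 1], pp$c, pp$g_L,
                                     eps_I_variants[1]))
  }
  structure(out, class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("Clamp protocol result\n")
  cat(sprintf("  holding levels: %s mV (rel. rest); eps_I variants: %s mV\n",
              paste(x$holding_levels, collapse = ", "),
              paste(x$eps_I_variants, collapse = ", ")))
  for (pol in c("E", "I")) {
    es <- error_summary(x$sim[[pol]], x$reference[[pol]])
    ei <- error_summary(x$im[[pol]], x$reference[[pol]])
    cat(sprintf("  %s: peak error SIM %.1f%%, IM %.1f%%%s\n", pol,
                100 * es$peak_relative_error, 100 * ei$peak_relative_error,
                if (x$sim[[pol]]$negative) " [SIM trace goes negative]" else ""))
  }
  invisible(x)
}

#' Spatial error map for a pair of constant-conductance inputs
#'
#' Scans the locations of a constant E / constant I conductance pair over the
#' dendrite and measures, for each location pair, the relative error of the
#' SIM and IM estimates against the single-input reference effective
#' conductance, plus a negative-conductance flag. The static protocol uses
#' exact clamped steady-state solves at each holding level (constant inputs
#' have no transient), so each cell is an exact small experiment.
#'
#' Default conductance amplitudes are small (0.05 nS E / 0.08 nS I,
#' preserving the 2.5:4 E:I ratio of the transient waveforms) so that the
#' scan probes the first-order regime in which the effective conductance is
#' proportional to the local conductance.
#'
#' @param model A passive `cable_model`.
#' @param distances Path distances from the soma to scan (um).
#' @param g_E,g_I Constant conductances (uS).
#' @param holding_levels Holding potentials (mV relative to rest).
#' @param eps_E Excitatory reversal (mV relative to rest).
#' @param eps_I_variants Two inhibitory reversals (mV relative to rest).
#' @return Data frame with one row per (E distance, I distance) pair:
#'   realized distances, per-method per-polarity relative errors, and
#'   negative-conductance flags.
#' @export
spatial_error_map <- function(model, distances, g_E = 5e-5, g_I = 8e-5,
                              holding_levels = c(-20, -10, 0, 10, 20),
                              eps_E = 70, eps_I_variants = c(-10, -20)) {
  reachable <- distances[distances <= max(model$distance)]
  if (length(reachable) < length(distances)) {
    message("skipping ", length(distances) - length(reachable),
            " unreachable distance(s)")
  }
  sites <- vapply(reachable, function(d) site_at_distance(model, d), integer(1))
  grid <- expand.grid(iE = seq_along(sites), iI = seq_along(sites))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    sE <- sites[grid$iE[r]]; sI <- sites[grid$iI[r]]
    cell <- static_cell(model, sE, sI, g_E, g_I, holding_levels, eps_E,
                        eps_I_variants)
    data.frame(distance_E = model$distance[sE], distance_I = model$distance[sI],
               sim_error_E = cell$sim_error_E, sim_error_I = cell$sim_error_I,
               im_error_E = cell$im_error_E, im_error_I = cell$im_error_I,
               sim_negative = cell$sim_negative, im_negative = cell$im_negative)
  })
  do.call(rbind, rows)
}

# one error-map cell: static clamp protocol via exact steady-state solves
static_cell <- function(model, sE, sI, g_E, g_I, holding_levels, eps_E,
                        eps_I_variants) {
  syn_I <- function(cond, h) {
    steady_state_solve(model, conductances = cond,
                       clamp = clamp_spec(h, model$soma))$syn_current
  }
  line <- function(cond) {
    I <- vapply(holding_levels, function(h) syn_I(cond, h), numeric(1))
    fit <- stats::lm.fit(cbind(1, holding_levels), I)
    c(k = -unname(fit$coefficients[2]), b = unname(fit$coefficients[1]))
  }
  both <- function(eps_I) {
    line(data.frame(site = c(sE, sI), g = c(g_E, g_I),
                    reversal = c(eps_E, eps_I)))
  }
  l1 <- both(eps_I_variants[1]); l2 <- both(eps_I_variants[2])
  sim <- sim_solve(l1["k"], l1["b"], eps_E, eps_I_variants[1])
  im <- im_solve(l1["b"], l2["b"], eps_E, eps_I_variants[1], eps_I_variants[2])
  # single-input references: intercept of the single-input static line
  ref_E <- line(data.frame(site = sE, g = g_E, reversal = eps_E))["b"] / eps_E
  ref_I <- line(data.frame(site = sI, g = g_I,
                           reversal = eps_I_variants[1]))["b"] /
    eps_I_variants[1]
  list(sim_error_E = abs(sim$gE - ref_E) / ref_E,
       sim_error_I = abs(sim$gI - ref_I) / ref_I,
       im_error_E = abs(im$gE_eff - ref_E) / ref_E,
       im_error_I = abs(im$gI_eff - ref_I) / ref_I,
       sim_negative = unname(sim$negative), im_negative = unname(im$negative))
}

#' Static demonstration of SIM failure versus the prefactor
#'
#' For a co-located E/I pair with prefactor `alpha`, builds the first-order
#' I-V lines at the two inhibitory reversals from a given pair of effective
#' conductances, then solves both SIM and IM and tabulates the SIM errors
#' against the closed-form predictions (which they must match identically in
#' this regime). At `alpha = 1` both methods are exact; as `alpha` shrinks
#' the SIM inhibitory estimate can turn negative.
#'
#' @param alphas Prefactor values in (0, 1].
#' @param gE_eff,gI_eff Effective conductances (uS).
#' @param eps_E,eps_I Reversal potentials (mV relative to rest).
#' @param eps_I_prime Second inhibitory reversal for IM.
#' @return Data frame with one row per `alpha`: SIM and IM estimates, SIM
#'   errors and predicted errors.
#' @export
static_demo_alpha <- function(alphas, gE_eff = 2e-3, gI_eff = 4e-3,
                              eps_E = 70, eps_I = -10, eps_I_prime = -20) {
  if (any(alphas <= 0 | alphas > 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  rows <- lapply(alphas, function(a) {
    k <- a * (gE_eff + gI_eff)
    b <- gE_eff * eps_E + gI_eff * eps_I
    b_prime <- gE_eff * eps_E + gI_eff * eps_I_prime
    sim <- sim_solve(k, b, eps_E, eps_I)
    im <- im_solve(b, b_prime, eps_E, eps_I, eps_I_prime)
    pred <- sim_error_prediction(k, a, eps_E, eps_I)
    data.frame(alpha = a,
               sim_gE = sim$gE, sim_gI = sim$gI,
               im_gE = im$gE_eff, im_gI = im$gI_eff,
               sim_dgE = sim$gE - gE_eff, sim_dgI = sim$gI - gI_eff,
               pred_dgE = pred$dgE, pred_dgI = pred$dgI,
               sim_negative = sim$negative)
  })
  do.call(rbind, rows)
}

#' Add Gaussian recording noise to a holding series
#'
#' @param h A [holding_series()].
#' @param sigma Noise standard deviation (nA).
#' @param seed Integer seed (reproducible).
#' @return A [holding_series()] with i.i.d. zero-mean Gaussian noise added to
#'   every current sample.
#' @export
add_noise <- function(h, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(h)
  with_seed(seed, {
    h$syn_current <- h$syn_current +
      matrix(stats::rnorm(length(h$syn_current), 0, sigma),
             nrow(h$syn_current))
    h
  })
}

#' Reversal-potential invariance of the effective conductance
#'
#' The effective conductance is a property of the input and the cable, not of
#' the reversal potential used to probe it. This check estimates the
#' reference effective conductance (single-polarity input, intercept of the
#' clamp-mode I-V line divided by the reversal) at each reversal value in a
#' sweep and returns the coefficient of variation (sd/mean) of the peak
#' amplitudes.
#'
#' @param model A `cable_model`.
#' @param site Input compartment.
#' @param eps_values Reversal potentials to sweep (mV relative to rest),
#'   at least 3; values equal to 0 (the resting potential) are excluded with
#'   a warning (zero driving force at rest).
#' @param peak,tau_rise,tau_decay Input kernel parameters (uS, ms).
#' @param holding_levels Holding potentials (mV relative to rest).
#' @param onset Stimulus onset after settle (ms).
#' @param duration,dt Simulation length and step (ms).
#' @return List with `cv` (sd/mean of peak conductances), `peaks` (uS) and
#'   `eps_values`.
#' @export
reversal_invariance_check <- function(model, site, eps_values, peak = 2.5e-3,
                                      tau_rise = 5, tau_decay = 7.8,
                                      holding_levels = c(-20, -10, 0, 10, 20),
                                      onset = 5, duration = 100, dt = 0.1) {
  keep <- eps_values[eps_values != 0]
  if (length(keep) < length(eps_values)) {
    warning("excluding reversal value(s) at the resting potential",
            call. = FALSE)
  }
  if (length(keep) < 3) stop("need at least 3 usable reversal values",
                             call. = FALSE)
  peaks <- vapply(keep, function(eps) {
    ev <- list(syn_event(site, onset, peak,
                         polarity = if (eps > 0) "E" else "I",
                         tau_rise = tau_rise, tau_decay = tau_decay,
                         reversal = eps))
    h <- clamp_series(model, ev, holding_levels, duration, dt, settle = 0)
    ref <- reference_from_intercept(fit_iv_per_timepoint(h), eps)
    max(ref$g)
  }, numeric(1))
  list(cv = stats::sd(peaks) / mean(peaks), peaks = peaks, eps_values = keep)
}
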