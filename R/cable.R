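#' Discretize a morphology into a compartmental cable model
#'
#' Splits every parent-child segment of the morphology into pieces no longer
#' than `max_segment_length` and assembles the passive compartmental circuit:
#' per-compartment membrane capacitance and leak conductance from the frustum
#' lateral area, and axial conductances between adjacent compartments from the
#' axial resistivity and frustum geometry. All soma points are collapsed into
#' a single electrical node whose area is the summed sphere area of the soma
#' points, i.e. the soma is treated as a point.
#'
#' @param m A `morphology`.
#' @param max_segment_length Maximum compartment length (um). Smaller values
#'   give a finer spatial grid.
#' @return A `cable_model`: a list with elements `n` (compartment count),
#'   `parent` (index of each compartment's parent, 0 for the soma root),
#'   `g_axial` (uS, conductance to parent), `capacitance` (nF), `g_leak`
#'   (uS), `e_leak` (mV), `soma` (soma compartment index), `distance` (um,
#'   path distance from the soma), `area` (um^2) and `passive`.
#' @examples
#' mod <- discretize(build_ball_and_stick(20, 400, 2), 10)
#' mod$n
#' @export
discretize <- function(m, max_segment_length = 10) {
  if (max_segment_length <= 0) stop("max_segment_length must be > 0", call. = FALSE)
  nd <- m$nodes
  p <- m$passive
  # unit helpers: areas um^2 -> cm^2 is 1e-8
  cap_nF <- function(area_um2) p$specific_capacitance * area_um2 * 1e-8 * 1e3
  leak_uS <- function(area_um2) p$specific_leak_conductance * area_um2 * 1e-8 * 1e6
  # axial conductance of a frustum piece (uS): pi r1 r2 / (Ra * L)
  ax_uS <- function(r1_um, r2_um, len_um) {
    pi * (r1_um * 1e-4) * (r2_um * 1e-4) /
      (p$axial_resistivity * len_um * 1e-4) * 1e6
  }

  soma_rows <- which(nd$region == "soma")
  soma_area <- sum(4 * pi * nd$radius[soma_rows]^2)  # sphere area per point

  parent <- integer(0); g_ax <- numeric(0); area <- numeric(0)
  dist <- numeric(0); origin <- integer(0)
  comp_of_node <- integer(nrow(nd))      # cable compartment holding each node
  comp_of_node[soma_rows] <- 1L
  n <- 1L
  parent[1] <- 0L; g_ax[1] <- NA_real_; area[1] <- soma_area
  dist[1] <- 0; origin[1] <- soma_rows[1]

  depths <- node_root_depths(m)
  for (i in seq_len(nrow(nd))) {
    if (nd$region[i] == "soma") next
    par_node <- nd$parent[i]
    seg_len <- sqrt(sum((nd[i, c("x", "y", "z")] -
                         nd[par_node, c("x", "y", "z")])^2))
    par_comp <- comp_of_node[par_node]
    if (seg_len <= 0) {
      # degenerate zero-length segment: collapse onto the parent compartment
      warning("zero-length segment at node ", nd$id[i], "; collapsed",
              call. = FALSE)
      comp_of_node[i] <- par_comp
      next
    }
    npieces <- max(1L, ceiling(seg_len / max_segment_length - 1e-9))
    r_par <- if (nd$region[par_node] == "soma") nd$radius[i] else nd$radius[par_node]
    r_i <- nd$radius[i]
    base_dist <- if (nd$region[par_node] == "soma") 0 else depths[par_node]
    for (k in seq_len(npieces)) {
      n <- n + 1L
      f0 <- (k - 1) / npieces; f1 <- k / npieces
      r0 <- r_par + (r_i - r_par) * f0
      r1 <- r_par + (r_i - r_par) * f1
      piece_len <- seg_len / npieces
      parent[n] <- par_comp
      g_ax[n] <- ax_uS(r0, r1, piece_len)
      area[n] <- pi * (r0 + r1) * piece_len   # frustum lateral area, um^2
      dist[n] <- base_dist + f1 * seg_len
      origin[n] <- i
      par_comp <- n
    }
    comp_of_node[i] <- n
  }

  structure(list(
    n = n, parent = parent, g_axial = g_ax,
    capacitance = cap_nF(area), g_leak = leak_uS(area),
    e_leak = p$leak_reversal, soma = 1L, distance = dist, area = area,
    comp_of_node = comp_of_node, passive = p
  ), class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat(sprintf("Cable model: %d compartments (soma = #%d)\n", x$n, x$soma))
  cat(sprintf("  total capacitance %.4g nF, total leak %.4g uS\n",
              sum(x$capacitance), sum(x$g_leak)))
  cat(sprintf("  max distance from soma %.1f um\n", max(x$distance)))
  invisible(x)
}

#' Compartment nearest to a path distance from the soma
#'
#' @param model A `cable_model`.
#' @param distance Target path distance (um).
#' @return Compartment index.
#' @export
site_at_distance <- function(model, distance) {
  which.min(abs(model$distance - distance))
}

# symmetric nodal conductance matrix (leak + axial), uS
conductance_matrix <- function(model) {
  n <- model$n
  G <- matrix(0, n, n)
  for (i in seq_len(n)[-1]) {
    j <- model$parent[i]; g <- model$g_axial[i]
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  diag(G) <- diag(G) + model$g_leak
  G
}

#' Double-exponential synaptic conductance waveform
#'
#' Peak-normalized difference of two exponentials,
#' `g(t) = peak * |exp(-(t-onset)/tau_decay) - exp(-(t-onset)/tau_rise)| / N`,
#' zero before onset, where `N` is the analytic maximum of the two-exponential
#' difference, so the returned series attains `peak` (to grid resolution) at
#' `t* = onset + tau_r tau_d log(tau_d/tau_r) / (tau_d - tau_r)`.
#'
#' @param t Time grid (ms).
#' @param onset Onset time (ms).
#' @param peak Peak conductance (uS).
#' @param tau_rise,tau_decay Rise and decay time constants (ms); must differ.
#' @return Conductance series (uS), nonnegative.
#' @examples
#' t <- seq(0, 60, 0.1)
#' g <- double_exp_conductance(t, 5, 2.5e-3, 5, 7.8)  # AMPA-like, 2.5 nS
#' max(g)
#' @export
double_exp_conductance <- function(t, onset, peak, tau_rise, tau_decay) {
  if (tau_rise == tau_decay) {
    stop("degenerate kernel: tau_rise must differ from tau_decay", call. = FALSE)
  }
  if (peak < 0) stop("peak must be >= 0", call. = FALSE)
  s <- t - onset
  g <- numeric(length(t))
  on <- s >= 0
  g[on] <- abs(exp(-s[on] / tau_decay) - exp(-s[on] / tau_rise))
  g * peak / dexp_norm(tau_rise, tau_decay)
}

# analytic peak of |exp(-t/tau_d) - exp(-t/tau_r)|
dexp_norm <- function(tau_rise, tau_decay) {
  tstar <- dexp_peak_time(tau_rise, tau_decay)
  abs(exp(-tstar / tau_decay) - exp(-tstar / tau_rise))
}

# analytic argmax of the two-exponential difference (relative to onset)
dexp_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Synaptic event specification
#'
#' A dynamic-clamp style conductance input: a double-exponential conductance
#' waveform injected at a compartment with a fixed reversal potential.
#'
#' @param site Compartment index.
#' @param onset Onset time (ms).
#' @param peak Peak conductance (uS).
#' @param tau_rise,tau_decay Kernel time constants (ms). Defaults are the
#'   AMPA-type values (5/7.8 ms) for `polarity = "E"` and the GABA-A values
#'   (6/18 ms) for `polarity = "I"`.
#' @param reversal Reversal potential (mV relative to rest). Defaults: 70 for
#'   E (an absolute 0 mV reversal at a -70 mV rest) and -10 for I (-80 mV
#'   absolute).
#' @param polarity `"E"` or `"I"` (bookkeeping tag).
#' @return A `syn_event` list.
#' @export
syn_event <- function(site, onset, peak, polarity = c("E", "I"),
                      tau_rise = NULL, tau_decay = NULL, reversal = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(tau_rise)) tau_rise <- if (polarity == "E") 5 else 6
  if (is.null(tau_decay)) tau_decay <- if (polarity == "E") 7.8 else 18
  if (is.null(reversal)) reversal <- if (polarity == "E") 70 else -10
  if (peak < 0) stop("peak must be >= 0", call. = FALSE)
  if (!is.finite(reversal)) stop("reversal must be finite", call. = FALSE)
  if (tau_rise == tau_decay) {
    stop("tau_rise must differ from tau_decay", call. = FALSE)
  }
  structure(list(site = site, onset = onset, peak = peak,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 reversal = reversal, polarity = polarity),
            class = "syn_event")
}

#' Ideal somatic voltage clamp specification
#'
#' @param holding Holding potential (mV relative to rest), constant per run.
#' @param site Clamped compartment (default 1, the soma).
#' @param settle Time (ms) allowed before stimulus onset; the baseline
#'   holding current is read out just before the first synaptic onset.
#' @return A `clamp_spec` list.
#' @export
clamp_spec <- function(holding, site = 1L, settle = 20) {
  if (settle < 0) stop("settle must be >= 0", call. = FALSE)
  structure(list(holding = holding, site = site, settle = settle),
            class = "clamp_spec")
}

#' Constant or time-varying current injection
#'
#' @param site Compartment index.
#' @param amplitude Constant current (nA), or a function of time `f(t_ms)`
#'   returning nA.
#' @return A `current_injection` list.
#' @export
current_injection <- function(site, amplitude) {
  if (is.numeric(amplitude) && !all(is.finite(amplitude))) {
    stop("amplitude must be finite", call. = FALSE)
  }
  structure(list(site = site, amplitude = amplitude),
            class = "current_injection")
}

# Hodgkin-Huxley style gating rate functions (textbook squid kinetics, rest
# at 0 mV). Used only for the generic active-channel interface.
hh_rates <- list(
  m = list(alpha = function(v) 0.1 * (25 - v) / (exp((25 - v) / 10) - 1),
           beta = function(v) 4 * exp(-v / 18), exponent = 3),
  h = list(alpha = function(v) 0.07 * exp(-v / 20),
           beta = function(v) 1 / (exp((30 - v) / 10) + 1), exponent = 1),
  n = list(alpha = function(v) 0.01 * (10 - v) / (exp((10 - v) / 10) - 1),
           beta = function(v) 0.125 * exp(-v / 80), exponent = 4)
)

#' Textbook active channel set (transient Na and delayed-rectifier K)
#'
#' A generic voltage-gated channel description for testing how weak active
#' conductances perturb passive linear properties such as transfer-resistance
#' reciprocity. Kinetics are the classic squid-axon rate functions expressed
#' relative to rest; densities default to a small fraction of the squid
#' values so that the resting state stays subthreshold-stable.
#'
#' @param model A `cable_model` (areas set the absolute conductances).
#' @param gbar_na,gbar_k Channel densities (S/cm^2).
#' @param e_na,e_k Reversal potentials (mV relative to rest).
#' @return A list of channel descriptions consumed by [simulate_cable()].
#' @export
hh_channels <- function(model, gbar_na = 0.012, gbar_k = 0.0036,
                        e_na = 115, e_k = -12) {
  to_uS <- function(dens) dens * model$area * 1e-8 * 1e6
  list(
    list(name = "na", gbar = to_uS(gbar_na), reversal = e_na,
         gates = hh_rates[c("m", "h")]),
    list(name = "kdr", gbar = to_uS(gbar_k), reversal = e_k,
         gates = hh_rates["n"])
  )
}

# steady-state gate values at voltage v
gate_inf <- function(gate, v) {
  a <- gate$alpha(v); b <- gate$beta(v)
  a / (a + b)
}

#' Simulate a compartmental cable model
#'
#' Integrates the passive (optionally active) cable equation
#' `C dV/dt = -g_L (V - e_L) - sum g_syn(t) (V - e_syn) + axial + I_inj`
#' with an implicit trapezoid (Crank-Nicolson) step; synaptic conductances are
#' evaluated at the half step, and each step solves the full linear system
#' exactly, so the scheme is unconditionally stable at the default
#' `dt = 0.1` ms.
#'
#' An ideal clamp is implemented by node substitution: the clamped row of the
#' linear system is replaced by `V = holding`, so the clamped voltage is exact
#' by construction, and the clamp current is recovered from the eliminated
#' balance equation. The baseline holding current is read out just before the
#' first synaptic onset, and the clamp-mode synaptic current is defined as
#' `syn_current(t) = baseline - clamp_current(t)`, so an excitatory input at a
#' holding level below its reversal yields a positive synaptic current.
#'
#' @param model A `cable_model`.
#' @param synapses List of [syn_event()] objects.
#' @param injections List of [current_injection()] objects.
#' @param clamp A [clamp_spec()] or `NULL`.
#' @param duration Simulation length (ms).
#' @param dt Time step (ms), default 0.1.
#' @param record Compartments to record (default: soma, plus clamp site).
#' @param channels Optional list of active channel descriptions (see
#'   [hh_channels()]); `NULL` for a passive run.
#' @return A `trace_set`: list with `time` (ms), `voltage` (matrix, one
#'   column per recorded site, mV relative to rest), `clamp_current`,
#'   `baseline_current` and `syn_current` (nA; `NULL` when unclamped), and
#'   `meta` (dt, holding, record sites).
#' @export
simulate_cable <- function(model, synapses = list(), injections = list(),
                           clamp = NULL, duration = 100, dt = 0.1,
                           record = NULL, channels = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(clamp) && duration <= clamp$settle) {
    stop("duration must exceed the clamp settle time", call. = FALSE)
  }
  n <- model$n
  if (is.null(record)) record <- unique(c(model$soma,
                                          if (!is.null(clamp)) clamp$site))
  time <- seq(0, duration, by = dt)
  nt <- length(time)

  M0 <- conductance_matrix(model)          # leak + axial, uS
  Cdt <- model$capacitance / dt            # nF/ms = uS
  drive0 <- model$g_leak * model$e_leak    # nA

  inj_vec <- function(t) {
    v <- numeric(n)
    for (inj in injections) {
      a <- if (is.function(inj$amplitude)) inj$amplitude(t) else inj$amplitude
      v[inj$site] <- v[inj$site] + a
    }
    v
  }
  # summed synaptic conductance per compartment at time t, and the
  # conductance-weighted reversal drive g*e (nA)
  syn_at <- function(t) {
    g <- numeric(n); ge <- numeric(n)
    for (j in seq_along(synapses)) {
      s <- synapses[[j]]
      gv <- double_exp_conductance(t, s$onset, s$peak, s$tau_rise, s$tau_decay)
      g[s$site] <- g[s$site] + gv
      ge[s$site] <- ge[s$site] + gv * s$reversal
    }
    list(g = g, ge = ge)
  }

  # initial state: rest for unclamped runs (injections and synapses switch on
  # at t >= 0), the synapse-free clamped steady state for clamped runs so the
  # baseline holding current is flat from t = 0
  if (is.null(clamp)) {
    V <- as.numeric(solve(M0, drive0))
  } else {
    V <- clamped_steady(M0, drive0, clamp$site, clamp$holding)$V
  }

  gates <- NULL
  if (!is.null(channels)) {
    gates <- lapply(channels, function(ch)
      lapply(ch$gates, function(g)
        vapply(V, function(v) gate_inf(g, v), numeric(1))))
  }

  Vout <- matrix(NA_real_, nt, length(record))
  Vout[1, ] <- V[record]
  clampI <- if (!is.null(clamp)) numeric(nt) else NULL

  # instantaneous clamp current at a sample time: the external current that
  # balances the clamped node given dV/dt = 0 there
  clamp_balance <- function(t, V, g_act, ge_act) {
    cs <- clamp$site
    syn <- syn_at(t)
    sum(M0[cs, ] * V) + (syn$g[cs] + g_act[cs]) * V[cs] -
      syn$ge[cs] - ge_act[cs] - drive0[cs] - inj_vec(t)[cs]
  }
  zero_n <- numeric(n)
  if (!is.null(clamp)) clampI[1] <- clamp_balance(0, V, zero_n, zero_n)

  for (s in seq_len(nt - 1L)) {
    th <- time[s] + dt / 2
    syn <- syn_at(th)
    g_act <- numeric(n); ge_act <- numeric(n)
    if (!is.null(channels)) {
      for (ci in seq_along(channels)) {
        ch <- channels[[ci]]
        open <- rep(1, n)
        for (gi in seq_along(ch$gates)) {
          gt <- ch$gates[[gi]]
          a <- vapply(V, gt$alpha, numeric(1))
          b <- vapply(V, gt$beta, numeric(1))
          tau <- 1 / (a + b); inf <- a * tau
          x <- inf + (gates[[ci]][[gi]] - inf) * exp(-dt / tau)
          gates[[ci]][[gi]] <- x
          open <- open * x^gt$exponent
        }
        gch <- ch$gbar * open
        g_act <- g_act + gch
        ge_act <- ge_act + gch * ch$reversal
      }
    }
    gdiag <- syn$g + g_act
    drive <- drive0 + syn$ge + ge_act + inj_vec(th)
    A <- 0.5 * M0; diag(A) <- diag(A) + Cdt + 0.5 * gdiag
    rhs <- Cdt * V - 0.5 * as.numeric(M0 %*% V) - 0.5 * gdiag * V + drive
    if (is.null(clamp)) {
      Vn <- solve(A, rhs)
    } else {
      Af <- A; rhsf <- rhs
      Af[clamp$site, ] <- 0; Af[clamp$site, clamp$site] <- 1
      rhsf[clamp$site] <- clamp$holding
      Vn <- solve(Af, rhsf)
    }
    V <- as.numeric(Vn)
    if (!is.null(clamp)) {
      clampI[s + 1L] <- clamp_balance(time[s + 1L], V, g_act, ge_act)
    }
    if (max(abs(V)) > 500) {
      stop("numerical instability (|V| > 500 mV) at t = ", round(th, 3),
           " ms with dt = ", dt, " ms", call. = FALSE)
    }
    Vout[s + 1L, ] <- V[record]
  }

  baseline <- NULL; syn_current <- NULL
  if (!is.null(clamp)) {
    onset_min <- if (length(synapses)) min(vapply(synapses, `[[`,
                                                 numeric(1), "onset")) else duration
    ib <- max(1L, sum(time < min(onset_min, duration)))
    baseline <- clampI[ib]
    syn_current <- baseline - clampI
  }
  structure(list(
    time = time,
    voltage = `colnames<-`(Vout, paste0("c", record)),
    clamp_current = clampI, baseline_current = baseline,
    syn_current = syn_current,
    meta = list(dt = dt, record = record,
                holding = if (!is.null(clamp)) clamp$holding else NULL,
                clamped = !is.null(clamp))
  ), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d samples, dt = %g ms, %d recorded site(s)%s\n",
              length(x$time), x$meta$dt, ncol(x$voltage),
              if (x$meta$clamped)
                sprintf(", clamped at %g mV", x$meta$holding) else ""))
  invisible(x)
}

# clamped steady state of the passive system: replace the clamped row by
# V = holding and recover the clamp current from the eliminated row
clamped_steady <- function(G, drive, site, holding) {
  Gf <- G; df <- drive
  Gf[site, ] <- 0; Gf[site, site] <- 1; df[site] <- holding
  V <- as.numeric(solve(Gf, df))
  I <- sum(G[site, ] * V) - drive[site]
  list(V = V, clamp_current = I)
}

#' Exact steady state of a passive cable model
#'
#' Solves the linear steady-state nodal system for constant current
#' injections and constant synaptic conductances, optionally with an ideal
#' clamp at one compartment.
#'
#' @param model A `cable_model` (passive).
#' @param injections Named or positional numeric vector of constant currents
#'   (nA) per compartment, or a list of [current_injection()] with constant
#'   amplitudes.
#' @param conductances Data frame with columns `site`, `g` (uS), `reversal`
#'   (mV), or `NULL`.
#' @param clamp A [clamp_spec()] or `NULL`.
#' @return List with `V` (per-compartment voltage, mV relative to rest) and,
#'   when clamped, `clamp_current` and `syn_current` (nA; the latter is
#'   baseline-subtracted, with the baseline from the synapse-free clamped
#'   state).
#' @export
steady_state_solve <- function(model, injections = NULL, conductances = NULL,
                               clamp = NULL) {
  n <- model$n
  G <- conductance_matrix(model)
  inj <- numeric(n)
  if (is.list(injections) && !is.data.frame(injections)) {
    for (ij in injections) inj[ij$site] <- inj[ij$site] + ij$amplitude
  } else if (!is.null(injections)) {
    v <- as.numeric(injections)
    if (length(v) == n) inj <- v else stop("injections vector must have length n",
                                           call. = FALSE)
  }
  drive <- model$g_leak * model$e_leak + inj
  Gs <- G
  if (!is.null(conductances)) {
    for (r in seq_len(nrow(conductances))) {
      s <- conductances$site[r]
      Gs[s, s] <- Gs[s, s] + conductances$g[r]
      drive[s] <- drive[s] + conductances$g[r] * conductances$reversal[r]
    }
  }
  if (is.null(clamp)) {
    if (all(model$g_leak == 0)) {
      stop("singular steady-state system: zero leak and no clamp", call. = FALSE)
    }
    return(list(V = as.numeric(solve(Gs, drive))))
  }
  st <- clamped_steady(Gs, drive, clamp$site, clamp$holding)
  base <- clamped_steady(G, model$g_leak * model$e_leak + inj,
                         clamp$site, clamp$holding)
  st$syn_current <- base$clamp_current - st$clamp_current
  st
}
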