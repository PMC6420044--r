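#' Holding series: clamp-mode synaptic currents across holding levels
#'
#' Bundles the baseline-subtracted synaptic current traces recorded at two or
#' more somatic holding levels on a shared time grid — the raw material of
#' the per-time-point I-V regression.
#'
#' @param time Shared time grid (ms).
#' @param holding_levels Holding potentials (mV relative to rest), one per
#'   column of `syn_current`; at least 2 distinct levels.
#' @param syn_current Matrix (time x level) of synaptic currents (nA).
#' @param eps_tag Optional label for the inhibitory-reversal variant that
#'   generated the series.
#' @return A `holding_series` list.
#' @export
holding_series <- function(time, holding_levels, syn_current, eps_tag = NULL) {
  syn_current <- as.matrix(syn_current)
  if (length(holding_levels) < 2 || length(unique(holding_levels)) < 2) {
    stop("need at least 2 distinct holding levels", call. = FALSE)
  }
  if (ncol(syn_current) != length(holding_levels) ||
      nrow(syn_current) != length(time)) {
    stop("syn_current must be time x holding level", call. = FALSE)
  }
  structure(list(time = time, holding_levels = holding_levels,
                 syn_current = syn_current, eps_tag = eps_tag),
            class = "holding_series")
}

#' @export
print.holding_series <- function(x, ...) {
  cat(sprintf("Holding series: %d levels (%s mV rel. rest), %d samples%s\n",
              length(x$holding_levels),
              paste(x$holding_levels, collapse = ", "), length(x$time),
              if (!is.null(x$eps_tag)) paste0(", eps_tag = ", x$eps_tag) else ""))
  invisible(x)
}

#' Per-time-point I-V regression
#'
#' At each time sample, ordinary least squares of the synaptic current on the
#' holding voltage across levels, cast as `I_syn = -k V + b`: `k` is the
#' negated regression slope and `b` the intercept. With exactly two levels
#' the fit is exact interpolation.
#'
#' @param h A [holding_series()].
#' @return An `iv_series`: list with `time`, `k` (uS), `b` (nA) and
#'   `r_squared` per time point.
#' @export
fit_iv_per_timepoint <- function(h) {
  V <- h$holding_levels
  if (stats::var(V) == 0) stop("holding levels are identical", call. = FALSE)
  if (any(!is.finite(h$syn_current))) {
    stop("non-finite synaptic currents", call. = FALSE)
  }
  Vc <- V - mean(V)
  # vectorized OLS over rows: slope_t = cov(I_t, V) / var(V)
  slope <- as.numeric(h$syn_current %*% Vc) / sum(Vc^2)
  b <- rowMeans(h$syn_current) - slope * mean(V)
  fitted <- outer(slope, V) + b
  ss_res <- rowSums((h$syn_current - fitted)^2)
  ss_tot <- rowSums((h$syn_current - rowMeans(h$syn_current))^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, pmin(1, 1 - ss_res / ss_tot)),
               1)  # constant rows are fit exactly by a flat line
  structure(list(time = h$time, k = -slope, b = b, r_squared = r2),
            class = "iv_series")
}

#' Conductance time course with method metadata
#'
#' @param time Time grid (ms).
#' @param g Conductance series (uS); may contain negative values, which are
#'   flagged rather than clipped.
#' @param polarity `"E"` or `"I"`.
#' @param method One of `"SIM"`, `"IM"`, `"per-level"`, `"reference"`.
#' @param reversal Reversal potential used (mV relative to rest).
#' @return A `conductance_trace` list with a `negative` flag.
#' @export
conductance_trace <- function(time, g, polarity, method, reversal = NA_real_) {
  structure(list(time = time, g = g, polarity = polarity, method = method,
                 reversal = reversal, negative = any(g < 0, na.rm = TRUE)),
            class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("%s %s conductance trace: peak %.4g nS at %.1f ms%s\n",
              x$method, x$polarity, max(x$g, na.rm = TRUE) * 1e3,
              x$time[which.max(x$g)],
              if (x$negative) " [contains negative values]" else ""))
  invisible(x)
}

#' Traditional slope-and-intercept estimate of E and I conductances
#'
#' Applies [sim_solve()] at every time point of an I-V series.
#'
#' @param iv An `iv_series` from [fit_iv_per_timepoint()].
#' @param eps_E,eps_I Reversal potentials (mV relative to rest).
#' @return List of two [conductance_trace()] objects (`E`, `I`).
#' @export
sim_estimate <- function(iv, eps_E = 70, eps_I = -10) {
  sol <- sim_solve(iv$k, iv$b, eps_E, eps_I)
  list(E = conductance_trace(iv$time, sol$gE, "E", "SIM", eps_E),
       I = conductance_trace(iv$time, sol$gI, "I", "SIM", eps_I))
}

#' Intercept-method estimate of effective E and I conductances
#'
#' Applies [im_solve()] per time point to the intercepts of two I-V series
#' recorded with identical inputs but different inhibitory reversal
#' potentials.
#'
#' @param iv,iv_prime `iv_series` objects at `eps_I` and `eps_I_prime`; must
#'   share the time grid.
#' @param eps_E Excitatory reversal (mV relative to rest).
#' @param eps_I,eps_I_prime The two inhibitory reversals (mV relative to
#'   rest).
#' @return List of two [conductance_trace()] objects (`E`, `I`).
#' @export
im_estimate <- function(iv, iv_prime, eps_E = 70, eps_I = -10,
                        eps_I_prime = -20) {
  if (length(iv$time) != length(iv_prime$time) ||
      any(iv$time != iv_prime$time)) {
    stop("the two I-V series must share a time grid", call. = FALSE)
  }
  sol <- im_solve(iv$b, iv_prime$b, eps_E, eps_I, eps_I_prime)
  list(E = conductance_trace(iv$time, sol$gE_eff, "E", "IM", eps_E),
       I = conductance_trace(iv$time, sol$gI_eff, "I", "IM", eps_I))
}

#' Per-holding-level conductance
#'
#' For a single-polarity input, each holding level gives a direct conductance
#' readout `g(t) = I_syn(t) / (eps - V_hold)`. On a point neuron all levels
#' agree; on a spatial neuron the traces differ across levels — direct
#' evidence of the nonlinear interaction between clamp current and synaptic
#' current. Levels at the reversal potential are excluded (singular driving
#' force) with a warning.
#'
#' @param h A [holding_series()].
#' @param eps Reversal potential of the input (mV relative to rest).
#' @return List of [conductance_trace()] objects, one per retained level,
#'   named by holding level.
#' @export
per_level_conductance <- function(h, eps) {
  keep <- which(h$holding_levels != eps)
  if (!length(keep)) {
    stop("all holding levels equal the reversal potential", call. = FALSE)
  }
  if (length(keep) < length(h$holding_levels)) {
    warning("excluding holding level(s) at the reversal potential",
            call. = FALSE)
  }
  out <- lapply(keep, function(j) {
    conductance_trace(h$time, h$syn_current[, j] / (eps - h$holding_levels[j]),
                      polarity = if (eps > 0) "E" else "I",
                      method = "per-level", reversal = eps)
  })
  names(out) <- paste0("V", h$holding_levels[keep])
  out
}

#' Least-squares fit of a double-exponential kernel to a conductance trace
#'
#' Fits `g(t) = peak * kernel(t - onset; tau_rise, tau_decay)` (the
#' peak-normalized two-exponential difference) by nonlinear least squares
#' with bounded restarts from perturbed starting values.
#'
#' @param g A [conductance_trace()] or numeric vector.
#' @param time Time grid (ms); taken from `g` when it is a trace.
#' @param max_restarts Restarts with jittered starts before giving up.
#' @return List with `peak` (uS), `tau_rise`, `tau_decay`, `onset` (ms) and
#'   `residual` (RMS of fit residuals).
#' @export
fit_double_exponential <- function(g, time = NULL, max_restarts = 5) {
  if (inherits(g, "conductance_trace")) { time <- g$time; g <- g$g }
  if (is.null(time)) stop("time grid required", call. = FALSE)
  pk <- max(g)
  if (!is.finite(pk) || pk <= 0 || stats::sd(g) == 0) {
    stop("fit failure: trace has no transient to fit", call. = FALSE)
  }
  ipk <- which.max(g)
  above <- which(g > 0.1 * pk)
  onset0 <- time[above[1]]
  # crude decay constant from the time to fall to 1/e of the peak
  after <- which(g[ipk:length(g)] < pk * exp(-1))
  tau_d0 <- if (length(after)) time[ipk + after[1] - 1] - time[ipk] else
    (max(time) - time[ipk]) / 2
  tau_d0 <- max(tau_d0, 2 * mean(diff(time)))
  start <- list(peak = pk, tau_rise = tau_d0 / 3, tau_decay = tau_d0,
                onset = max(onset0 - tau_d0 / 3, min(time)))
  df <- data.frame(t = time, g = g)
  model_fun <- function(t, peak, tau_rise, tau_decay, onset) {
    double_exp_conductance(t, onset, peak, tau_rise, tau_decay)
  }
  dtm <- mean(diff(time))
  for (attempt in seq_len(max_restarts + 1L)) {
    st <- start
    if (attempt > 1L) {
      jit <- function(v) v * stats::runif(1, 0.5, 1.8)
      st <- list(peak = jit(start$peak), tau_rise = jit(start$tau_rise),
                 tau_decay = jit(start$tau_decay),
                 onset = start$onset + stats::rnorm(1, 0, tau_d0 / 4))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ model_fun(t, peak, tau_rise, tau_decay, onset),
        data = df, start = st,
        lower = c(peak = 0, tau_rise = dtm / 10, tau_decay = dtm / 5,
                  onset = min(time) - tau_d0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      res <- sqrt(mean(stats::resid(fit)^2))
      if (res < 0.5 * pk) {
        # report rise < decay regardless of parameterization order
        taus <- sort(c(cf[["tau_rise"]], cf[["tau_decay"]]))
        return(list(peak = cf[["peak"]], tau_rise = taus[1],
                    tau_decay = taus[2], onset = cf[["onset"]],
                    residual = res))
      }
    }
  }
  stop("fit failure: double-exponential fit did not converge after ",
       max_restarts, " restarts (peak = ", signif(pk, 3), ")", call. = FALSE)
}

#' Reference effective conductance from the unclamped point-neuron equation
#'
#' In the absence of any injected current, inverting the somatic
#' point-neuron balance for a single-polarity input gives
#' `g_eff(t) = (c dV/dt + g_L V) / (eps - V)`, using centered finite
#' differences for `dV/dt` (one-sided at the endpoints). Samples where `V`
#' crosses the reversal are masked with a warning.
#'
#' @param time Time grid (ms).
#' @param V Unclamped somatic voltage (mV relative to rest).
#' @param c Somatic capacitance (nF).
#' @param g_L Somatic leak conductance (uS).
#' @param eps Reversal potential (mV relative to rest).
#' @return A [conductance_trace()] with method `"reference"`.
#' @export
reference_from_point_model <- function(time, V, c, g_L, eps) {
  n <- length(V)
  dt <- diff(time)
  dVdt <- numeric(n)
  dVdt[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  dVdt[1] <- (V[2] - V[1]) / dt[1]
  dVdt[n] <- (V[n] - V[n - 1]) / dt[n - 1]
  drive <- eps - V
  g <- (c * dVdt + g_L * V) / drive
  near <- abs(drive) < 1e-6 * abs(eps)
  if (any(near)) {
    warning("masking ", sum(near), " sample(s) where V crosses the reversal",
            call. = FALSE)
    g[near] <- NA_real_
  }
  conductance_trace(time, g, polarity = if (eps > 0) "E" else "I",
                    method = "reference", reversal = eps)
}

#' Effective point-neuron parameters of a cable model's soma
#'
#' The somatic voltage of a spatial neuron responds to somatic current like a
#' point leaky integrator with leak `1/K_SS` (the somatic input conductance,
#' dendritic load included) and an effective time constant. The time constant
#' is measured as the centroid of the somatic step response,
#' `integral (1 - V/V_inf) dt`, which equals the decay constant exactly for a
#' single-exponential response.
#'
#' @param model A passive `cable_model`.
#' @param dt Time step for the step-response simulation (ms).
#' @param duration Step length (ms); should be several membrane time
#'   constants.
#' @return List with `g_L` (uS), `c` (nF) and `tau` (ms).
#' @seealso [reference_from_point_model()]
#' @export
effective_point_params <- function(model, dt = 0.1, duration = 200) {
  G <- conductance_matrix(model)
  inj <- numeric(model$n); inj[model$soma] <- 1
  base <- as.numeric(solve(G, model$g_leak * model$e_leak))
  V <- as.numeric(solve(G, model$g_leak * model$e_leak + inj))
  K_SS <- V[model$soma] - base[model$soma]
  st <- simulate_cable(model,
                       injections = list(current_injection(model$soma, 0.01)),
                       duration = duration, dt = dt)
  Vs <- st$voltage[, model$soma == st$meta$record]
  tau <- sum(1 - Vs / Vs[length(Vs)]) * dt
  list(g_L = 1 / K_SS, c = tau / K_SS, tau = tau)
}

#' Reference effective conductance from the I-V intercept
#'
#' For a single-polarity input the intercept of the clamp-mode I-V line is
#' the effective reversal current, so `g_eff(t) = b(t) / eps`. This is the
#' definition-level reference: the conductance at the soma induced by the
#' input in the absence of injected current.
#'
#' @param iv An `iv_series` from a single-polarity protocol.
#' @param eps Reversal potential of the input (mV relative to rest), nonzero.
#' @return A [conductance_trace()] with method `"reference"`.
#' @export
reference_from_intercept <- function(iv, eps) {
  if (eps == 0) stop("eps must be nonzero", call. = FALSE)
  conductance_trace(iv$time, iv$b / eps,
                    polarity = if (eps > 0) "E" else "I",
                    method = "reference", reversal = eps)
}

#' Error summary of an estimated conductance trace against a reference
#'
#' Two scalar metrics: the relative difference of peak amplitudes,
#' `|max(est) - max(ref)| / max(ref)`, and the time-averaged relative error
#' `integral |est - ref| dt / integral |ref| dt` (ratio of integrals, which
#' stays defined where the reference passes through zero).
#'
#' @param est,ref [conductance_trace()] objects on a shared grid.
#' @return List with `peak_relative_error` and
#'   `time_averaged_relative_error`.
#' @export
error_summary <- function(est, ref) {
  if (length(est$time) != length(ref$time) || any(est$time != ref$time)) {
    stop("estimate and reference must share a time grid", call. = FALSE)
  }
  ok <- is.finite(est$g) & is.finite(ref$g)
  eg <- est$g[ok]; rg <- ref$g[ok]
  if (max(rg) <= 0) stop("reference peak is not positive", call. = FALSE)
  list(
    peak_relative_error = abs(max(eg) - max(rg)) / max(rg),
    time_averaged_relative_error = sum(abs(eg - rg)) / sum(abs(rg))
  )
}
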