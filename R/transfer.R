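#' Measure the transfer-resistance matrix
#'
#' The transfer resistance `K_AB` between compartments A and B is the
#' steady-state voltage change at B per unit current injected at A (MOhm with
#' voltages in mV and currents in nA). For a passive model it is computed
#' from the exact steady-state nodal solve; for an active model it is
#' measured by small-signal simulation of a long current step, averaging the
#' voltage deviation over the late window of the step.
#'
#' @param model A `cable_model`.
#' @param sites Compartment indices to probe.
#' @param probe_current Probe amplitude (nA); small by default so active
#'   models stay near rest. The passive result is independent of it.
#' @param method `"steady"` (exact passive solve), `"simulate"` (small-signal
#'   step), or `"auto"` (steady when `channels` is `NULL`).
#' @param channels Active channel list for the simulated method.
#' @param step_duration Step length (ms) for the simulated method; the last
#'   fifth of the step is averaged.
#' @param dt Time step for the simulated method (ms).
#' @return A `transfer_matrix`: list with `K` (MOhm, probed sites x probed
#'   sites), `sites`, `distance` (um) and `method`.
#' @export
measure_transfer_matrix <- function(model, sites = seq_len(model$n),
                                    probe_current = 0.01,
                                    method = c("auto", "steady", "simulate"),
                                    channels = NULL, step_duration = 500,
                                    dt = 0.1) {
  method <- match.arg(method)
  if (probe_current <= 0) stop("probe_current must be > 0", call. = FALSE)
  if (any(sites < 1 | sites > model$n)) stop("invalid site index", call. = FALSE)
  if (method == "auto") method <- if (is.null(channels)) "steady" else "simulate"
  ns <- length(sites)
  K <- matrix(NA_real_, ns, ns)
  if (method == "steady") {
    G <- conductance_matrix(model)
    base <- as.numeric(solve(G, model$g_leak * model$e_leak))
    for (i in seq_len(ns)) {
      inj <- numeric(model$n); inj[sites[i]] <- probe_current
      V <- as.numeric(solve(G, model$g_leak * model$e_leak + inj))
      K[i, ] <- (V[sites] - base[sites]) / probe_current
    }
  } else {
    nwin <- function(tr) {
      i0 <- ceiling(0.8 * length(tr$time))
      colMeans(tr$voltage[i0:length(tr$time), , drop = FALSE])
    }
    base <- simulate_cable(model, duration = step_duration, dt = dt,
                           record = sites, channels = channels)
    vb <- nwin(base)
    # require the baseline itself to be settled
    v_late <- base$voltage[nrow(base$voltage), ]
    for (i in seq_len(ns)) {
      tr <- simulate_cable(
        model, injections = list(current_injection(sites[i], probe_current)),
        duration = step_duration, dt = dt, record = sites, channels = channels)
      vp <- nwin(tr)
      drift <- max(abs(tr$voltage[nrow(tr$voltage), ] -
                       tr$voltage[ceiling(0.8 * nrow(tr$voltage)), ]))
      if (drift > 0.05 * max(abs(vp - vb), 1e-9)) {
        stop("active model did not reach steady state within the probe window",
             call. = FALSE)
      }
      K[i, ] <- (vp - vb) / probe_current
    }
  }
  structure(list(K = K, sites = sites, distance = model$distance[sites],
                 probe_current = probe_current, method = method),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Transfer matrix: %d sites (%s method), K_SS candidates on diagonal\n",
              length(x$sites), x$method))
  print(round(x$K[seq_len(min(6, nrow(x$K))), seq_len(min(6, ncol(x$K))),
                  drop = FALSE], 3))
  invisible(x)
}

#' Prefactor map K_XS / K_SS over the tree
#'
#' The first-order proportionality between the effective conductance at the
#' soma and the local conductance at compartment X is the ratio of the
#' transfer resistance `K_XS` to the somatic input resistance `K_SS`. On a
#' passive tree the ratio is 1 at the soma and decays towards the tips.
#'
#' @param model A passive `cable_model`.
#' @return A data frame with columns `site`, `distance` (um) and `ratio`.
#' @export
prefactor_map <- function(model) {
  G <- conductance_matrix(model)
  inj <- numeric(model$n); inj[model$soma] <- 1
  V <- as.numeric(solve(G, model$g_leak * model$e_leak + inj))
  base <- as.numeric(solve(G, model$g_leak * model$e_leak))
  dV <- V - base
  ratio <- dV / dV[model$soma]   # K_XS / K_SS by reciprocity
  structure(data.frame(site = seq_len(model$n), distance = model$distance,
                       ratio = ratio),
            class = c("prefactor_map", "data.frame"))
}

#' @export
plot.prefactor_map <- function(x, ...) {
  graphics::plot(x$distance, x$ratio, xlab = "path distance from soma (um)",
                 ylab = expression(K[XS] / K[SS]), ylim = c(0, 1), ...)
  invisible(x)
}

#' Maximum relative asymmetry of a transfer matrix
#'
#' Passive linear cables obey reciprocity, `K_XY = K_YX`; active membranes
#' break it only weakly near rest. Returns
#' `max over pairs |K_ij - K_ji| / max(|K_ij|, |K_ji|)`.
#'
#' @param K A `transfer_matrix` or a square numeric matrix.
#' @return Dimensionless asymmetry in `[0, Inf)`; 0 for a symmetric matrix.
#' @export
reciprocity_deviation <- function(K) {
  if (inherits(K, "transfer_matrix")) K <- K$K
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square", call. = FALSE)
  if (nrow(K) < 2) return(0)
  dev <- 0
  for (i in seq_len(nrow(K) - 1)) {
    for (j in (i + 1):ncol(K)) {
      m <- max(abs(K[i, j]), abs(K[j, i]))
      if (m > 0) dev <- max(dev, abs(K[i, j] - K[j, i]) / m)
    }
  }
  dev
}

#' Export a transfer matrix to CSV
#'
#' Long-format export with site metadata (compartment index and path distance
#' from the soma).
#'
#' @param tm A `transfer_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(tm, path) {
  ns <- length(tm$sites)
  df <- data.frame(
    from = rep(tm$sites, each = ns), to = rep(tm$sites, ns),
    from_distance = rep(tm$distance, each = ns),
    to_distance = rep(tm$distance, ns),
    K_MOhm = as.vector(t(tm$K)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
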