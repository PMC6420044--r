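#' Two-port (three-site) transfer-resistance parameters
#'
#' The static description of a neuron receiving one excitatory and one
#' inhibitory input on the dendrite while clamped at the soma: the six
#' transfer resistances between the E site, the I site and the soma, plus the
#' two synaptic reversal potentials. Reciprocity (`K_SE = K_ES` etc.) is
#' assumed, as holds for passive cables.
#'
#' @param K_EE,K_II,K_SS Input resistances at the E site, I site and soma
#'   (MOhm); all positive.
#' @param K_ES,K_IS Transfer resistances from the input sites to the soma
#'   (MOhm).
#' @param K_EI Transfer resistance between the two input sites (MOhm).
#' @param eps_E,eps_I Reversal potentials (mV relative to rest). Defaults 70
#'   and -10 (absolute 0 mV and -80 mV at a -70 mV rest).
#' @return A `two_port_params` list.
#' @seealso [colocated_two_port()] for the co-located convenience form.
#' @export
two_port_params <- function(K_EE, K_II, K_SS, K_ES, K_IS, K_EI,
                            eps_E = 70, eps_I = -10) {
  if (K_SS <= 0) stop("K_SS must be positive", call. = FALSE)
  vals <- c(K_EE, K_II, K_SS, K_ES, K_IS, K_EI, eps_E, eps_I)
  if (!all(is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  structure(list(K_EE = K_EE, K_II = K_II, K_SS = K_SS, K_ES = K_ES,
                 K_IS = K_IS, K_EI = K_EI, eps_E = eps_E, eps_I = eps_I),
            class = "two_port_params")
}

#' Co-located two-port parameters
#'
#' When the E and I inputs share a dendritic site, `K_ES = K_IS = alpha K_SS`
#' and the local input resistances coincide (`K_EE = K_II = K_EI`). `alpha`
#' is the space-clamp prefactor; `alpha = 1` recovers somatic inputs, where
#' the traditional slope-and-intercept decomposition is exact.
#'
#' @param alpha Prefactor `K_XS / K_SS` in (0, 1].
#' @param K_SS Somatic input resistance (MOhm).
#' @param K_XX Local input resistance at the shared site (MOhm); defaults to
#'   `K_SS`. Passive consistency requires `K_XX >= alpha^2 * K_SS`.
#' @param eps_E,eps_I Reversal potentials (mV relative to rest).
#' @return A `two_port_params` list.
#' @export
colocated_two_port <- function(alpha, K_SS = 100, K_XX = K_SS,
                               eps_E = 70, eps_I = -10) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (K_XX < alpha^2 * K_SS) {
    stop("K_XX must be at least alpha^2 * K_SS for a passive system",
         call. = FALSE)
  }
  two_port_params(K_EE = K_XX, K_II = K_XX, K_SS = K_SS,
                  K_ES = alpha * K_SS, K_IS = alpha * K_SS, K_EI = K_XX,
                  eps_E = eps_E, eps_I = eps_I)
}

#' Exact effective conductance for a single static input
#'
#' For a constant local conductance `g` at a dendritic site q, the somatic
#' voltage is `V_S = g K_qS eps_q / (1 + g K_qq)` and the effective
#' conductance seen at the soma is `g_eff = V_S / (K_SS (eps_q - V_S))`. At
#' the soma (`K_qS = K_qq = K_SS`) this returns `g` exactly; for small `g`
#' the ratio `g_eff / g` tends to the prefactor `K_qS / K_SS`.
#'
#' @param g Local conductance (uS), nonnegative.
#' @param K_qS Transfer resistance site-to-soma (MOhm).
#' @param K_SS Somatic input resistance (MOhm).
#' @param K_qq Input resistance at the site (MOhm).
#' @param eps_q Reversal potential (mV relative to rest), nonzero.
#' @return Effective conductance (uS).
#' @export
effective_conductance_exact <- function(g, K_qS, K_SS, K_qq, eps_q) {
  if (g < 0) stop("g must be >= 0", call. = FALSE)
  V_S <- g * K_qS * eps_q / (1 + g * K_qq)
  if (any(abs(eps_q - V_S) < .Machine$double.eps * abs(eps_q))) {
    stop("singular driving force: somatic voltage equals the reversal",
         call. = FALSE)
  }
  V_S / (K_SS * (eps_q - V_S))
}

#' Relative error of the first-order effective-conductance expansion
#'
#' Truncating the geometric series for `1/(1 - x)` after the linear term,
#' where `x = V_S / eps` is the somatic deflection expressed as a fraction of
#' the reversal potential, leaves a relative error of exactly `x^2`. For an
#' IPSP of -3 mV against an inhibitory reversal of -10 mV (x = 0.3) the error
#' is 0.09, i.e. about 9 percent.
#'
#' @param x Ratio `V_S / eps`, with `|x| < 1`.
#' @return Relative error (dimensionless), `x^2`.
#' @examples
#' first_order_expansion_error(0.3)  # 0.09
#' @export
first_order_expansion_error <- function(x) {
  if (any(abs(x) >= 1)) stop("|x| must be < 1", call. = FALSE)
  x^2
}

# common denominator of the exact three-site solution
two_port_denom <- function(p, gE, gI) {
  1 + gE * p$K_EE + gI * p$K_II + gE * gI * (p$K_EE * p$K_II - p$K_EI^2)
}

#' Exact somatic voltage under clamp current and dual dendritic input
#'
#' Closed-form solution of the static three-site system (E site, I site,
#' soma) for the somatic voltage given local conductances `gE`, `gI` and an
#' injected somatic current `I_inj`. The expression is exact to all orders in
#' the conductances and is linear in `I_inj`.
#'
#' @param p A [two_port_params()] object.
#' @param gE,gI Local conductances (uS).
#' @param I_inj Injected somatic current (nA).
#' @return Somatic voltage (mV relative to rest).
#' @export
exact_soma_voltage <- function(p, gE, gI, I_inj = 0) {
  D <- two_port_denom(p, gE, gI)
  if (any(abs(D) < 1e-14)) stop("singular two-port system", call. = FALSE)
  with(p, {
    (gE * eps_E * (K_ES + gI * (K_ES * K_II - K_EI * K_IS)) +
     gI * eps_I * (K_IS + gE * (K_IS * K_EE - K_EI * K_ES)) +
     I_inj * (K_SS + gE * (K_EE * K_SS - K_ES^2) + gI * (K_II * K_SS - K_IS^2)) -
     I_inj * gE * gI * (K_ES^2 * K_II + K_EE * K_IS^2 + K_EI^2 * K_SS -
                        K_EE * K_II * K_SS - 2 * K_EI * K_ES * K_IS)) / D
  })
}

#' Exact clamp-mode synaptic current
#'
#' The synaptic current arriving at the soma in the presence of the injected
#' clamp current, `I_syn = V_S / K_SS - I_inj`. The product terms between the
#' synaptic conductances and `I_inj` are the nonlinear interaction between
#' clamp current and dendritic synaptic current that the traditional method
#' neglects.
#'
#' @inheritParams exact_soma_voltage
#' @return Synaptic current (nA); positive values depolarize.
#' @export
exact_syn_current <- function(p, gE, gI, I_inj = 0) {
  exact_soma_voltage(p, gE, gI, I_inj) / p$K_SS - I_inj
}

#' Exact clamp-mode I-V line
#'
#' Both the somatic voltage and the clamp-mode synaptic current are linear in
#' the injected current, so eliminating `I_inj` yields the line
#' `I_syn = -k V_S + b`. Returns the full-order slope and intercept; the
#' identity `I_syn = -k V_S + b` holds for every `I_inj`.
#'
#' @param p A [two_port_params()] object.
#' @param gE,gI Local conductances (uS).
#' @return An `iv_line`: list with `k` (uS) and `b` (nA).
#' @export
iv_line_exact <- function(p, gE, gI) {
  with(p, {
    K_EIS <- K_EE * K_II * K_SS + 2 * K_EI * K_ES * K_IS -
      K_ES^2 * K_II - K_IS^2 * K_EE - K_EI^2 * K_SS
    den <- K_SS + gE * (K_EE * K_SS - K_ES^2) + gI * (K_II * K_SS - K_IS^2) +
      gE * gI * K_EIS
    if (any(abs(den) < 1e-14)) stop("singular two-port system", call. = FALSE)
    k <- (gE * K_ES^2 + gI * K_IS^2 +
          gE * gI * (K_ES^2 * K_II + K_IS^2 * K_EE - 2 * K_EI * K_ES * K_IS)) /
      (K_SS * den)
    b <- (gE * eps_E * K_ES + gI * eps_I * K_IS +
          gE * gI * (eps_E * (K_ES * K_II - K_EI * K_IS) +
                     eps_I * (K_IS * K_EE - K_EI * K_ES))) / den
    structure(list(k = k, b = b), class = "iv_line")
  })
}

#' First-order clamp-mode I-V line
#'
#' To first order in the local conductances the slope and intercept are
#' `k = (K_ES/K_SS)^2 gE + (K_IS/K_SS)^2 gI` and
#' `b = (K_ES/K_SS) gE eps_E + (K_IS/K_SS) gI eps_I`: the slope carries the
#' squared prefactors, while the intercept equals the effective reversal
#' current `gE_eff eps_E + gI_eff eps_I`. For somatic inputs (prefactors 1)
#' these reduce to the traditional relations `k = gE + gI`,
#' `b = gE eps_E + gI eps_I`.
#'
#' @inheritParams iv_line_exact
#' @return An `iv_line` list with `k` (uS) and `b` (nA).
#' @export
iv_line_first_order <- function(p, gE, gI) {
  rE <- p$K_ES / p$K_SS; rI <- p$K_IS / p$K_SS
  structure(list(k = rE^2 * gE + rI^2 * gI,
                 b = rE * gE * p$eps_E + rI * gI * p$eps_I),
            class = "iv_line")
}

#' @export
print.iv_line <- function(x, ...) {
  cat(sprintf("I-V line: I_syn = -k V + b, k = %.6g uS, b = %.6g nA\n",
              x$k, x$b))
  invisible(x)
}

#' Slope-and-intercept (traditional) conductance decomposition
#'
#' Solves `k = gE + gI`, `b = gE eps_E + gI eps_I` for the two conductances.
#' Valid only for somatic inputs; for dendritic inputs the slope is
#' contaminated by the squared space-clamp prefactors and the solution is
#' biased, possibly negative. Negative outputs are returned unclipped and
#' flagged, since unphysical negativity is the diagnostic signature of the
#' method's failure.
#'
#' @param k Slope (uS).
#' @param b Intercept (nA).
#' @param eps_E,eps_I Reversal potentials (mV relative to rest); must differ.
#' @return List with `gE`, `gI` (uS) and `negative` (logical flag).
#' @export
sim_solve <- function(k, b, eps_E = 70, eps_I = -10) {
  if (any(eps_E == eps_I)) stop("eps_E must differ from eps_I", call. = FALSE)
  gE <- (b - k * eps_I) / (eps_E - eps_I)
  gI <- (k * eps_E - b) / (eps_E - eps_I)
  list(gE = gE, gI = gI, negative = (gE < 0) | (gI < 0))
}

#' Intercept-method conductance decomposition
#'
#' Uses only I-V intercepts: `b = gE_eff eps_E + gI_eff eps_I` together with
#' a second intercept `b'` obtained after shifting the inhibitory reversal to
#' `eps_I'`, giving `gI_eff = (b - b') / (eps_I - eps_I')` and
#' `gE_eff = (b - gI_eff eps_I) / eps_E`. The slope — and with it the unknown
#' space-clamp prefactors — is never used.
#'
#' @param b,b_prime Intercepts (nA) at the two inhibitory reversals.
#' @param eps_E Excitatory reversal (mV relative to rest), nonzero.
#' @param eps_I,eps_I_prime The two inhibitory reversals (mV relative to
#'   rest); must differ.
#' @return List with `gE_eff`, `gI_eff` (uS) and `negative` flag.
#' @export
im_solve <- function(b, b_prime, eps_E = 70, eps_I = -10, eps_I_prime = -20) {
  if (any(eps_I == eps_I_prime)) {
    stop("eps_I must differ from eps_I_prime", call. = FALSE)
  }
  if (any(eps_E == 0)) stop("eps_E must be nonzero", call. = FALSE)
  gI <- (b - b_prime) / (eps_I - eps_I_prime)
  gE <- (b - gI * eps_I) / eps_E
  list(gE_eff = gE, gI_eff = gI, negative = (gE < 0) | (gI < 0))
}

#' Predicted error of the traditional method for co-located inputs
#'
#' For E and I inputs at a shared site with prefactor `alpha = K_XS / K_SS`,
#' the absolute errors of the traditional slope-and-intercept estimates are
#' `dgE = k eps_I (1 - 1/alpha) / (eps_I - eps_E)` and
#' `dgI = k eps_E (1 - 1/alpha) / (eps_E - eps_I)` where `k` is the measured
#' slope. Both are nonpositive for `alpha <= 1` (the traditional method
#' always underestimates) and their ratio is `-eps_I : eps_E` identically, so
#' the inhibitory estimate is distorted far more than the excitatory one
#' whenever `|eps_I| << eps_E`.
#'
#' @param k Measured I-V slope (uS).
#' @param alpha Space-clamp prefactor in (0, 1].
#' @param eps_E,eps_I Reversal potentials (mV relative to rest).
#' @return List with `dgE`, `dgI` (uS).
#' @export
sim_error_prediction <- function(k, alpha, eps_E = 70, eps_I = -10) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(alpha > 1)) stop("alpha must be <= 1", call. = FALSE)
  list(dgE = k * eps_I * (1 - 1 / alpha) / (eps_I - eps_E),
       dgI = k * eps_E * (1 - 1 / alpha) / (eps_E - eps_I))
}

#' Witness for the nonexistence of a local-to-measured transform
#'
#' If a transform from the local conductance to the traditionally measured
#' conductance existed, its first-order Taylor coefficient would have to
#' equal both the squared prefactor (from matching the slope equation) and
#' the prefactor itself (from matching the intercept equation). These agree
#' only when `K_XS = K_SS`, i.e. only for somatic inputs; for any dendritic
#' site the two requirements contradict, so no transform exists.
#'
#' @param p A [two_port_params()] object.
#' @return List with `F1_slope` (`(K_ES/K_SS)^2`), `F1_intercept`
#'   (`K_ES/K_SS`), `G1_slope`, `G1_intercept`, and `contradiction` (TRUE
#'   when a transform cannot exist).
#' @export
no_transform_witness <- function(p) {
  rE <- p$K_ES / p$K_SS; rI <- p$K_IS / p$K_SS
  list(F1_slope = rE^2, F1_intercept = rE,
       G1_slope = rI^2, G1_intercept = rI,
       contradiction = (rE^2 != rE) || (rI^2 != rI))
}
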