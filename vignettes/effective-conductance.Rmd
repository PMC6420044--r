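---
title: "Effective synaptic conductance under somatic voltage clamp: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective synaptic conductance under somatic voltage clamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synclamp)
```

## The model

A neuron is represented as a tree of passive cable compartments. Each
compartment `i` obeys the current balance

$$ C_i \frac{dV_i}{dt} = -g_{L,i}(V_i - \varepsilon_L)
   - \sum_s g_s(t)\,(V_i - \varepsilon_s)
   + \sum_{j \sim i} g_{a,ij}(V_j - V_i) + I_{inj,i}, $$

with all potentials relative to the resting potential, so the resting state
is $V \equiv 0$. Membrane quantities come from the specific passive
parameters and the compartment's frustum area; axial conductances from the
axial resistivity and frustum geometry; the soma is collapsed to a single
point compartment. Synapses are conductance inputs (dynamic-clamp
semantics): peak-normalized double-exponential waveforms
$g(t) \propto |e^{-t/\tau_d} - e^{-t/\tau_r}|$ with AMPA-type (5/7.8 ms,
reversal +70 mV relative) and GABA-A-type (6/18 ms, -10 mV relative)
defaults. The printed two-exponential difference is negative when
$\tau_r < \tau_d$ is substituted directly; we use the absolute-valued,
peak-normalized form so that the labeled rise/decay constants and the stated
peak amplitude (2.5 nS E, 4 nS I by default) are honored regardless of the
sign order of the two exponentials.

Key default parameters:

| parameter | default | units | notes |
|---|---|---|---|
| axial resistivity | 150 | Ohm cm | generic pyramidal-cell value |
| specific capacitance | 1 | uF/cm^2 | |
| leak conductance | 5e-5 | S/cm^2 | membrane resistivity 20 kOhm cm^2 |
| time step `dt` | 0.1 | ms | see numerics below |
| holding levels | -20..+20 | mV rel. rest | -90..-50 mV absolute at -70 mV rest |
| inhibitory reversal variants | -10, -20 | mV rel. rest | -80, -90 mV absolute |

Measured passive properties vary widely across preparations, so all of these
are user-overridable; absolute potentials are converted to the
relative-to-rest convention at the configuration boundary.

## Voltage clamp and the clamp-mode synaptic current

The ideal somatic clamp is implemented by node substitution: the clamped row
of each linear system is replaced by $V_{soma} = V_{hold}$, so the clamped
voltage is exact by construction, and the clamp current is recovered from
the eliminated balance equation. Series-resistance and imperfect-control
effects are deliberately out of scope: the analysis assumes the soma itself
is well controlled.

The observable of every protocol is the baseline-subtracted clamp current,
`syn_current(t) = baseline - clamp_current(t)`, where the baseline is the
steady holding current just before stimulus onset. With this sign
convention an excitatory input at a holding level below its reversal
produces a positive synaptic current. Clamped runs are initialized at the
synapse-free clamped steady state, so the baseline is flat from the first
sample and a long settle period is unnecessary.

## Numerics

Time integration is an implicit trapezoid (Crank–Nicolson) step with one
exact dense linear solve per step and synaptic conductances evaluated at the
half step. The scheme is unconditionally stable, which is what makes the
0.1 ms default step safe; the packaged fixtures change their peak clamp-mode
synaptic current by less than 0.5% when the step is halved (this is a test).
The clamp current is read out as the instantaneous nodal balance of the
clamped compartment at each sample time, which makes the point-neuron clamp
identity $I_{syn}(t) = g(t)(\varepsilon - V_{hold})$ exact rather than
accurate to $O(dt)$. Steady states (transfer resistances, constant-input
protocols) use exact linear solves, not time stepping. Degenerate
zero-length morphology segments are collapsed with a warning; integration
aborts with an informative error if any voltage exceeds 500 mV.

A generic voltage-gated channel interface (gating variables with
alpha/beta rate functions, exponential gate updates) is included with a
textbook transient-Na/delayed-rectifier pair at low density. Its only
packaged role is to verify that transfer-resistance reciprocity — exact in
any passive linear cable — survives approximately (relative asymmetry well
below 0.1) when weak active conductances are present near rest. The
realistic channel repertoire of hippocampal pyramidal neurons is out of
scope.

## Transfer resistances and the static theory

`measure_transfer_matrix()` probes $K_{AB}$, the steady voltage change at B
per unit current at A (MOhm); passive models use the exact solve, active
models a small-signal step (0.01 nA default, late-window average of a 500 ms
step — small enough to stay near rest, long enough to be static). The
prefactor map $K_{XS}/K_{SS}$ equals 1 at the soma and decays towards the
tips; it is the first-order ratio of effective to local conductance.

The static three-site theory (E site, I site, soma) is implemented in closed
form: the exact somatic voltage and clamp-mode synaptic current under
constant conductances and injected current, the exact and first-order I-V
lines, the SIM and IM solvers, the SIM error laws, and the
contradiction witness showing no transform exists between local and
SIM-measured conductances. All closed forms are tested against a brute-force
numerical solve of the underlying five-unknown linear system (1000 random
positive-definite parameter draws, 1e-10 relative tolerance).

## Estimators

* **Per-time-point I-V regression** — unweighted ordinary least squares of
  the synaptic current on the holding voltage at each sample (the protocol
  states no weighting, and the per-level noise is homoscedastic by
  construction); with two levels the fit is exact interpolation.
* **SIM** — the traditional decomposition, applied per time point. Negative
  outputs are returned unclipped and flagged: unphysical negativity is the
  method's diagnostic failure mode, not a numerical artifact to hide.
* **IM** — intercepts from two protocols that differ only in the inhibitory
  reversal.
* **Per-level conductance** — $I_{syn}/(\varepsilon - V_{hold})$ per holding
  level; the spread of these traces across levels is direct evidence of the
  clamp/synapse interaction. Levels at the reversal potential are excluded
  (singular driving force) with a warning; they are retained in the I-V
  regression, which has no singularity there.
* **References** — for a single-polarity input, the intercept divided by the
  reversal is the effective conductance by definition (and, in the static
  limit, exactly at all orders). The alternative point-model reference
  inverts $g = (c\,dV/dt + g_L V)/(\varepsilon - V)$ on the unclamped
  somatic voltage, using the *effective* somatic point parameters
  ($g_L = 1/K_{SS}$ with the dendritic load included, and the step-response
  centroid time constant): using the bare soma compartment's capacitance and
  leak would ignore the dendrite entirely. The point integrator remains an
  approximation of a cable soma; on the packaged 100 um fixture the two
  reference peaks agree to about 6%, and the intercept-based reference is
  the one used for error scoring.
* `fit_double_exponential()` recovers waveform parameters by bounded
  nonlinear least squares with jittered restarts.

Error metrics: the two headline numbers are the relative difference of peak
amplitudes and a time-averaged relative error. The latter is not defined by
a formula in the source literature; we fix
$\int |est - ref|\,dt / \int |ref|\,dt$ (ratio of integrals), which stays
defined where the reference passes through zero.

## Experiments and fixtures

`gen_schedule()` draws input sites uniformly over the dendritic compartments
and gives each site a *fixed* count of `round(rate x window / 1000)`
uniformly distributed onset times: a fixed count (rather than a Poisson
draw) matches a stated rate over a fixed window and keeps totals
reproducible under the seed. `run_protocol()` orchestrates the full IM
measurement: five-level clamp series at both inhibitory reversals with
identical inputs, single-polarity reference series, regression, and both
estimates.

The packaged study conditions, chosen once:

* **Proximal pair fixture** — ball-and-stick, 400 um x 2 um dendrite, 20 um
  soma, co-located 2.5 nS E / 4 nS I transient pair 100 um from the soma:
  the dynamic-clamp experimental configuration at desk scale.
* **Distal fixture** — 1500 um x 1.5 um stick, pair at 1300 um. With the
  default passive parameters the electrotonic length is about 2.1, giving a
  space-clamp prefactor of roughly 0.24 at the input site — inside the
  regime where the SIM inhibitory estimate turns negative (the closed-form
  threshold for the 2.5:4 nS ratio is a prefactor near 0.3).
* **Branched fixture** — a seeded random tree (3 levels, 0.7 branch
  probability, ~450 um maximal path distance) for reciprocity properties and
  the reversal-invariance sweep.
* **Error-map scan** — constant-conductance E/I pairs scanned along the
  distal fixture using exact clamped steady states. Amplitudes are 0.05 nS
  E / 0.08 nS I, preserving the 2.5:4 E:I ratio: the transient amplitudes
  put a thin distal dendrite far outside the small-signal regime (local
  $g \cdot K_{XX}$ of order 1–3), whereas the first-order statements the map
  illustrates — SIM error growing monotonically with distance, IM error
  staying within a few percent, distal SIM negativity — are claims about the
  small-$g$ regime. The negativity threshold itself is amplitude-independent
  at first order, so the map's white region is not an artifact of the small
  amplitudes.

Sub-threshold amplitudes are used throughout (unclamped somatic deflections
stay within ~15 mV of rest). Reduced problem sizes — 40–70 compartments,
100–200 ms windows, five holding levels — keep the full test suite and the
acceptance computation to a few minutes; the statements under test
(orderings, scalings, invariances) are resolution-independent well before
these sizes.

## What the synthetic data does and does not establish

The generators emulate: branched passive trees with realistic passive
constants, dynamic-clamp double-exponential conductance injections at
defined dendritic sites, ideal five-level somatic clamp protocols,
inhibitory-reversal shifts, and optional Gaussian recording noise. They do
not emulate: active dendritic conductances beyond the textbook test pair,
synaptic noise and trial-to-trial variability of real networks, NMDA voltage
dependence, electrode series resistance, or spines. Passing tests therefore
establish the *mechanism* — the slope, not the intercept, is corrupted by
the space-clamp prefactors, IM dominates SIM wherever inputs are dendritic,
SIM distorts inhibition by the factor $-\varepsilon_I:\varepsilon_E$ more
than excitation, and negative SIM conductances arise at small prefactors —
but not the specific error percentages of any particular real neuron, which
depend on its morphology and channel densities.

Two quantitative observations deserve a note. First, in a purely passive
model the intercept-based effective conductance is *exactly* invariant under
reversal-potential changes (the clamped cable is linear and the synaptic
drive enters proportionally to the reversal), so the packaged
reversal-invariance sweep returns a coefficient of variation at rounding
level, far inside the few-percent invariance reported for active neurons.
Second, the IM recovery error against the first-order effective conductance
is governed by the dimensionless product of local conductance and local
input resistance; it scales as $O(g^2)$ absolutely (halving $g$ quarters
it), and percent-level accuracy statements only make sense once
$g \cdot K$ is of order $10^{-2}$ — at 2–5 nS on a thin distal dendrite
(hundreds of MOhm to GOhm) the pair interaction is genuinely beyond first
order, and the package reports recovery-error-versus-$g$ behavior rather
than asserting a universal threshold.

## Other design decisions

* Distances are 3D path lengths along the tree (zig-zag geometry), not
  straight-line distances.
* SWC import accepts the standard 7 columns, maps every non-soma type to
  dendrite, collapses multi-point somata to one electrical node, and keeps
  the file's node order when it is already topological (making
  write-then-read an exact identity); otherwise nodes are re-ordered
  breadth-first with original ids kept as labels.
* The compartmental discretization exposes a maximum segment length rather
  than a fixed compartment count; the reference reconstruction granularity
  of any particular study is not reproducible from published information.
* The baseline holding current is re-measured in every clamped run (per
  level and per reversal variant) rather than once per cell.
* Trace interchange is tidy CSV (`time, site, variable, value, holding,
  replicate`); at the problem sizes involved a binary container adds nothing.
* The co-located two-port convenience constructor defaults the local input
  resistance to $K_{XX} = K_{SS}$, a moderate passively consistent choice
  (any $K_{XX} \ge \alpha^2 K_{SS}$ is admissible).

## Limitations

The static theory is first order in the conductances; the estimators are
multi-trial (inputs must repeat across holding levels and reversal
variants); the effective conductance characterizes synaptic impact *at the
soma*, not local dendritic nonlinearities; and shifting an inhibitory
reversal is experimentally invasive — in simulation it is free, which is
precisely why the simulator exists.
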