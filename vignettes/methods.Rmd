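---
title: "Methods: response detection, latency statistics and the AND-gate membrane model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response detection, latency statistics and the AND-gate membrane model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiagate)
```

# Scope

`aiagate` quantifies single-trial GCaMP responses in *C. elegans*
chemosensory neurons and interneurons, and simulates the biophysical
mechanism — a bistable membrane gated by coincident excitation and
disinhibition — that explains why a downstream interneuron like AIA
responds reliably only to an integrated sensory state. The pipeline starts
from extracted fluorescence traces (one row per stimulus pulse); video
ingestion, ROI tracking and motion registration are out of scope.

# Trace model and preprocessing

A recording is an ensemble of raw fluorescence traces sampled at 10
frames/s, with a 10 s stimulus pulse embedded after at least 10 s of
baseline. Frame indices in metadata are 0-based and the stimulus window is
half-open, `[stim_onset, stim_offset)`, so `stim_onset` doubles as the
number of pre-stimulus frames; a trace latency in seconds is
`(onset_frame - stim_onset) / frame_rate`. Traces containing any
non-finite value are flagged and excluded from every computation but never
dropped from the file, so pulse numbering and metadata pairing are stable.

Preprocessing follows the conventions of the imaging literature:

* **dF/F0** — `compute_dff()` uses the *median* of the 100 pre-stimulus
  frames (10 s) as F0. The median is robust to occasional baseline
  transients; a zero F0 is a hard error rather than a silent Inf.
* **Smoothing** — `smooth_trace()` is a 5-frame centered boxcar. At the
  trace boundaries the window is truncated to the available frames (the
  convention is unstated in the source methods; truncation preserves the
  trace length and is linear, which the tests exploit).
* **Min–max scaling** — inhibition calling operates on the trace scaled
  to [0, 1]. The scale window defaults to the full trace; because
  scaling is affine-invariant it makes no difference whether the raw or
  dF/F0 trace is scaled. Whether the original analysis scaled over the
  full recording or only the pulse epoch is unknowable from the text; the
  full trace is the less parameterized choice and is exposed as an
  argument.
* **Bleach correction** — for constant-illumination recordings,
  `bleach_correct()` fits a least-squares line to the non-stimulus
  frames and returns `(F - L)/L`, i.e. divides by the fitted line rather
  than by a constant F0. Only the linear model is provided; exponential
  detrending is a non-goal.

# Response calling

Activation: the onset is the first frame `t` in the stimulus window at
which the mean smoothed dF/F0 over `t..t+12` strictly exceeds the
pre-stimulus mean by 2 pre-stimulus SDs, *and* the one-frame forward
derivative at `t` exceeds the pre-stimulus derivative mean by 1 derivative
SD. Inhibition (on the scaled trace): the mean over `t..t+10` falls below
the pre-stimulus mean by 2 SDs, and the mean derivative over `t..t+10`
falls below by 0.5 SDs *or* over `t..t+5` by 1.15 SDs.

Reading notes baked into the implementation:

* "exceeded two standard deviations of the mean" is read as exceeding
  `mean + 2*SD`; thresholds for inhibition are `mean - k*SD`. This is the
  standard reading and the one consistent with the inflection-point
  justification that `threshold_sweep()` reproduces.
* Baseline statistics are computed on the same signal the criteria are
  evaluated on (smoothed dF/F0 for activation, scaled trace for
  inhibition), because the criteria are stated on those signals.
* Derivatives are forward differences per frame. They are not converted
  to per-second units: every threshold is a multiple of the baseline SD
  of the same quantity, so units cancel.
* Inequalities are strict; a frame whose look-ahead window would run past
  the end of the *trace* is ineligible (windows may dangle past the
  stimulus offset).
* A zero baseline SD (possible on degenerate synthetic input) reduces the
  threshold to strict exceedance of the mean and flags the call.
* The source methods state the activation derivative multiplier as 1 SD
  in the operational sentence but 2 SD in the justification paragraph.
  The operational value (1) is the default; the constant is a parameter
  (`act_deriv_mult`), not a hard-coded resolution of the discrepancy.

Two behavioral consequences are worth knowing. The magnitude criterion
looks 12 frames ahead, so on a strong transient the call can precede the
true signal start by up to `act_window` frames (the derivative criterion,
at 1 SD, is lenient enough that baseline noise can supply it). Conversely
on slow declines the inhibition window mean needs several frames below
threshold before it clears 2 SDs. The detector is therefore validated not
against fixed offsets but by *oracle equivalence*: on every tested trace
its calls must equal a naive per-frame transcription of the published
criteria, exactly. Monotonicity (raising any multiplier never creates a
call or makes one earlier) is tested as a property.

Magnitudes use the two published definitions: end-of-pulse mean minus
pre-onset mean (`magnitude_sensory()`, sign-free) for non-adapting sensory
responses, and the within-pulse peak (`magnitude_peak()`) for adapting
ones. Both, and the 33%-to-66% rise time, are computed here on the
smoothed dF/F0 — the same signal detection sees; the source text does not
say whether its magnitudes were smoothed, and the 5-frame boxcar changes a
peak by at most a few percent at these kinetics.

# Cumulative profiles, KS comparison, bootstrap lag

A cumulative response-time profile is the fraction of *all* trials that
have responded by time `t` on the frame grid; non-responders stay in the
denominator forever. The two-sample comparison takes `D` as the largest
absolute gap between two such curves — this treats non-responding trials
as right-censored mass at the horizon, which is exactly why the test
"captures both the latencies and probability of response". Group sizes
are total trial counts.

The p-value is the asymptotic Kolmogorov tail
`2 * sum((-1)^(k-1) * exp(-2 k^2 lambda^2))` (terms truncated below
1e-10) at `lambda = sqrt(ne) * D`, `ne = n1*n2/(n1+n2)`. The *uncorrected*
lambda is the default deliberately: it reproduces the published worked
example (`D = 0.470`, `n = 28, 24` gives `p = 0.0066`, printed as 0.007),
which pins down the exact variant the original analysis used. The
Stephens small-sample form is available via `correction = "stephens"` but
both variants share a caveat: with ~40 trials per group, `D` is discrete
and even the exact two-sample test rejects well under 5% at nominal 5%.
The suite asserts validity (the test is conservative, never
anti-conservative) rather than exact nominal calibration, which no
faithful implementation of this procedure attains at these sizes.

The lag between an upstream and a downstream population is the difference
of their 50%-response times — the first frame at which the cumulative
curve reaches 0.5, with no interpolation. Uncertainty comes from
resampling whole trials with replacement within each group (default 1000
draws, one user seed for everything); the SD of the resampled lags is
reported as the standard error, resamples in which either group fails to
reach 50% are excluded and counted, and an undefined point estimate is
reported as such rather than guessed. The bootstrap SEM is validated
against exhaustive enumeration of all `n^n` resamples on groups small
enough to enumerate.

# The synthetic generator

`generate_ensemble()` emulates the statistical structure the analysis
assumes, with ground truth: stable baseline with Gaussian noise
(optionally AR(1); default i.i.d., since the original noise structure is
unspecified), Bernoulli responder status, latency drawn from a
configurable law (default a shifted lognormal: median ≈ 1.2 s, a
right tail of multi-second latencies, nothing below 0.2 s — the
phenomenology of odor responses at moderate concentration), a stereotyped
rise (default exponential, tau = 0.5 s, matching sub-second 33–66% rise
times), per-trial peak jitter, optional adaptation and optional linear
bleaching. Inhibition ensembles carry the mirrored signal: a tonically
elevated level that decays to baseline after onset. Defaults — 40 pulses
per condition, responder fraction 0.8, peak 1.0 dF/F0, noise SD 0.05 —
are fixed once to represent a typical strong-stimulus condition (tens of
pulses per condition, high but imperfect reliability) and are not tuned
per test.

What the generator does *not* emulate: indicator kinetics beyond the
parametric shapes, motion artifacts, correlated noise across traces,
slow baseline drift other than linear bleach, and multi-event responses.
Passing tests therefore demonstrate correctness of the statistics under
the stated generative assumptions, not robustness to every artifact of
real recordings.

# The bistable membrane and the AND-gate

The membrane model is
`C dV/dt = -I_ss(V) - g_cl s_cl (V - E_cl) + g_gap (v_awa - V) + I_inj`.
No equations are published for this cell; the model is calibrated to the
printed electrophysiology. The intrinsic steady-state current is built
from three conductances,

`I_ss(V) = g_leak (V + 80) + g_ca m_inf(V) (V - 60) + g_k n_inf(V) (V + 90)`

with Boltzmann activations (`m_inf` half-activation -45 mV, slope 5;
`n_inf` half-activation -25 mV, slope 5). An N-shaped curve could also be
had from a bare cubic polynomial, but a cubic with stable zeros at -80
and -20 mV and a 2–3 pA knee necessarily has a shallow depolarized
branch: its fixed point would drift by tens of mV over the 3–8 pA step
range, contradicting the observation that further current barely moves
the plateau beyond -20 mV. The three-current form decouples the two
branch stiffnesses: ~0.25 nS at rest (GΩ input resistance, as measured
in these neurons) and ~3.5 nS on the plateau.

Calibration, in order:

1. `g_leak = 0.25` nS with `E_leak = -80` mV puts rest near -80 mV and
   sets the knee (saddle-node) current of the resting branch at ~2.2 pA,
   between the printed 2 pA (no switch) and 3 pA (switch) steps.
2. `g_ca` is solved at construction so that `I_ss(-20) = 0` exactly: the
   depolarized stable state sits at -20 mV by definition of the
   calibration, not by simulation luck.
3. `g_k = 0.8` nS stiffens the depolarized branch.
4. `g_cl = 3.5` nS exceeds the steepest negative slope of `I_ss`
   (~3.0 nS), so the fully open shunt makes the cell monostable near
   rest — the gate's "off" state. `E_cl = -80` mV sits at rest: the
   shunt acts by lowering input resistance, not by hyperpolarizing.
5. `g_gap = 0.1` nS with a presynaptic command of -15 mV (driven) or
   -75 mV (silent) supplies ~3.5–6.5 pA of depolarizing drive when the
   partner is active — suprathreshold with the shunt closed, futile with
   it open.

With this calibration the model is bistable at zero input, so a plateau
*persists* after a suprathreshold step ends (hysteresis). Whether the
real cell's plateau outlasts the stimulus is not stated in the source;
`hysteresis_report()` exposes which regime a given calibration is in
instead of asserting one.

Numerics: fixed points come from a 0.05 mV sign-change scan refined by
bisection to |I| < 1e-6 pA, with stability from the local slope.
Integration is fixed-step RK4 at 0.1 ms (membrane time constants are
0.3–4 ms); a dt-halving check and an independent stiff-solver
cross-check (`deSolve::lsoda`, run segment-wise so it never steps across
a current discontinuity) bound transition-time error in the tests. The
ramp transition is detected as the crossing of the resting
configuration's unstable fixed point; the plateau flag requires the
final voltage within 5 mV of the depolarized stable state after 10 s.
The calcium proxy is a static sigmoid of V (half-activation -45 mV,
slope 8 mV) — sufficient for the all-or-none correspondence between
voltage and indicator plateaus, with no attempt at indicator kinetics.

```{r fixed-points}
m <- membrane_model()
find_fixed_points(m)
```

# Problem sizes and runtime choices

The test suite and the acceptance analyses run at deliberately desk-scale
sizes, chosen once: 1000-trace oracle-equivalence sweeps, 200–400-trace
recovery and false-positive ensembles, 1000-replicate null calibration of
the profile comparison, 50,000 bootstrap draws when checking the SEM
against exhaustive enumeration (keeping Monte-Carlo error well under the
1% comparison band), and single-cell simulations of the full step series
and both ramps at 0.1 ms. The headline percentages of the original study
(responder fractions per genotype) depend on its recorded traces and are
deliberately not reproduced; the property-based checks above stand in
for them.

# Known limitations

* The detector calls at most one onset per pulse and does not separate
  multi-event responses.
* The KS p-value is asymptotic; at very small n (a few trials per group)
  it can differ several-fold from the exact permutation tail, although
  both are then far from any decision boundary. An exact option is
  deliberately omitted to keep the statistic identical to the published
  procedure.
* Absolute conductance and capacitance scales of the membrane model are
  constrained only by the printed pA/mV operating points; the defaults
  are one consistent choice, documented above, not a fit to raw
  recordings.
* The AND-gate simulator models the presynaptic partner as a square
  voltage command; its own action-potential dynamics are not modeled.
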