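---
title: "A neuromodulatory ring-attractor model of the locust heading circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuromodulatory ring-attractor model of the locust heading circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`locustcompass` implements a firing-rate model of a heading (compass)
circuit in the central complex of the desert locust. Unlike the fruit-fly
circuit, where the protocerebral bridge (PB) carries two mirrored compass
bumps and angular velocity enters as feed-forward input, this circuit
assumes a *single* 360° heading representation across the 16 PB columns and
updates it through *multiplicative neuromodulation* of the recurrent
synapses.

The network has 34 units:

* 16 **CL1a** neurons (one per PB column, preferred headings `k * 22.5°`,
  k = 0..15 from L8 to R8) encoding heading as a single cosine bump,
* 16 **CL2** neurons inheriting the heading signal and mediating
  turn-dependent updates,
* 1 **bias** neuron firing constantly at 100 Hz, maintaining the operating
  point,
* 2 **angular-velocity (AV) neurons**, one tuned to clockwise and one to
  counterclockwise rotation, firing proportionally to `|v|` up to 30 Hz at
  150 °/s. They make no conventional synapses; they scale the conductances
  of the columnar synapses through a release probability `P_rel`.

### Neurons and synapses

Neurons are steady-state firing-rate units: because the synaptic time
constant far exceeds the membrane time constant (`tau_s >> tau_m`), the
membrane potential is taken at its conductance-based steady state

\[ U_\infty = \frac{\sum_i \tilde g_{tot,i} P_{s,i} E_{s,i}}
                   {1 + \sum_i \tilde g_{tot,i} P_{s,i}}, \]

and the firing rate follows a logistic function
`r(U) = 99.6 Hz / (1 + exp(-0.19/mV * (U - 17.8 mV)))`. Only the synaptic
state variables carry dynamics. The channel-open probability of each
presynaptic source obeys

\[ \dot P_s = P_{s,max}\, r(t) - (r(t) + \tau_s^{-1})\, P_s , \]

the classical result of convolving a Poisson spike density with a
single-exponential channel kernel; its fixed point is
`r / (r + 1/tau_s)`. The effective conductance of a synapse is
`g_tot = g_s + P_rel_cw * g_mod_cw + P_rel_ccw * g_mod_ccw`: one
unmodulated weight plus one modulatory weight per AV neuron, all free
parameters. A single signed conductance with one reversal potential
(`E_ex = 60 mV` above rest) stands in for separate excitatory and
inhibitory channels; the sign of the weight decides the synapse's action.
Negative total conductance is an abstraction, guarded by an error if the
membrane denominator approaches zero (`eps_denom = 1e-3`).

The release probability of each AV neuron relaxes towards its normalised
rate with time constant `tau_s_mod`:
`dP_rel/dt = (r_mod / r_av_max - P_rel) / tau_s_mod`. This is the simplest
law that is proportional to the modulatory rate at its fixed point and
confines `P_rel` to [0, 1].

### Choice of the synaptic time constants

The membrane constant `tau_m = 1.5 ms` is absorbed by the steady-state
assumption and kept only as a validation constant. The biology constrains
`tau_s` only from below (`tau_s >> tau_m`) and orders
`tau_s_mod > tau_s`. We found the *training protocol* adds a sharp upper
constraint: weights are optimised over a 200 ms window whose shift phase
lasts 160 ms, so any synaptic transient that has not settled within that
window is unconstrained by the objective. With a slow modulatory constant
(e.g. `tau_s_mod = 200 ms`) the release probability reaches barely half of
its asymptote during training; at sustained rotations the circuit then
shifts its bump almost twice as fast as trained, and the 4-s integration
error grows several-fold regardless of how long one optimises. We therefore
set `tau_s = 25 ms` (still ~17x the membrane constant) and
`tau_s_mod = 50 ms`, which completes ~96% of the release transient inside
the shift phase while respecting both stated orderings. Both constants are
configurable.

### Connectivity

Synapses are restricted to a boolean mask derived from projection anatomy
(`build_columnar_mask()`):

1. CL1a → CL2 within the same PB column;
2. CL2 → CL1a where the CL2 output column in the lower central body (CBL)
   overlaps the CL1a input arbor;
3. CL1a → CL1a for overlapping CBL arbors, including self-connections;
4. CL2 ↔ CL2 all-to-all within a lower-nodulus group (one per PB
   hemisphere);
5. bias → every columnar neuron.

The CBL mapping requires a convention, since the published projection
schemes do not fix every cell of the matrix: columnar neurons of each
hemisphere innervate alternating CBL columns across the full CBL width
(left CL1a on even columns `2k`, right CL1a on odd columns `2(k-8)+1`), and
the CL2 scheme is shifted by one column, mirror-symmetrically in the two
hemispheres. The CBL is treated as a *linear* (crescent-shaped) array — no
wrap-around — and "overlap" means the source output column lies within two
columns of the target CL1a central column (central endings mixed, flanking
endings up to two columns on each side). Each CL2 then reaches one
same-column contralateral CL1a plus ipsi- and contralateral flanking
neighbours; boundary columns simply have fewer partners. The resulting mask
is mirror-symmetric and its recurrent blocks are symmetric. AV neurons may
modulate every synapse among columnar neurons (not the bias input);
restricting modulation to synapses onto CL1a or onto CL2 only
(`modulated =` argument) reproduces the re-optimised model variants.

## Training

Free parameters are the masked weights: 324 feed-forward plus 2 × 292
modulatory. The objective simulates the circuit for 200 ms at 4 ms RK4
steps (trajectory rows 0..49) from random initial headings:

* 64 *maintenance* trials hold `v = 0` and penalise the squared deviation
  of CL1a and CL2 rates from their initial bump at every 10th row
  (rows 0, 10, 20, 30, 40);
* 64 *shift* trials apply a random constant `v` drawn from [-150, 150] °/s
  for the first 4/5 of the horizon (40 steps), then `v = 0`, and penalise
  deviations from the bump of the true final heading over the last 10 rows.

Each of the four mean-squared-error terms (two populations × two trial
types) is a mean over its trials, rows, and 16 neurons, in Hz². A
regulariser with relative weight 0.1 adds the summed population variance of
the weights along each wrapped diagonal of the four 16×16 quadrants of the
connectivity matrix (and across each bias column), applied identically to
the unmodulated and both modulatory matrices: anatomically repeated
structures are pushed towards equal weights. Truncated diagonals (from the
crescent CBL) form shorter groups.

Optimisation is L-BFGS (`stats::optim`, history 50, gradient tolerance
1e-7) with an *analytic* gradient: a hand-derived reverse-mode adjoint
sweep through the RK4 stages and the algebraic rate readout. The release
probabilities do not depend on the weights, so only the 33 open
probabilities per trial are differentiated through. The adjoint is verified
against central finite differences to 1e-4 in the test suite. Weights are
initialised uniformly in ±0.01 (seeded); batch generation, initialisation
and evaluation derive independent sub-seeds from one master seed.

Probabilities are clamped to [0, 1] after each integration step in the
simulator; the exact flow cannot leave that region (at `P = 0` the
derivative is `r >= 0`, at `P = 1` it is `-1/tau_s < 0`), so for healthy
states the clamp only removes rounding excursions. The training forward
pass omits the clamp, keeping the objective smooth; if a line-search step
ever drives the membrane denominator towards zero, the objective returns a
large penalty value and the search backtracks.

## Evaluation protocols

**Integration accuracy** (`run_integration_suite`): trials of 4 s at 1 ms
steps from random headings, driven by the angular-velocity fixture
generator below. The decoded heading is the phase of the least-squares
cosine fit to the final CL1a rates (closed form, since the preferred
directions are equally spaced); the error metric is the wrapped absolute
angular difference, bounded by 180°. Optional perturbations follow the
study conditions: Gaussian membrane noise (SD 0, 0.1, 0.5 or 1 mV) added to
`U` before the rate nonlinearity at every millisecond; Beta resampling of
every `P_s` each millisecond with the noise-free value as mean and a
pseudocount (10, 100, 1000) setting the coefficient of variation; and
uniform multiplicative weight noise (range 0.01, 0.03, 0.05) applied once
per trial to all weights. Per-millisecond noise requires `dt = 1 ms`.

**Attractor stability** (`run_attractor_suite`): the initial rate vector of
all 32 columnar neurons is perturbed with Gaussian noise whose SD is a
fraction (0..1) of the bump amplitude *before* the synaptic fixed points
are seeded; after 100 ms the relative mean-squared deviation of the CL1a
activity from its best-fitting cosine is reported (normalised by the
activity variance, so 0 is a perfect cosine).

**Closed-loop agent** (`run_agent_trials`): the CL1a rates are squashed by
a logistic sigmoid into a rounded square wave and projected onto 8 TB1
units through a non-negative, anatomically masked map fitted by ridge
regression (`optimize_cl1a_tb1_map`); each TB1 subtype has two permissible
input domains half a turn apart, and the decay term prunes the anti-phase
domain. A CPU1-style comparator between the TB1 bump and a hard-coded CPU4
goal encoding (the difference of the summed products with the goal shifted
one column either way) yields a turn command that is an odd, corrective
function of the heading error. Agents take 200 steps of 0.1 s (one
step-length forward per step — they can neither rotate on the spot nor
sidestep) while the heading circuit integrates the realised angular
velocity, wind rotation included, in 1 ms increments. Wind gusts
(500-1500 ms) either translate the agent one step-length sideways per step
or rotate it by a total uniform ±90° spread over the gust; the two are
mutually exclusive.

The interface's `phase_shift` parameter offsets the TB1 bump relative to
CL1a to compensate implementation-specific biases between the
continuous-time heading representation and the discretised steering stage;
it shifts the closed-loop equilibrium to `goal - phase_shift`. Its default
is calibrated so that closed-loop deviations are symmetric about zero for
this implementation (see `README`); it is exposed for adjustment alongside
the squash slope/midpoint, the square-wave slope, the steering gain and the
goal-vector length, none of which are biologically constrained. (A fixed
offset of -5° reproduces the bias compensation a discrete-time steering
stage requires, and the fitted map realises it faithfully; with the
continuous stage used here the measured closed-loop bias is zero, so the
default offset is zero.)

## The angular-velocity fixture generator

`generate_av_trajectory()` emulates the rotational trajectory of a walking
locust as first-order low-pass-filtered Gaussian noise: a stationary AR(1)
process with autocorrelation time 500 ms and stationary SD 50 °/s, sampled
at the integration step and clipped to ±150 °/s (clipping affects ~0.3% of
samples). This captures the zero-mean, temporally correlated, bounded
character of walking rotations; it does *not* emulate saccadic
turn-and-fixate structure, pauses, velocity-dependent gait changes, or any
coupling between translation and rotation. Tests passing under this
generator therefore show robustness to smooth meandering input, not to
every statistical feature of real locust walking.

## Problem sizes

The package's own test suite and the acceptance script run at desk scale,
chosen as the sizes at which the quantities stabilise: training uses the
standard 128-trial batch with an L-BFGS iteration cap of 900-1200 depending
on context (the integration accuracy is stable from ~800 iterations, the
zero-velocity drift keeps improving slightly up to ~1200); evaluation
suites use 80-200 trials instead of the study-scale 1000-2000, with
standard errors reported alongside means.

## Known limitations

* The mask convention near the PB midline and at the CBL ends is one of
  several defensible readings of the projection schemes; the builder
  exposes the mask for override.
* Rates are algebraic, so the model cannot express membrane-driven delays;
  all lags come from the two synaptic time constants.
* The regulariser treats truncated diagonals as independent groups, so
  boundary synapses are less strongly tied than interior ones.
* The steering circuit is a deliberately small adaptation of a published
  path-integration model: no homing-vector accumulation, no multimodal cue
  fusion, no flight dynamics.
* Trained weight sets are families, not unique optima: different seeds give
  different matrices with similar behaviour.
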