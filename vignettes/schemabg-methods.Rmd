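---
title: "Schema selection through basal-ganglia loops: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema selection through basal-ganglia loops: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemabg)
```

# The model

`schemabg` simulates hierarchical schema selection on the unambiguous
("Madrid") variant of the Wisconsin Card Sorting Test. Two banks of cortical
schema nodes compete for control of behaviour: three *cognitive* schemas,
one per sorting rule (colour, shape, number), and four *sensorimotor*
schemas, one per card placement act (put the card under target 1--4).
Competition is not resolved by lateral inhibition within the cortex but by
per-schema basal-ganglia channels — striatum (D1 and D2 populations),
subthalamic nucleus (STN), external and internal globus pallidus (GPe,
GPi) — wired into segregated cortico-striato-thalamo-cortical loops. Tonic
GPi activity keeps the thalamic feedback inhibitory; a channel whose
striatal D1 drive silences its GPi unit is *disinhibited* and its cortical
schema can win selection.

Every unit updates once per cycle with the same three steps: collect input
`u`, low-pass filter it (`a <- delta * a + (1 - delta) * u`, `delta = 0.6`),
and squash it with a logistic saturation `1 / (1 + exp(-alpha * (a -
beta)))`. Thalamic output is the negated logistic, in (-1, 0). The STN
projects diffusely (each GPe/GPi unit receives the *sum* of STN outputs), so
the total inhibition of the layer scales with the total cortical drive —
this is the classic selection/control-pathway arrangement, and the package
verifies its selection property directly (steady-state GPi is lowest on the
channel with the largest cortical input; see `tests/testthat`).

A schema is selected when its output exceeds the static threshold
`theta_s = 0.5` *and* its accumulated output since the relevant reference
point reaches an integration threshold drawn per trial from N(4000, 400^2)
area units. The accumulator criterion is what gives the model its
evidence-accumulation response times, measured in cycles from card onset to
sensorimotor selection.

Two adaptive quantities carry all of the learning:

* **Striatal thresholds** `beta_str[i]` of the three cognitive channels.
  After each feedback event with sign `r`, every cognitive channel receives
  a feature-match value `f[i]` (+1 if the channel's rule maps the card onto
  the chosen target; otherwise `(2 * w_neg - 1) - m_r * f_prev * r_prev`),
  a prediction error `delta[i] = r * f[i] - a_med[i]` (where `a_med[i]` is
  the median of the channel's smoothed cortical activation over the trial),
  and the update `beta_str[i] <- clip((beta_str[i] - eps_str * delta[i]) *
  (1 + zeta), 0, 1)`. Rewarded rules are disinhibited, punished rules
  suppressed, and unused rules parked at high threshold.
* **Sensorimotor gain** `alpha_sma`, set at each feedback event to
  `(1 + zeta) * prod(1 + eps_sma + o_sma[i])`. The product is a
  response-conflict monitor: it grows with the number and activation of
  co-active placement schemas and peaks when all of them peak.

## Parameters that matter

All defaults are returned by `wcst_params()`. The behaviourally important
ones:

| parameter | default | role |
|---|---|---|
| `eps_str` | 0.40 | striatal learning rate; the dopamine-linked quantity reduced in the virtual patient groups |
| `eps_sma` | 0.50 | conflict-driven cortical gain adaptation rate |
| `w_neg`   | 0.00 | blunting of the negative feature-match value (0.3 instead of -1 at 0.65) |
| `m_r`     | 0.00 | carry-over of the previous trial's signed feedback into the feature match |
| `o_ext`, `o_stim` | 0.75, 0.50 | tonic drive to rule schemas; stimulus drive to matching placement schemas |
| `w_rule`  | 0.40 | top-down weight from the selected rule to the placement act it implies for the current card |
| `theta_a_mean`, `theta_a_sd` | 4000, 400 | integration threshold draw (area units) |
| `area_scale` | 32.78 | converts per-cycle output sums into area units (calibrated once, see below) |

Virtual groups are regions of (`eps_str`, `eps_sma`, `w_neg`, `m_r`) space:
healthy controls at/around the defaults, Parkinson's disease with reduced
learning rates and elevated `w_neg`, `m_r` (`parameter_space()`,
`pd_groups()`).

# Numerical and design choices

The dynamics above pin most of the implementation down, but a handful of
choices were genuinely open. They are recorded here because they shape the
simulated statistics.

**Timescale calibration (`area_scale`).** The integration threshold is
specified in area units with mean 4000, while response times are on the
order of 100 cycles and a placement schema emits at most one output unit
per cycle. The two scales are bridged by a single constant, `area_scale`,
calibrated once by bisection (`calibrate_area_scale()`) so that the mean
post-positive-feedback response time at default parameters is 129.1 cycles.
The calibration uses only the post-positive RT; the post-negative RT and
all group RTs are out-of-sample consequences.

**Prediction-error form.** The update is implemented as
`delta = r * f - a_med` ("signed match minus expectation"). The
alternative reading `delta = r * (f - a_med)` is available as
`wcst_params(rpe_form = "parenthesized")`, but it makes the punishment of a
strongly active incumbent rule vanishingly small (`eps_str * (1 - a_med)`
per trial), which produces four to six perseverative errors per rule switch
at default parameters and an order of magnitude more at low `eps_str` —
incompatible with the behavioural profiles the model is meant to produce.
Under the default form a punished incumbent's threshold rises by about
`eps_str * (1 + a_med)` per error, giving roughly one unavoidable error
plus one perseverative error per switch at defaults, and about three
perseverative errors per switch at `eps_str = 0.1`.

**Median activation.** `a_med` is the median of the *smoothed activation*
`a` (the quantity the integrators track), not of the squashed output `o`.
For a maintained rule `a` saturates near `o_ext + o_thal ~ 0.71` rather
than near 1, which keeps the maintenance drift of the rewarded rule's
threshold small and makes the punishment step nearly independent of how
saturated the output was.

**Stimulus noise.** The uniform noise on `o_stim` is redrawn every cycle
(`stim_noise = "per_cycle"`). A single per-trial draw would bias the entire
~125-cycle evidence race on every trial and produces about 2.3 set-loss
errors per session at default parameters; redrawn noise averages out over
the integration and leaves rule-guided responding intact.

**Selection policy.** A selected rule schema persists while its output
stays above `theta_s`; a non-selected schema that satisfies both selection
criteria *and* exceeds the incumbent's output displaces it
(`sel_displacement = TRUE`). Cognitive evidence accumulators carry across
trials and restart when their schema loses selection
(`cog_area_policy = "reset_deselect"`); sensorimotor accumulators restart
at every card onset, because they time the overt response. Displacement is
what lets a drifting competitor intrude during a maintained run — the
mechanism behind set-loss errors in the blunted-negative-reward groups.

**Action execution and the inter-trial interval.** Executing a placement
act is followed by `iti_cycles = 20` cycles with the card withdrawn. The
executed schema then decays through the leaky integrators and its channel's
disinhibition fades. Without this interval the winner's cortico-thalamic
loop stays latched (its GPi near zero, every other channel suppressed by
the diffuse STN drive) and the same response repeats on any card sharing a
feature with the previous target — which is three quarters of the deck.
Cognitive dynamics continue through the interval, so rule switching can
begin as soon as feedback arrives.

**Degenerate inputs and edge cases.** A trial that reaches the 1000-cycle
cap is an omission: it is logged, scored `other_error`-adjacent (its own
class), excluded from RT averages, and triggers no learning. Sessions
without a single incorrect trial have an undefined ERN component; sessions
in which the model never switches schema have an undefined PSP (both return
flagged `NA`, as at extreme `w_neg` where the model stops switching).
Ties in selection go to the highest output, then the lowest index.

# ERP proxies

The error-related negativity (ERN) proxy is the negated extreme one-step
change across sensorimotor outputs, `-absmax(o_sma(t) - o_sma(t-1))`; the
sustained parietal positivity (SPP) proxy is the same functional applied to
the cognitive outputs. Response-locked ERN windows span 20 cycles before to
40 after each response. Two stereotyped, outcome-independent transients are
masked when outcome-dependent peaks are measured: the decay of the executed
schema (8 cycles after the response) and the onset rise of the next card
(8 cycles after the interval). What remains is the feedback-driven
reorganisation — after an error, the withdrawal and redirection of top-down
drive early in the next trial — which is larger on incorrect than correct
trials, dips below baseline just before the response, and peaks after it.
The per-session ERN attenuation is the correct-trial peak-to-baseline
magnitude minus the incorrect-trial one (negative when the error signal is
robust, approaching zero as it attenuates); the PSP attenuation is the mean
SPP peak on shift trials minus the mean on the trials that follow them,
with each trial's peak taken from the previous response to its own response
so that the schema transition lies inside the shift trial's window.

The proxies inherit the model's discreteness: they are piecewise-smooth
with isolated jumps, not millisecond-scale waveforms, and their magnitudes
are in output units per cycle. Only their relational properties (outcome
asymmetry, position relative to the response, parameter dependence) are
meaningful, and only those are asserted in the tests.

# What the simulations do and do not show

The task generator *is* the study design: 64-card sessions drawn as
shuffled copies of the 24-card unambiguous deck, criterion-10 rule
schedule with uniformly drawn replacement rules (a random-run schedule
with run lengths uniform on {2,3,4,5}, median 3.5, is available for
administrations that shift the rule after short unpredictable runs), and binary feedback scored with the
PE/SL/IE taxonomy. Reproducing the reference group statistics under these
conditions shows that the mechanisms — reward-driven striatal threshold
adaptation, conflict-driven gain adaptation, loop-based selection — carry
the intended behavioural signatures. It does not show that real
participants are parameterised this way: the virtual groups are single
points or uniform boxes in a four-dimensional slice of parameter space,
all other parameters are shared exactly, and the deck and schedule are
idealised.

Problem sizes used throughout the package's own studies: 100 sessions for
the baseline and patient-group tables; 20 virtual participants per group
for the midpoint ERP comparison; a 4^4-point grid with 10 sessions per
point (2560 sessions per space) for the attenuation--error correlations;
20 sessions per sweep point; 20 sessions per `eps_sma` value for the
lagged GPi--cortex control analysis. The test suite runs reduced versions
of the same computations.

# Known limitations

* **Set-loss floor.** At default parameters the model produces essentially
  zero set-loss errors: competitor thresholds peg at their ceiling during a
  maintained run and the per-cycle stimulus noise cannot overcome the
  guided race margin. Published set-loss rates at comparable settings are
  small but non-zero (~0.3 per session), and that floor appears to be
  parameter-independent — plausibly a by-product of the discrete
  cortico-thalamic oscillation episodes described for some parameter
  regions, which the present fixed-point dynamics do not produce. The same
  structural fact biases the blunted-negative-reward group's set-loss rate
  slightly high, since all of its set losses come from threshold-drift
  intrusions.
* **Integration errors.** With the default prediction-error form the model
  almost never returns to a rule punished two trials earlier, so
  integration errors stay near zero even in the slow-learning groups.
* **Oscillations.** For some parameter combinations the discrete loop can
  oscillate; the default parameter set is well inside the stable regime,
  and no attempt is made to reproduce oscillation-driven phenomena.
* The ERN/SPP proxies are bridging signals, not forward-modelled
  potentials; scalp topography, latency in milliseconds and waveform shape
  are out of scope.

# Reproducing the numbers

```{r, eval = FALSE}
s1 <- study1(seed = 1)        # baseline table
s2 <- study2(seed = 2)        # virtual patient groups
s3 <- study3(seed = 3)        # midpoint ERN/PSP comparison
s4 <- study4(seed = 4)        # parameter-space grids + rank correlations
s5 <- study5(seed = 5)        # sweeps of eps_str, eps_sma, w_neg
lag <- gpi_sma_lagged_correlation(seed = 9)
```

`scripts/acceptance.R` at the repository root chains the headline
quantities end-to-end from a single seed.
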