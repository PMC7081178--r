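# schemabg

Rate-coded simulation of hierarchical schema selection through basal-ganglia
loops, grounded in the unambiguous ("Madrid") variant of the Wisconsin Card
Sorting Test (WCST).

## The problem and the model

How does the brain pick one routine — one *schema* — out of several that the
current situation affords, and how does that selection break down in
Parkinson's disease? `schemabg` implements a computational answer: cortical
schema nodes for the three sorting rules (colour, shape, number) and the four
card-placement acts do not inhibit each other directly; each feeds a
dedicated basal-ganglia channel (striatum D1/D2, STN, GPe, GPi) inside a
cortico-striato-thalamo-cortical loop, and behaviour is controlled by
whichever schema the basal ganglia disinhibit.

Every unit follows the same update per processing cycle: input *u*, leaky
integration *a ← δ·a + (1 − δ)·u*, logistic saturation
*o = σ(a; β, α) = 1 / (1 + e^{−α(a−β)})* (negated for the thalamus, whose
tonic activity suppresses cortex). A schema is selected when its output
passes a static threshold θ_s and its integrated output passes a per-trial
evidence threshold θ_A ~ N(4000, 400²) area units; response time is the
cycle count from card onset to placement selection.

Learning happens at two sites, once per feedback event *r* ∈ {+1, −1}:

* striatal thresholds of the rule channels,
  *β_str,i ← clip((β_str,i − ε_str·(r·f_i − ã_i))(1 + ζ), 0, 1)*, where
  *f_i* is the channel's feature-match value (+1 when its rule is consistent
  with the response, otherwise *(2w_neg − 1) − m_r·f_prev·r_prev*) and *ã_i*
  the median activation over the last trial — rewarded rules are
  disinhibited, punished ones suppressed;
* the sensorimotor gain, *α_sma ← (1 + ζ)·Π_i(1 + ε_sma + o_i)*, a
  response-conflict monitor.

Reducing ε_str (striatal dopamine sensitivity) reproduces the Parkinsonian
profile — slower sorting, more perseverative errors — while raising w_neg
(blunted negative-reward sensitivity) produces set-loss errors. Model-internal
proxies of two ERP components are computed from cycle-level activations: the
error-related negativity (ERN), *−absmax(Δo_sensorimotor)* response-locked,
and the posterior switch positivity (SPP/PSP), *absmax(Δo_cognitive)*
contrasting shift against post-shift trials.

## A worked example

```r
library(schemabg)
r <- run_session(seed = 42)   # 64 unambiguous cards, criterion-10 schedule
r
#> <wcst_run>  64 trials
#>    cards_correct       categories               PE               SL
#>           51.000            5.000            5.000            0.000
#>               IE      other_error        omissions rt_post_positive
#>            0.000            8.000            0.000          130.820
#> rt_post_negative
#>          140.615
```

This virtual participant sorted 51 of 64 cards correctly, completed 5
categories (runs of 10 consecutive correct sorts), committed 5 perseverative
errors (sticking to the punished rule), no set-loss or integration errors,
and 8 residual errors — mostly the unavoidable first error after each
unannounced rule change. Sorting took ~131 cycles after positive feedback
and ~141 after negative feedback, the rule-switch cost. The full per-trial
log is in `r$log`:

```r
head(r$log[, c("trial", "card_colour", "card_shape", "card_number",
               "response", "applied_rule", "feedback", "rt_cycles")], 3)
#>  trial card_colour card_shape card_number response applied_rule feedback rt_cycles
#>      1         red     circle           3        1       colour        1       306
#>      2       green     circle           1        2       colour        1       145
#>      3      yellow       star           1        3       colour        1       135
```

Higher-level drivers reproduce whole simulation studies: `study1()`
(baseline statistics over 100 sessions), `study2()` (four virtual
Parkinson's groups), `study3()` (midpoint ERN/PSP comparison between
healthy-control and patient parameter spaces), `study4()` (4⁴-point
parameter grids with Spearman correlations between ERP attenuation and
error counts), `study5()` (parameter sweeps), and
`gpi_sma_lagged_correlation()` (lagged coupling between GPi and
sensorimotor cortex). A command-line driver over the same functions is in
`inst/scripts/schemabg`. The methods vignette
(`vignettes/schemabg-methods.Rmd`) documents the model, the numerical
choices and their rationale.

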