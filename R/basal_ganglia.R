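# Per-schema basal-ganglia channels (striatum D1/D2, STN, GPe, GPi, thalamus)
# wired into segregated cortico-thalamic loops. Each step_* function performs
# one synchronous update of one nucleus layer: u -> leaky integration -> logistic.

#' Default basal-ganglia pathway weights
#'
#' Excitatory weights are positive, inhibitory weights negative, following
#' the pathway anatomy: cortex excites STN (hyperdirect), striatal D1
#' inhibits GPi (direct/selection pathway), striatal D2 inhibits GPe and STN
#' excites GPe/GPi diffusely while GPe inhibits STN and GPi
#' (indirect/control pathway).
#'
#' @return Named list of weights.
#' @export
bg_weights <- function() {
  list(
    w_ctx_stn   =  1.2,
    w_gpe_stn   = -1.0,
    w_stn_gpe   =  0.9,
    w_strd2_gpe = -1.0,
    w_stn_gpi   =  0.9,
    w_gpe_gpi   = -0.3,
    w_strd1_gpi = -1.0
  )
}

.step_nucleus <- function(state, u, beta, alpha, delta) {
  state$a <- delta * state$a + (1 - delta) * u
  state$o <- logistic(state$a, beta, alpha)
  state
}

#' One update of a striatal layer (D1 or D2)
#'
#' Striatal input is a copy of the corresponding cortical output. The
#' threshold `beta_str` is the dopamine-linked quantity that reward learning
#' adapts (per cognitive channel); it may be a vector, one threshold per
#' channel.
#'
#' @param state List with `a`, `o`.
#' @param o_ctx Cortical outputs (cognitive or sensorimotor layer).
#' @param beta_str Striatal threshold(s).
#' @param params A [wcst_params()] list.
#' @return Updated `state`.
#' @export
step_striatum <- function(state, o_ctx, beta_str, params) {
  .step_nucleus(state, o_ctx, beta_str, params$alpha_str, params$delta)
}

#' One update of the subthalamic nucleus layer
#'
#' Excitatory hyperdirect input from the cortex, inhibitory input from GPe
#' (previous cycle).
#'
#' @param state List with `a`, `o`.
#' @param o_ctx Cortical outputs.
#' @param o_gpe_prev GPe outputs from the previous cycle.
#' @param weights A [bg_weights()] list.
#' @param params A [wcst_params()] list.
#' @return Updated `state`.
#' @export
step_stn <- function(state, o_ctx, o_gpe_prev, weights, params) {
  u <- weights$w_ctx_stn * o_ctx + weights$w_gpe_stn * o_gpe_prev
  .step_nucleus(state, u, params$beta_stn, params$alpha_stn, params$delta)
}

#' One update of the external globus pallidus layer
#'
#' The STN projection is diffuse: every GPe channel receives the *sum* of all
#' STN outputs, so the only channel-specific term is the D2 inhibition
#' (previous cycle).
#'
#' @inheritParams step_stn
#' @param o_stn Current-cycle STN outputs.
#' @param o_strd2_prev Striatal D2 outputs from the previous cycle.
#' @return Updated `state`.
#' @export
step_gpe <- function(state, o_stn, o_strd2_prev, weights, params) {
  u <- weights$w_stn_gpe * sum(o_stn) + weights$w_strd2_gpe * o_strd2_prev
  .step_nucleus(state, u, params$beta_gpe, params$alpha_gpe, params$delta)
}

#' One update of the internal globus pallidus layer
#'
#' Diffuse STN excitation scales the whole layer with global input, while
#' channel-wise GPe and striatal D1 inhibition carve out the channel to be
#' disinhibited downstream.
#'
#' @inheritParams step_gpe
#' @param o_gpe Current-cycle GPe outputs.
#' @param o_strd1 Current-cycle striatal D1 outputs.
#' @return Updated `state`.
#' @export
step_gpi <- function(state, o_stn, o_gpe, o_strd1, weights, params) {
  u <- weights$w_stn_gpi * sum(o_stn) + weights$w_gpe_gpi * o_gpe +
    weights$w_strd1_gpi * o_strd1
  .step_nucleus(state, u, params$beta_gpi, params$alpha_gpi, params$delta)
}

#' One update of the thalamic layer
#'
#' The thalamus is tonically active and inhibited by GPi; its output is the
#' negated logistic, in (-1, 0), fed back to the cortex. Less GPi output
#' means less cortical suppression (disinhibition).
#'
#' @param state List with `a`, `o`.
#' @param o_gpi Current-cycle GPi outputs.
#' @param params A [wcst_params()] list.
#' @return Updated `state` with `o` in (-1, 0).
#' @export
step_thalamus <- function(state, o_gpi, params) {
  state$a <- params$delta * state$a + (1 - params$delta) * o_gpi
  state$o <- -logistic(state$a, params$beta_thal, params$alpha_thal)
  state
}

#' Feature-match value of a cognitive channel after a response
#'
#' A channel whose rule is consistent with the response (the rule maps the
#' card onto the chosen target) gets +1. Otherwise the value is
#' `(2 * w_neg - 1) - m_r * f_prev * r_prev`: with both parameters at 0 this
#' is -1; larger `w_neg` blunts negative reward, larger `m_r` carries the
#' previous trial's feedback forward.
#'
#' @param card The stimulus card.
#' @param response Target index chosen.
#' @param channel_rule The channel's sorting rule.
#' @param params A [wcst_params()] list (`w_neg`, `m_r`).
#' @param f_prev Channel's feature-match value on the previous feedback
#'   event (0 at session start).
#' @param r_prev Previous feedback sign (0 at session start).
#' @return The feature-match value f.
#' @export
feature_match <- function(card, response, channel_rule, params,
                          f_prev = 0, r_prev = 0) {
  if (rule_target(card, channel_rule) == response) 1
  else (2 * params$w_neg - 1) - params$m_r * f_prev * r_prev
}

#' Reward prediction error of a cognitive channel
#'
#' Difference between the feedback-signed feature-match value and the
#' channel's median cortical activation over the trial just finished:
#' `rf - a_median` (the default, `"signed_match"`, with the match value f
#' signed by the feedback r). A punished applied
#' rule (r = -1, f = +1, high activation) then receives a large negative
#' prediction error, raising its striatal threshold quickly, while a
#' rewarded applied rule with high activation receives a small positive one
#' (fully predicted reward). The alternative `"parenthesized"` form
#' `r(f - a_median)` signs the whole difference by the feedback instead;
#' it weakens the punishment of strongly active incumbents and produces far
#' slower rule switching.
#'
#' @param r Feedback sign (+1 / -1).
#' @param f Feature-match value.
#' @param a_median Median cortical output of the channel over the last trial.
#' @param form `"signed_match"` or `"parenthesized"`.
#' @return The prediction error delta.
#' @export
reward_prediction_error <- function(r, f, a_median,
                                    form = c("signed_match", "parenthesized")) {
  form <- match.arg(form)
  if (form == "signed_match") r * f - a_median else r * (f - a_median)
}

#' Reward-driven update of a striatal threshold
#'
#' `beta <- clip((beta - eps_str * rpe) * (1 + zeta), 0, 1)`. Positive
#' prediction errors lower the threshold (more striatal drive, channel
#' disinhibited); negative ones raise it. Applied to cognitive channels only,
#' once per feedback event.
#'
#' @param beta Current threshold in \[0, 1\].
#' @param eps_str Striatal learning rate.
#' @param rpe Reward prediction error.
#' @param zeta_draw Multiplicative noise draw (0 for deterministic value).
#' @return Updated threshold, clipped to \[0, 1\].
#' @export
update_beta_str <- function(beta, eps_str, rpe, zeta_draw = 0) {
  min(1, max(0, (beta - eps_str * rpe) * (1 + zeta_draw)))
}
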