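#' Logistic saturation function
#'
#' All units in the model squash their smoothed input through
#' `1 / (1 + exp(-alpha * (x - beta)))`: `beta` is the activation threshold
#' (the input at which output is 0.5) and `alpha` the gain (slope).
#'
#' @param x Input (smoothed activation).
#' @param beta Threshold.
#' @param alpha Gain.
#' @return Output in (0, 1).
#' @export
logistic <- function(x, beta, alpha) {
  1 / (1 + exp(-alpha * (x - beta)))
}

#' One update of the cognitive (rule) schema layer
#'
#' Each of the three rule nodes receives a constant top-down excitation
#' `o_ext` plus the (negative) output of its thalamic unit from the previous
#' cycle. The input is low-pass filtered with smoothing constant `delta` and
#' squashed with the layer's threshold/gain.
#'
#' @param state List with numeric vectors `a` (smoothed activation) and `o`
#'   (output), one entry per rule node.
#' @param o_thal Thalamic outputs from the previous cycle, each in (-1, 0).
#' @param params A [wcst_params()] list.
#' @return Updated `state` (synchronous update across nodes).
#' @export
step_cognitive <- function(state, o_thal, params) {
  u <- params$o_ext + o_thal
  state$a <- params$delta * state$a + (1 - params$delta) * u
  state$o <- logistic(state$a, params$beta_pfc, params$alpha_pfc)
  state
}

#' One update of the sensorimotor (card placement) schema layer
#'
#' Each of the four placement nodes receives top-down excitation `w_rule`
#' from every *selected* cognitive schema that routes the current card onto
#' its target, plus the (noisy) stimulus drive for matching targets, plus its
#' thalamic feedback from the previous cycle. The gain of this layer
#' (`alpha_sma`) is the dynamic, conflict-adapted gain.
#'
#' @param state List with vectors `a`, `o` (length 4).
#' @param o_ctx Cognitive-layer outputs (length 3).
#' @param selected_mask Logical length 3; which cognitive schemas are
#'   selected (only selected schemas pass excitation down).
#' @param stim Stimulus drive per target node (`(o_stim + noise) * match`).
#' @param o_thal Sensorimotor thalamic outputs from the previous cycle.
#' @param params A [wcst_params()] list.
#' @param routing 4 x 3 0/1 matrix; `routing[i, j] = 1` iff sorting rule j
#'   maps the current card onto target i (see [rule_routing()]). Card
#'   placement is rule-conditional, so the top-down pathway is gated by the
#'   current card.
#' @param alpha_sma Current (adapted) gain; defaults to `params$alpha_sma`.
#' @return Updated `state`.
#' @export
step_sensorimotor <- function(state, o_ctx, selected_mask, stim, o_thal,
                              params, routing, alpha_sma = params$alpha_sma) {
  if (length(o_ctx) != ncol(routing) || length(state$a) != nrow(routing))
    stop("dimension mismatch between layers and routing matrix")
  topdown <- as.numeric(routing %*% (params$w_rule * o_ctx * selected_mask))
  u <- topdown + stim + o_thal
  state$a <- params$delta * state$a + (1 - params$delta) * u
  state$o <- logistic(state$a, params$beta_sma, alpha_sma)
  state
}

#' Card-conditional routing matrix from rules to targets
#'
#' @param card A card.
#' @return A 4 x 3 0/1 matrix with `[i, j] = 1` iff rule j (colour, shape,
#'   number) maps `card` onto target i.
#' @export
rule_routing <- function(card) {
  m <- matrix(0, 4, 3, dimnames = list(NULL, .rules))
  m[card$t_colour, 1] <- 1
  m[card$t_shape, 2] <- 1
  m[card$t_number, 3] <- 1
  m
}

#' Threshold pair used for schema selection
#'
#' A schema is selected when its output exceeds the static threshold
#' `theta_s` *and* the area under its output since stimulus onset, scaled by
#' `area_scale`, reaches the per-trial integration threshold drawn from
#' `N(theta_a_mean, theta_a_sd^2)` (truncated positive). The integration
#' criterion is what gives the model its evidence-accumulation response
#' times.
#'
#' @param theta_s Static activation threshold in (0, 1).
#' @param theta_a_mean,theta_a_sd Mean and s.d. of the integration threshold
#'   draw (area units).
#' @param area_scale Calibration constant converting accumulated output
#'   (summed per cycle) to area units.
#' @return A list of selection thresholds.
#' @export
selection_thresholds <- function(theta_s = 0.5, theta_a_mean = 4000,
                                 theta_a_sd = 400, area_scale = NULL) {
  if (is.null(area_scale)) area_scale <- wcst_params()$area_scale
  stopifnot(theta_s > 0, theta_s < 1, area_scale > 0)
  list(theta_s = theta_s, theta_a_mean = theta_a_mean,
       theta_a_sd = theta_a_sd, area_scale = area_scale)
}

#' Check whether any node of a layer can be selected
#'
#' @param state Layer state with `o` and `area` (accumulated output since
#'   stimulus onset).
#' @param thresholds A [selection_thresholds()] list.
#' @param theta_a_draw This trial's integration threshold draw.
#' @return Index of the selected node, or `NA_integer_` if none qualifies.
#'   When several nodes qualify on the same cycle the one with the highest
#'   output wins (ties: lowest index).
#' @export
check_selection <- function(state, thresholds, theta_a_draw) {
  ok <- state$o > thresholds$theta_s &
    thresholds$area_scale * state$area >= theta_a_draw
  if (!any(ok)) return(NA_integer_)
  cand <- which(ok)
  cand[which.max(state$o[cand])]
}

#' Conflict-driven update of the sensorimotor gain
#'
#' The gain of the sensorimotor saturation function is set, once per feedback
#' event, to `(1 + zeta) * prod(1 + eps_sma + o_i)` over all sensorimotor
#' outputs. The product form behaves like a response-conflict monitor: it
#' grows with the number and activation of simultaneously active placement
#' schemas and peaks when all of them peak.
#'
#' @param o_sma Sensorimotor outputs at feedback time.
#' @param eps_sma Cortical learning-rate parameter.
#' @param zeta_sma Multiplicative noise draw (0 for the deterministic value).
#' @return The new gain.
#' @export
update_alpha_sma <- function(o_sma, eps_sma, zeta_sma = 0) {
  (1 + zeta_sma) * prod(1 + eps_sma + o_sma)
}
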