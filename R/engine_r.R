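# Pure-R reference engine. Runs the identical dynamics to the compiled
# engine, built from the exported step_* functions, and consumes RNG draws in
# the identical order, so that with the same seed the two engines agree to
# machine precision. Used for validation and for stepping through the model;
# roughly two orders of magnitude slower than the compiled path.

.trunc_norm_pos <- function(mean, sd) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

.new_nucleus <- function(n, beta, alpha, negate = FALSE) {
  o <- logistic(0, beta, alpha)
  list(a = rep(0, n), o = rep(if (negate) -o else o, n))
}

.engine_run_session_r <- function(card_mat, params, schedule, record_traces) {
  p <- params
  n_trials <- nrow(card_mat)
  w <- bg_weights()
  w[names(w)] <- p[names(w)]
  thresholds <- selection_thresholds(p$theta_s, p$theta_a_mean, p$theta_a_sd,
                                     p$area_scale)

  pfc <- .new_nucleus(3, p$beta_pfc, p$alpha_pfc)
  d1c <- .new_nucleus(3, p$beta_str, p$alpha_str)
  d2c <- .new_nucleus(3, p$beta_str, p$alpha_str)
  stnc <- .new_nucleus(3, p$beta_stn, p$alpha_stn)
  gpec <- .new_nucleus(3, p$beta_gpe, p$alpha_gpe)
  gpic <- .new_nucleus(3, p$beta_gpi, p$alpha_gpi)
  thalc <- .new_nucleus(3, p$beta_thal, p$alpha_thal, negate = TRUE)

  alpha_sma <- p$alpha_sma
  sma <- .new_nucleus(4, p$beta_sma, alpha_sma)
  d1s <- .new_nucleus(4, p$beta_str, p$alpha_str)
  d2s <- .new_nucleus(4, p$beta_str, p$alpha_str)
  stns <- .new_nucleus(4, p$beta_stn, p$alpha_stn)
  gpes <- .new_nucleus(4, p$beta_gpe, p$alpha_gpe)
  gpis <- .new_nucleus(4, p$beta_gpi, p$alpha_gpi)
  thals <- .new_nucleus(4, p$beta_thal, p$alpha_thal, negate = TRUE)

  beta_c <- rep(p$beta_str, 3)
  f_prev <- rep(0, 3)
  r_prev <- 0
  sel_c <- NA_integer_
  # cognitive evidence accumulates across trials (restarts on deselection);
  # sensorimotor accumulators restart at every card onset
  area_c <- rep(0, 3)

  log_cols <- list(trial = integer(n_trials), response = integer(n_trials),
                   applied_rule = integer(n_trials), active_rule = integer(n_trials),
                   feedback = integer(n_trials), rt_cycles = integer(n_trials),
                   selected_cognitive = integer(n_trials),
                   onset_cycle = integer(n_trials), response_cycle = integer(n_trials))
  beta_log <- matrix(0, n_trials, 3)
  alpha_log <- numeric(n_trials)
  tr_pfc <- list(); tr_sma <- list(); tr_gpis <- list()
  global_cycle <- 0L

  for (t in seq_len(n_trials)) {
    ct <- card_mat[t, ]
    match_vec <- rep(FALSE, 4)
    match_vec[ct] <- TRUE
    zstim_trial <- if (p$stim_noise == "per_trial")
      runif(4, -p$zeta_stim, p$zeta_stim) else rep(0, 4)
    thA_c <- .trunc_norm_pos(p$theta_a_mean, p$theta_a_sd)
    thA_s <- .trunc_norm_pos(p$theta_a_mean, p$theta_a_sd)
    area_s <- rep(0, 4)
    response <- NA_integer_; rt <- 0L
    pfc_hist <- matrix(0, p$cycle_cap, 3)
    log_cols$onset_cycle[t] <- global_cycle + 1L

    for (cyc in seq_len(p$cycle_cap)) {
      # noisy stimulus drive on matching targets
      zstim <- if (p$stim_noise == "per_trial") zstim_trial
               else runif(4, -p$zeta_stim, p$zeta_stim)
      stim <- ifelse(match_vec, p$o_stim + zstim, 0)

      # cognitive loop
      pfc <- step_cognitive(pfc, thalc$o, p)
      d2c_prev <- d2c$o; gpec_prev <- gpec$o
      d1c <- step_striatum(d1c, pfc$o, beta_c, p)
      d2c <- step_striatum(d2c, pfc$o,
                           if (p$d2_adapts) beta_c else rep(p$beta_str, 3), p)
      stnc <- step_stn(stnc, pfc$o, gpec_prev, w, p)
      gpec <- step_gpe(gpec, stnc$o, d2c_prev, w, p)
      gpic <- step_gpi(gpic, stnc$o, gpec$o, d1c$o, w, p)
      thalc <- step_thalamus(thalc, gpic$o, p)

      area_c <- area_c + pfc$o
      if (!is.na(sel_c) && pfc$o[sel_c] <= p$theta_s) {
        if (p$cog_area_policy != "cumulative") area_c[sel_c] <- 0
        sel_c <- NA_integer_
        thA_c <- .trunc_norm_pos(p$theta_a_mean, p$theta_a_sd)
      }
      if (is.na(sel_c) || p$sel_displacement) {
        cand <- check_selection(list(o = pfc$o, area = area_c), thresholds, thA_c)
        if (!is.na(cand) &&
            (is.na(sel_c) || pfc$o[cand] > pfc$o[sel_c]))
          sel_c <- cand
      }

      # sensorimotor loop
      sel_mask <- rep(FALSE, 3)
      if (!is.na(sel_c)) sel_mask[sel_c] <- TRUE
      routing <- matrix(0, 4, 3)
      routing[cbind(ct, 1:3)] <- 1
      sma <- step_sensorimotor(sma, pfc$o, sel_mask, stim, thals$o, p, routing,
                               alpha_sma = alpha_sma)
      d2s_prev <- d2s$o; gpes_prev <- gpes$o
      d1s <- step_striatum(d1s, sma$o, p$beta_str, p)
      d2s <- step_striatum(d2s, sma$o, p$beta_str, p)
      stns <- step_stn(stns, sma$o, gpes_prev, w, p)
      gpes <- step_gpe(gpes, stns$o, d2s_prev, w, p)
      gpis <- step_gpi(gpis, stns$o, gpes$o, d1s$o, w, p)
      thals <- step_thalamus(thals, gpis$o, p)

      pfc_hist[cyc, ] <- pfc$a
      if (record_traces) {
        tr_pfc[[length(tr_pfc) + 1L]] <- pfc$o
        tr_sma[[length(tr_sma) + 1L]] <- sma$o
        tr_gpis[[length(tr_gpis) + 1L]] <- gpis$o
      }
      global_cycle <- global_cycle + 1L

      area_s <- area_s + sma$o
      hit <- check_selection(list(o = sma$o, area = area_s), thresholds, thA_s)
      if (!is.na(hit)) {
        response <- hit
        rt <- cyc
        o_resp <- sma$o
        break
      }
    }

    log_cols$trial[t] <- t
    log_cols$selected_cognitive[t] <- if (is.na(sel_c)) 0L else sel_c
    log_cols$response_cycle[t] <- global_cycle

    if (is.na(response)) {
      log_cols$response[t] <- 0L
      log_cols$applied_rule[t] <- 0L
      log_cols$active_rule[t] <- match(schedule$active_rule, .rules)
      log_cols$feedback[t] <- 0L
      log_cols$rt_cycles[t] <- p$cycle_cap
      beta_log[t, ] <- beta_c
      alpha_log[t] <- alpha_sma
      next
    }

    applied <- which(ct == response)[1]
    if (is.na(applied)) applied <- 0L
    correct <- applied == match(schedule$active_rule, .rules)
    r <- if (correct) 1L else -1L

    log_cols$response[t] <- response
    log_cols$applied_rule[t] <- applied
    log_cols$active_rule[t] <- match(schedule$active_rule, .rules)
    log_cols$feedback[t] <- r
    log_cols$rt_cycles[t] <- rt

    med <- apply(pfc_hist[seq_len(rt), , drop = FALSE], 2, median)
    card <- list(t_colour = ct[1], t_shape = ct[2], t_number = ct[3])
    f_now <- vapply(1:3, function(i)
      feature_match(card, response, .rules[i], p, f_prev[i], r_prev),
      numeric(1))
    for (i in 1:3) {
      rpe <- reward_prediction_error(r, f_now[i], med[i], p$rpe_form)
      zeta <- runif(1, -p$zeta_str, p$zeta_str)
      beta_c[i] <- update_beta_str(beta_c[i], p$eps_str, rpe, zeta)
    }
    zeta <- runif(1, -p$zeta_sma, p$zeta_sma)
    alpha_sma <- update_alpha_sma(o_resp, p$eps_sma, zeta)
    f_prev <- f_now
    r_prev <- r
    beta_log[t, ] <- beta_c
    alpha_log[t] <- alpha_sma

    fb <- give_feedback(card, response, schedule)
    stopifnot(fb$feedback == r)
    schedule <- fb$schedule

    # inter-trial interval: card withdrawn, network keeps integrating; the
    # executed placement schema decays and its channel's latch fades
    for (k in seq_len(p$iti_cycles)) {
      pfc <- step_cognitive(pfc, thalc$o, p)
      d2c_prev <- d2c$o; gpec_prev <- gpec$o
      d1c <- step_striatum(d1c, pfc$o, beta_c, p)
      d2c <- step_striatum(d2c, pfc$o,
                           if (p$d2_adapts) beta_c else rep(p$beta_str, 3), p)
      stnc <- step_stn(stnc, pfc$o, gpec_prev, w, p)
      gpec <- step_gpe(gpec, stnc$o, d2c_prev, w, p)
      gpic <- step_gpi(gpic, stnc$o, gpec$o, d1c$o, w, p)
      thalc <- step_thalamus(thalc, gpic$o, p)
      area_c <- area_c + pfc$o
      if (!is.na(sel_c) && pfc$o[sel_c] <= p$theta_s) {
        if (p$cog_area_policy != "cumulative") area_c[sel_c] <- 0
        sel_c <- NA_integer_
        thA_c <- .trunc_norm_pos(p$theta_a_mean, p$theta_a_sd)
      }
      if (is.na(sel_c) || p$sel_displacement) {
        cand <- check_selection(list(o = pfc$o, area = area_c), thresholds, thA_c)
        if (!is.na(cand) &&
            (is.na(sel_c) || pfc$o[cand] > pfc$o[sel_c]))
          sel_c <- cand
      }
      sma <- step_sensorimotor(sma, pfc$o, rep(FALSE, 3), rep(0, 4), thals$o,
                               p, matrix(0, 4, 3), alpha_sma = alpha_sma)
      d2s_prev <- d2s$o; gpes_prev <- gpes$o
      d1s <- step_striatum(d1s, sma$o, p$beta_str, p)
      d2s <- step_striatum(d2s, sma$o, p$beta_str, p)
      stns <- step_stn(stns, sma$o, gpes_prev, w, p)
      gpes <- step_gpe(gpes, stns$o, d2s_prev, w, p)
      gpis <- step_gpi(gpis, stns$o, gpes$o, d1s$o, w, p)
      thals <- step_thalamus(thals, gpis$o, p)
      if (record_traces) {
        tr_pfc[[length(tr_pfc) + 1L]] <- pfc$o
        tr_sma[[length(tr_sma) + 1L]] <- sma$o
        tr_gpis[[length(tr_gpis) + 1L]] <- gpis$o
      }
      global_cycle <- global_cycle + 1L
    }
  }

  out <- c(log_cols, list(beta_str = beta_log, alpha_sma = alpha_log,
                          categories = schedule$categories))
  if (record_traces) {
    out$trace_pfc <- t(do.call(cbind, tr_pfc))
    out$trace_sma <- t(do.call(cbind, tr_sma))
    out$trace_gpi_sma <- t(do.call(cbind, tr_gpis))
    # transpose to node x cycle for parity with the compiled engine layout
    out$trace_pfc <- t(out$trace_pfc)
    out$trace_sma <- t(out$trace_sma)
    out$trace_gpi_sma <- t(out$trace_gpi_sma)
  }
  out
}

#' Run a single trial with the reference dynamics
#'
#' Convenience wrapper around the reference engine for stepping through a
#' single card presentation from a quiescent network; activations do not
#' carry over. For full sessions use [run_session()].
#'
#' @param card A card (one-row data frame).
#' @param params A [wcst_params()] list.
#' @param active_rule The schedule's active rule for feedback.
#' @param seed Optional seed.
#' @return List with `response`, `applied_rule`, `feedback`, `rt_cycles`.
#' @export
run_trial <- function(card, params = wcst_params(), active_rule = "colour",
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  card_mat <- as.matrix(card[, c("t_colour", "t_shape", "t_number")])
  storage.mode(card_mat) <- "integer"
  schedule <- new_rule_schedule("criterion", active_rule = active_rule)
  raw <- .engine_run_session_r(card_mat, params, schedule, FALSE)
  list(response = if (raw$response[1] == 0L) NA_integer_ else raw$response[1],
       applied_rule = if (raw$applied_rule[1] == 0L) NA_character_
                      else .rules[raw$applied_rule[1]],
       feedback = if (raw$feedback[1] == 0L) NA_integer_ else raw$feedback[1],
       rt_cycles = raw$rt_cycles[1])
}
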