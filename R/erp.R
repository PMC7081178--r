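# Proxies for two ERP components, computed from cycle-level schema outputs:
# the error-related negativity (ERN) from one-step changes in sensorimotor
# outputs, and the sustained parietal positivity / posterior switch
# positivity (SPP/PSP) from one-step changes in cognitive outputs.

#' Signed element of largest magnitude
#'
#' @param v Non-empty numeric vector.
#' @return The element of `v` with the greatest absolute value, sign
#'   preserved; ties go to the lowest index.
#' @export
absmax <- function(v) {
  if (!length(v)) stop("empty vector")
  v[which.max(abs(v))]
}

#' Per-cycle ERN proxy signal
#'
#' At each cycle the signal is the negated extreme one-step change across
#' sensorimotor outputs: `-absmax(o_sma(t) - o_sma(t-1))`. Large abrupt
#' changes in placement-schema activity (response selection, feedback-driven
#' gain changes) show up as deflections.
#'
#' @param sma_outputs Cycle x node matrix of sensorimotor outputs.
#' @return Numeric vector, one value per cycle (first cycle 0).
#' @export
ern_signal <- function(sma_outputs) {
  n <- nrow(sma_outputs)
  if (n < 2L) return(numeric(n))
  d <- diff(sma_outputs)
  c(0, -apply(d, 1, absmax))
}

#' Per-cycle SPP proxy signal
#'
#' `absmax(o_pfc(t) - o_pfc(t-1))` across cognitive (rule) outputs; rule
#' switches produce large values.
#'
#' @param pfc_outputs Cycle x node matrix of cognitive outputs.
#' @return Numeric vector, one value per cycle (first cycle 0).
#' @export
spp_trace <- function(pfc_outputs) {
  n <- nrow(pfc_outputs)
  if (n < 2L) return(numeric(n))
  d <- diff(pfc_outputs)
  c(0, apply(d, 1, absmax))
}

#' Response-locked ERN traces by outcome
#'
#' Cuts the per-cycle ERN signal into response-locked windows
#' (`window_pre` cycles before to `window_post` cycles after each response)
#' and averages them separately over correct and incorrect trials.
#'
#' @param run A `wcst_run` produced with `record_traces = TRUE`.
#' @param window_pre,window_post Window half-widths in cycles.
#' @return List with `cycles` (window offsets), `correct` and `incorrect`
#'   (mean traces; `NULL` when that outcome never occurred), `n_correct`,
#'   `n_incorrect`, and `per_trial` (trial x window matrix with outcome
#'   labels).
#' @export
ern_trace <- function(run, window_pre = 20L, window_post = 40L) {
  stopifnot(!is.null(run$traces))
  sig <- ern_signal(run$traces$sma)
  .locked_traces(sig, run$log, window_pre, window_post)
}

# offsets after the response occupied by the stereotyped decay of the
# executed placement schema; identical for correct and incorrect responses,
# so it is masked when outcome-dependent peaks are measured
.execution_transient <- 8L

.locked_traces <- function(sig, log, window_pre, window_post) {
  offsets <- seq(-window_pre, window_post)
  ok <- log$error_class != "omission"
  centers <- log$response_cycle[ok]
  outcome <- ifelse(log$feedback[ok] > 0, "correct", "incorrect")
  keep <- centers - window_pre - 10L >= 1L & centers + window_post <= length(sig)
  centers <- centers[keep]
  outcome <- outcome[keep]
  per_trial <- t(vapply(centers, function(cc) sig[cc + offsets],
                        numeric(length(offsets))))
  baseline <- vapply(centers, function(cc)
    mean(sig[(cc - window_pre - 10L):(cc - window_pre - 1L)]), numeric(1))
  mean_of <- function(lbl) {
    if (!any(outcome == lbl)) return(NULL)
    colMeans(per_trial[outcome == lbl, , drop = FALSE])
  }
  list(cycles = offsets,
       correct = mean_of("correct"),
       incorrect = mean_of("incorrect"),
       n_correct = sum(outcome == "correct"),
       n_incorrect = sum(outcome == "incorrect"),
       per_trial = per_trial, outcome = outcome, baseline = baseline)
}

#' ERN attenuation of a session
#'
#' Summarises the response-locked ERN component as the peak-to-baseline
#' magnitude of the mean correct-trial signal minus the same magnitude for
#' incorrect trials (baseline: mean signal over the 10 cycles preceding the
#' window). The stereotyped decay transient of the executed placement schema
#' (the first few cycles after the response, identical for both outcomes) is
#' masked, so the measure reflects the outcome-dependent reorganisation that
#' follows feedback. A robust error signal makes the incorrect-trial
#' deflection larger than the correct-trial one, giving a negative value; as
#' the error signal attenuates the difference shrinks towards zero.
#'
#' @inheritParams ern_trace
#' @return Scalar attenuation, or `NA` (flagged with a warning) when the
#'   session has no correct or no incorrect trials.
#' @export
ern_attenuation <- function(run, window_pre = 20L, window_post = 40L) {
  tr <- ern_trace(run, window_pre, window_post)
  if (is.null(tr$correct) || is.null(tr$incorrect)) {
    warning("ERN attenuation undefined: need both correct and incorrect trials")
    return(NA_real_)
  }
  # mask the two exogenous, outcome-independent transients: the decay of
  # the executed schema right after the response, and the ringing of the
  # next card's onset rise (the card appears iti_cycles after the response)
  iti <- run$params$iti_cycles
  cyc <- tr$cycles
  keep <- (cyc <= 0L | cyc > .execution_transient) &
    !(cyc > iti & cyc <= iti + .execution_transient)
  base_c <- mean(tr$baseline[tr$outcome == "correct"])
  base_i <- mean(tr$baseline[tr$outcome == "incorrect"])
  mag <- function(trace, base) max(abs(trace[keep] - base))
  mag(tr$correct, base_c) - mag(tr$incorrect, base_i)
}

#' Trial labels for set shifting
#'
#' A shift trial is the first trial on which the model's selected cognitive
#' schema differs from the previous trial's after negative feedback; the
#' trial immediately following a shift is the first-cue (post-shift) trial.
#'
#' @param log A session log.
#' @return Character vector per trial: `shift`, `post_shift`, or `repeat`.
#' @export
shift_labels <- function(log) {
  n <- nrow(log)
  lab <- rep("repeat", n)
  sel <- log$selected_cognitive
  for (t in 2:n) {
    if (!is.na(sel[t]) && !is.na(sel[t - 1]) && sel[t] != sel[t - 1] &&
        !is.na(log$feedback[t - 1]) && log$feedback[t - 1] < 0)
      lab[t] <- "shift"
  }
  post <- which(lab == "shift") + 1L
  post <- post[post <= n & lab[post] != "shift"]
  lab[post] <- "post_shift"
  lab
}

#' PSP attenuation of a session
#'
#' Mean peak SPP over shift trials minus mean peak SPP over the trials
#' immediately following them. Each trial's peak is taken over the cycles
#' from the previous response up to the trial's own response, so the
#' schema transition that the shift realises (which unfolds between the two
#' responses) lies inside the shift trial's window. Sessions in which the
#' model never switches schema have no shift trials and the PSP is
#' undefined (`NA`, flagged).
#'
#' @param run A `wcst_run` with traces.
#' @return Scalar attenuation or flagged `NA`.
#' @export
psp_attenuation <- function(run) {
  stopifnot(!is.null(run$traces))
  sig <- spp_trace(run$traces$pfc)
  log <- run$log
  lab <- shift_labels(log)
  n <- nrow(log)
  from <- c(log$onset_cycle[1], log$response_cycle[-n] + 1L)
  peak <- vapply(seq_len(n), function(t)
    max(sig[from[t]:log$response_cycle[t]]), numeric(1))
  if (!any(lab == "shift") || !any(lab == "post_shift")) {
    warning("PSP undefined: no schema shifts in session")
    return(NA_real_)
  }
  mean(peak[lab == "shift"]) - mean(peak[lab == "post_shift"])
}

#' ERN and PSP attenuation of a session
#'
#' @param run A `wcst_run` with traces.
#' @return `list(ern_att, psp_att)` (either may be flagged `NA`).
#' @export
session_erp_summary <- function(run) {
  ern <- suppressWarnings(ern_attenuation(run))
  psp <- suppressWarnings(psp_attenuation(run))
  list(ern_att = ern, psp_att = psp)
}

#' Centred moving average
#'
#' @param x Numeric series.
#' @param window Odd window length; endpoints use the shrunken symmetric
#'   window that fits.
#' @return Smoothed series of the same length.
#' @export
smooth_signal <- function(x, window = 5L) {
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}
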