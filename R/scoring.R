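#' Classify every trial of a session log
#'
#' Negative-feedback trials are scored with the three-way taxonomy used for
#' the unambiguous WCST:
#'
#' * **PE** (perseverative error): the response applies the most recently
#'   rewarded rule even though feedback on the previous trial was negative.
#' * **SL** (set-loss error): the response changes rule despite positive
#'   feedback on the previous trial.
#' * **IE** (integration error): following negative feedback the response
#'   switches to a rule that had already been applied and punished on the
#'   trial before that feedback (two trials back) -- a failure to integrate
#'   recent feedback.
#' * **other_error**: any remaining error, including the unavoidable first
#'   error after an unannounced rule change and responses sharing no feature
#'   with the chosen target. Omissions are scored `omission`.
#'
#' Precedence is PE, then SL, then IE. Trials with no previous trial cannot be
#' classified beyond other_error.
#'
#' @param log A per-trial data frame with columns `applied_rule`, `feedback`
#'   (+1/-1, NA for omissions) and `response`.
#' @param ie_positive_exclusion Also count as IE a switch to a rule that was
#'   logically excluded by *positive* feedback two trials back. Off by
#'   default: with criterion schedules this would score every unlucky first
#'   switch attempt as an integration failure.
#' @return Character vector of classes, one per trial:
#'   `correct`, `PE`, `SL`, `IE`, `other_error`, `omission`.
#' @export
classify_errors <- function(log, ie_positive_exclusion = FALSE) {
  n <- nrow(log)
  out <- character(n)
  last_rewarded <- NA_character_
  for (t in seq_len(n)) {
    fb <- log$feedback[t]
    if (is.na(fb)) {
      out[t] <- "omission"
      next
    }
    if (fb > 0) {
      out[t] <- "correct"
      last_rewarded_next <- log$applied_rule[t]
    } else {
      out[t] <- .classify_one(log, t, last_rewarded, ie_positive_exclusion)
      last_rewarded_next <- last_rewarded
    }
    last_rewarded <- last_rewarded_next
  }
  out
}

# classify a single negative-feedback trial given the most recently rewarded
# rule as of t-1
.classify_one <- function(log, t, last_rewarded, ie_positive_exclusion) {
  rule_t <- log$applied_rule[t]
  if (t == 1L) return("other_error")
  fb_prev <- log$feedback[t - 1L]
  rule_prev <- log$applied_rule[t - 1L]
  if (is.na(fb_prev)) return("other_error")
  # PE: consistent with the previously successful rule despite negative feedback
  if (fb_prev < 0 && !is.na(last_rewarded) && !is.na(rule_t) &&
      rule_t == last_rewarded)
    return("PE")
  # SL: rule change despite positive feedback on the previous trial
  if (fb_prev > 0 && !is.na(rule_t) && !is.na(rule_prev) && rule_t != rule_prev)
    return("SL")
  # IE: switch after negative feedback to a rule excluded by the trial before
  if (fb_prev < 0 && !is.na(rule_t) && !is.na(rule_prev) && rule_t != rule_prev &&
      t >= 3L && !is.na(log$feedback[t - 2L])) {
    fb2 <- log$feedback[t - 2L]
    rule2 <- log$applied_rule[t - 2L]
    punished_then <- fb2 < 0 && !is.na(rule2) && rule2 == rule_t
    excluded_by_pos <- ie_positive_exclusion && fb2 > 0 && !is.na(rule2) &&
      rule2 != rule_t
    if (punished_then || excluded_by_pos) return("IE")
  }
  "other_error"
}

#' Classify one trial of a history
#'
#' Single-trial accessor over [classify_errors()].
#'
#' @param history Per-trial data frame (see [classify_errors()]).
#' @param t Trial index (1-based).
#' @param ... Passed to [classify_errors()].
#' @return The class of trial `t`.
#' @export
classify_error <- function(history, t, ...) {
  if (t < 1L || t > nrow(history)) stop("`t` out of range")
  classify_errors(history, ...)[t]
}

#' Completed criterion runs in a session
#'
#' @param log Per-trial data frame with a `feedback` column.
#' @param schedule The schedule the session was run under (for the criterion
#'   length); alternatively pass `criterion_length` directly.
#' @param criterion_length Used when `schedule` is `NULL`.
#' @return Number of completed runs of consecutive correct sorts (categories
#'   achieved).
#' @export
count_categories <- function(log, schedule = NULL, criterion_length = 10L) {
  if (!is.null(schedule)) {
    if (schedule$mode != "criterion")
      stop("category counting from a log requires a criterion schedule; ",
           "random-run schedules report categories in the run result")
    criterion_length <- schedule$criterion_length
  }
  run <- 0L
  cats <- 0L
  for (fb in log$feedback) {
    if (!is.na(fb) && fb > 0) {
      run <- run + 1L
      if (run >= criterion_length) {
        cats <- cats + 1L
        run <- 0L
      }
    } else {
      run <- 0L
    }
  }
  cats
}
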