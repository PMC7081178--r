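#' Create a rule schedule
#'
#' The experimenter's side of the task: an active sorting rule, positive
#' feedback for responses consistent with it, and a rule change once the
#' criterion run of correct sorts is reached. Two modes are supported:
#' `"criterion"` switches after a fixed number of consecutive correct sorts
#' (default 10), `"random_run"` switches after a run length drawn uniformly
#' from `run_length_support` (default {2,3,4,5}, median 3.5), redrawn at every
#' switch.
#'
#' @param mode `"criterion"` or `"random_run"`.
#' @param criterion_length Correct sorts required before a switch in
#'   criterion mode.
#' @param run_length_support Integer support of the run-length draw in
#'   random-run mode.
#' @param active_rule Starting rule; `NULL` draws one uniformly.
#'
#' @return A list with class `wcst_schedule` holding the active rule, the
#'   correct-run counter, the current run target and the categories count.
#' @export
new_rule_schedule <- function(mode = c("criterion", "random_run"),
                              criterion_length = 10L,
                              run_length_support = 2:5,
                              active_rule = NULL) {
  mode <- match.arg(mode)
  if (is.null(active_rule)) active_rule <- .rules[sample.int(3L, 1L)]
  active_rule <- match.arg(active_rule, .rules)
  run_length_support <- as.integer(run_length_support)
  run_target <- if (mode == "criterion") as.integer(criterion_length)
                else run_length_support[1L + floor(runif(1) * length(run_length_support))]
  structure(list(
    mode = mode,
    criterion_length = as.integer(criterion_length),
    run_length_support = as.integer(run_length_support),
    active_rule = active_rule,
    run_counter = 0L,
    run_target = run_target,
    categories = 0L
  ), class = "wcst_schedule")
}

#' Deliver feedback and advance the schedule
#'
#' Feedback is +1 iff the rule applied by the response equals the schedule's
#' active rule. On the criterion-th consecutive correct sort the category is
#' credited and the active rule switches to one of the two other rules,
#' drawn uniformly.
#'
#' @param card The stimulus card.
#' @param response Target index 1--4.
#' @param schedule A `wcst_schedule`.
#' @return `list(feedback = +1 or -1, schedule = updated schedule)`.
#' @export
give_feedback <- function(card, response, schedule) {
  stopifnot(inherits(schedule, "wcst_schedule"))
  rule <- applied_rule(card, response)
  correct <- !is.na(rule) && rule == schedule$active_rule
  if (correct) {
    schedule$run_counter <- schedule$run_counter + 1L
    if (schedule$run_counter >= schedule$run_target) {
      schedule$categories <- schedule$categories + 1L
      others <- setdiff(.rules, schedule$active_rule)
      schedule$active_rule <- others[1L + floor(runif(1) * 2)]
      schedule$run_counter <- 0L
      if (schedule$mode == "random_run") {
        sup <- schedule$run_length_support
        schedule$run_target <- sup[1L + floor(runif(1) * length(sup))]
      }
    }
  } else {
    schedule$run_counter <- 0L
  }
  list(feedback = if (correct) 1L else -1L, schedule = schedule)
}
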