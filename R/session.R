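#' Run one WCST session
#'
#' Builds a trial sequence from shuffled copies of the 24-card deck, runs the
#' full two-loop dynamics trial by trial (compiled engine), scores every
#' trial with the PE/SL/IE taxonomy and returns per-trial and session-level
#' results. Cortical and subcortical activations persist across trials and
#' through a short inter-trial interval in which the card is withdrawn;
#' sensorimotor evidence accumulators reset at each card onset, cognitive
#' ones when a rule schema loses selection.
#'
#' @param params A [wcst_params()] list.
#' @param n_trials Number of cards (default 64).
#' @param schedule_mode `"criterion"` (switch after `criterion_length`
#'   consecutive correct sorts) or `"random_run"` (switch after a run drawn
#'   uniformly from `run_length_support`).
#' @param seed Integer seed making the session fully reproducible; `NULL`
#'   continues the caller's RNG stream.
#' @param record_traces Keep per-cycle outputs of the cognitive, sensorimotor
#'   and sensorimotor-GPi layers (needed for the ERP proxies).
#' @param criterion_length,run_length_support Schedule settings.
#' @param engine `"cpp"` (default) or `"r"` for the pure-R reference engine,
#'   which reproduces the compiled engine cycle-for-cycle (slow; used for
#'   validation).
#'
#' @return A list of class `wcst_run`:
#'   `log` (per-trial data frame), `summary` (named vector of session
#'   measures), `categories`, `seed`, `params`, and when requested `traces`
#'   (list of cycle x node matrices `pfc`, `sma`, `gpi_sma`).
#' @export
run_session <- function(params = wcst_params(), n_trials = 64L,
                        schedule_mode = c("criterion", "random_run"),
                        seed = NULL, record_traces = FALSE,
                        criterion_length = 10L, run_length_support = 2:5,
                        engine = c("cpp", "r")) {
  schedule_mode <- match.arg(schedule_mode)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  if (n_trials < 1) stop("`n_trials` must be >= 1")

  cards <- build_trial_sequence(n_trials)
  schedule <- new_rule_schedule(schedule_mode, criterion_length,
                                run_length_support)
  card_mat <- as.matrix(cards[, c("t_colour", "t_shape", "t_number")])
  storage.mode(card_mat) <- "integer"

  raw <- if (engine == "cpp") {
    .engine_run_session(card_mat, params,
                        ifelse(schedule_mode == "criterion", 0L, 1L),
                        as.integer(criterion_length),
                        as.integer(run_length_support),
                        match(schedule$active_rule, .rules),
                        schedule$run_target, record_traces)
  } else {
    .engine_run_session_r(card_mat, params, schedule, record_traces)
  }

  log <- data.frame(
    trial = raw$trial,
    card_colour = cards$colour, card_shape = cards$shape,
    card_number = cards$number,
    response = ifelse(raw$response == 0L, NA_integer_, raw$response),
    applied_rule = ifelse(raw$applied_rule == 0L, NA_character_,
                          .rules[pmax(raw$applied_rule, 1L)]),
    active_rule = .rules[raw$active_rule],
    feedback = ifelse(raw$feedback == 0L, NA_integer_, raw$feedback),
    rt_cycles = raw$rt_cycles,
    selected_cognitive = ifelse(raw$selected_cognitive == 0L, NA_integer_,
                                raw$selected_cognitive),
    onset_cycle = raw$onset_cycle,
    response_cycle = raw$response_cycle,
    stringsAsFactors = FALSE
  )
  log$error_class <- classify_errors(log, params$ie_positive_exclusion)

  res <- list(
    log = log,
    categories = raw$categories,
    beta_str = raw$beta_str,
    alpha_sma = raw$alpha_sma,
    seed = seed,
    params = params,
    schedule_mode = schedule_mode
  )
  if (record_traces)
    res$traces <- list(pfc = t(raw$trace_pfc), sma = t(raw$trace_sma),
                       gpi_sma = t(raw$trace_gpi_sma))
  res$summary <- summarize_session(res)
  class(res) <- "wcst_run"
  res
}

#' @export
print.wcst_run <- function(x, ...) {
  cat("<wcst_run> ", nrow(x$log), "trials\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' Session-level dependent measures
#'
#' @param run A `wcst_run`.
#' @return Named vector: `cards_correct`, `categories`, `PE`, `SL`, `IE`,
#'   `other_error`, `omissions`, `rt_post_positive`, `rt_post_negative`
#'   (mean cycles on trials preceded by positive / negative feedback;
#'   omissions excluded from RT averages).
#' @export
summarize_session <- function(run) {
  log <- run$log
  cls <- log$error_class
  n <- nrow(log)
  prev_fb <- c(NA, log$feedback[-n])
  valid_rt <- cls != "omission"
  c(
    cards_correct = sum(cls == "correct"),
    categories = run$categories,
    PE = sum(cls == "PE"),
    SL = sum(cls == "SL"),
    IE = sum(cls == "IE"),
    other_error = sum(cls == "other_error"),
    omissions = sum(cls == "omission"),
    rt_post_positive = mean(log$rt_cycles[valid_rt & !is.na(prev_fb) & prev_fb > 0]),
    rt_post_negative = mean(log$rt_cycles[valid_rt & !is.na(prev_fb) & prev_fb < 0])
  )
}

#' Run many sessions, optionally across a group's parameter points
#'
#' For fixed/midpoint groups, `n_runs` sessions at the (mid)point; for grid
#' groups, `n_runs` sessions at each grid point. Each session gets its own
#' sub-seed derived from `seed`, so results are reproducible and independent
#' of ordering.
#'
#' @param group A [group_spec()] (or `NULL` for the base parameter set).
#' @param n_runs Sessions per parameter point.
#' @param base Base [wcst_params()]; the group's four parameters override it.
#' @param seed Master seed.
#' @param n_trials,schedule_mode,... Passed to [run_session()].
#' @param measure_erp Also compute per-session ERN/PSP attenuation (runs with
#'   traces; see [session_erp_summary()]).
#' @return A data frame with one row per session: parameter point, seed, the
#'   session measures, and (when `measure_erp`) `ern_att` and `psp_att`.
#' @export
run_group <- function(group = NULL, n_runs = 100L, base = wcst_params(),
                      seed = 1L, n_trials = 64L,
                      schedule_mode = "criterion", measure_erp = FALSE, ...) {
  pts <- if (is.null(group)) {
    data.frame(eps_str = base$eps_str, eps_sma = base$eps_sma,
               w_neg = base$w_neg, m_r = base$m_r, group = "base")
  } else {
    group_points(group)
  }
  if (nrow(pts) == 0L) stop("empty parameter point set")
  rows <- vector("list", nrow(pts) * n_runs)
  k <- 0L
  for (p in seq_len(nrow(pts))) {
    par_p <- base
    par_p$eps_str <- pts$eps_str[p]
    par_p$eps_sma <- pts$eps_sma[p]
    par_p$w_neg <- pts$w_neg[p]
    par_p$m_r <- pts$m_r[p]
    for (rn in seq_len(n_runs)) {
      k <- k + 1L
      run_seed <- (as.numeric(seed) * 10007 + p * 211 + rn) %%
        .Machine$integer.max
      run <- run_session(par_p, n_trials = n_trials,
                         schedule_mode = schedule_mode, seed = run_seed,
                         record_traces = measure_erp, ...)
      meas <- run$summary
      row <- data.frame(group = pts$group[p], point = p, run = rn,
                        seed = run_seed,
                        eps_str = pts$eps_str[p], eps_sma = pts$eps_sma[p],
                        w_neg = pts$w_neg[p], m_r = pts$m_r[p],
                        t(meas), stringsAsFactors = FALSE)
      if (measure_erp) {
        erp <- session_erp_summary(run)
        row$ern_att <- erp$ern_att
        row$psp_att <- erp$psp_att
      }
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Mean and s.d. of dependent measures over runs
#'
#' @param results Data frame from [run_group()] (one row per session).
#' @param measures Columns to summarise.
#' @return Data frame with one row per group and `mean_*` / `sd_*` columns.
#'   With a single run the s.d. is reported as 0 and flagged in
#'   `attr(, "single_run")`.
#' @export
summarize_runs <- function(results,
                           measures = c("cards_correct", "categories", "PE",
                                        "SL", "IE", "rt_post_positive",
                                        "rt_post_negative")) {
  if (!nrow(results)) stop("no results to summarise")
  measures <- intersect(measures, names(results))
  groups <- unique(results$group)
  out <- lapply(groups, function(g) {
    sub <- results[results$group == g, measures, drop = FALSE]
    mns <- vapply(sub, mean, numeric(1), na.rm = TRUE)
    sds <- if (nrow(sub) > 1L) vapply(sub, sd, numeric(1), na.rm = TRUE)
           else rep(0, length(measures))
    stats <- c(rbind(mns, sds))
    names(stats) <- paste0(rep(c("mean_", "sd_"), length(measures)),
                           rep(measures, each = 2))
    data.frame(group = g, t(stats), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "single_run") <- any(table(results$group) == 1L)
  out
}

#' Calibrate the area scale against a target response time
#'
#' The integration threshold is specified in area units (mean 4000) while
#' response times are tens-to-hundreds of cycles; `area_scale` converts the
#' per-cycle output sum into area units. This routine bisects over
#' `area_scale` until the mean post-positive-feedback RT under `base`
#' parameters matches `target_rt`. RT decreases monotonically in
#' `area_scale` (a larger scale crosses the threshold sooner).
#'
#' @param base Base parameter set.
#' @param target_rt Target mean post-positive RT in cycles.
#' @param n_runs Sessions per evaluation.
#' @param lower,upper Bracketing search range.
#' @param tol Stop when the achieved RT is within `tol` cycles.
#' @param seed Seed for the evaluation runs (held fixed across iterations so
#'   the search sees a smooth objective).
#' @return The calibrated `area_scale` (also attached as
#'   `attr(, "achieved_rt")`).
#' @export
calibrate_area_scale <- function(base = wcst_params(), target_rt = 129.10,
                                 n_runs = 20L, lower = 5, upper = 200,
                                 tol = 2, seed = 101L) {
  eval_rt <- function(scale) {
    pp <- base
    pp$area_scale <- scale
    res <- run_group(NULL, n_runs = n_runs, base = pp, seed = seed)
    mean(res$rt_post_positive, na.rm = TRUE)
  }
  rt_lo <- eval_rt(lower)
  rt_hi <- eval_rt(upper)
  if (!(rt_lo > target_rt && rt_hi < target_rt))
    stop("search range does not bracket the target RT (",
         round(rt_lo, 1), " .. ", round(rt_hi, 1), ")")
  for (it in 1:40) {
    mid <- sqrt(lower * upper)
    rt_mid <- eval_rt(mid)
    if (abs(rt_mid - target_rt) <= tol) break
    if (rt_mid > target_rt) lower <- mid else upper <- mid
  }
  structure(mid, achieved_rt = rt_mid)
}

#' Write a per-trial session log as CSV
#'
#' Columns: trial, card features, response, applied and active rule,
#' feedback, response time in cycles, error class.
#'
#' @param run A `wcst_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(run, path) {
  cols <- c("trial", "card_colour", "card_shape", "card_number", "response",
            "applied_rule", "active_rule", "feedback", "rt_cycles",
            "error_class")
  write.csv(run$log[, cols], path, row.names = FALSE)
  invisible(path)
}
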