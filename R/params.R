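#' Full model parameter set
#'
#' Returns the default parameter set of the model; any parameter can be
#' overridden by name. Defaults:
#'
#' * `delta` 0.60 — smoothing constant of all leaky integrations.
#' * `o_ext` 0.75 — constant top-down excitation of cognitive schema units.
#' * `o_stim` 0.50 — stimulus drive to matching sensorimotor units.
#' * `w_rule` 0.40 — weight from a selected cognitive schema to the
#'   sensorimotor unit its rule routes the card onto.
#' * `w_neg` 0.00, `m_r` 0.00 — negative-reward sensitivity and feedback
#'   memory in the feature-match value.
#' * basal-ganglia weights, see [bg_weights()].
#' * `eps_str` 0.40, `eps_sma` 0.50 — striatal and sensorimotor learning
#'   rates.
#' * `theta_a_mean` 4000, `theta_a_sd` 400 — per-trial integration threshold
#'   draw (area units); `theta_s` 0.50 — static selection threshold.
#' * gains `alpha_*` 8 (striatum 8.5); thresholds `beta_*` per layer
#'   (thalamus 0.45, sensorimotor cortex 0.40, cognitive cortex 0.50,
#'   striatum 0.50, STN 0.30, GPe 0.25, GPi 0.25).
#' * noise half-ranges: `zeta_stim` 0.2, `zeta_str` 0.1, `zeta_sma` 0.1
#'   (uniform, symmetric about 0).
#' * implementation constants: `area_scale` (cycle-sum to area-unit
#'   calibration, see [calibrate_area_scale()]); `cycle_cap` 1000 (a trial
#'   that reaches it is an omission); `iti_cycles` 20 (cycles between a
#'   response and the next card, with the card withdrawn, during which the
#'   executed placement schema decays); `d2_adapts` (whether the adapted
#'   cognitive striatal threshold is shared by D1 and D2; default TRUE);
#'   `rpe_form` (see [reward_prediction_error()]); `sel_displacement`
#'   (whether a qualifying higher-output cognitive schema may displace the
#'   incumbent; default TRUE); `cog_area_policy` (`"reset_deselect"`:
#'   cognitive evidence accumulates across trials and restarts when the node
#'   is deselected; `"cumulative"`: never restarts); `stim_noise`
#'   (`"per_cycle"` or `"per_trial"` draw of the stimulus noise);
#'   `ie_positive_exclusion` (see [classify_errors()]).
#'
#' @param ... Named overrides, e.g. `wcst_params(eps_str = 0.1, w_neg = 0.65)`.
#' @return A named list with class `wcst_params`. Overridden names are
#'   recorded in `attr(, "overrides")`.
#' @export
wcst_params <- function(...) {
  p <- list(
    delta = 0.60,
    o_ext = 0.75,
    o_stim = 0.50,
    w_rule = 0.40,
    w_neg = 0.00,
    m_r = 0.00,
    w_ctx_stn = 1.2,
    w_gpe_stn = -1.0,
    w_stn_gpe = 0.9,
    w_strd2_gpe = -1.0,
    w_stn_gpi = 0.9,
    w_gpe_gpi = -0.3,
    w_strd1_gpi = -1.0,
    eps_str = 0.40,
    eps_sma = 0.50,
    theta_a_mean = 4000,
    theta_a_sd = 400,
    theta_s = 0.50,
    alpha_pfc = 8.0,
    alpha_sma = 8.0,
    alpha_stn = 8.0,
    alpha_gpe = 8.0,
    alpha_gpi = 8.0,
    alpha_thal = 8.0,
    alpha_str = 8.5,
    beta_pfc = 0.50,
    beta_sma = 0.40,
    beta_str = 0.50,
    beta_stn = 0.30,
    beta_gpe = 0.25,
    beta_gpi = 0.25,
    beta_thal = 0.45,
    zeta_stim = 0.2,
    zeta_str = 0.1,
    zeta_sma = 0.1,
    area_scale = 32.78,
    cycle_cap = 1000L,
    iti_cycles = 20L,
    d2_adapts = TRUE,
    rpe_form = "signed_match",
    sel_displacement = TRUE,
    cog_area_policy = "reset_deselect",
    stim_noise = "per_cycle",
    ie_positive_exclusion = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  structure(p, overrides = names(over), class = c("wcst_params", "list"))
}

#' @export
print.wcst_params <- function(x, ...) {
  cat("<wcst_params>\n")
  over <- attr(x, "overrides")
  for (nm in names(x)) {
    mark <- if (nm %in% over) " *" else ""
    cat(sprintf("  %-22s %s%s\n", nm, format(x[[nm]]), mark))
  }
  if (length(over)) cat("  (* overridden from default)\n")
  invisible(x)
}

#' Virtual participant group specification
#'
#' A group is a point or region of the four-dimensional space
#' (`eps_str`, `eps_sma`, `w_neg`, `m_r`). `fixed` mode uses the values as
#' given; `midpoint` collapses each range to its midpoint; `grid` evaluates
#' the midpoints of `subintervals` equal subdivisions of each range
#' (`subintervals^4` points).
#'
#' @param name Group label.
#' @param eps_str,eps_sma,w_neg,m_r A single value or a length-2 range.
#' @param mode `"fixed"`, `"midpoint"` or `"grid"`.
#' @param subintervals Number of equal subintervals per dimension in grid
#'   mode.
#' @return A list with class `group_spec`.
#' @export
group_spec <- function(name, eps_str, eps_sma = 0.5, w_neg = 0, m_r = 0,
                       mode = c("fixed", "midpoint", "grid"),
                       subintervals = 4L) {
  mode <- match.arg(mode)
  rng <- function(x) {
    if (!length(x) %in% 1:2 || any(!is.finite(x))) stop("invalid range")
    range(x)
  }
  structure(list(
    name = name,
    eps_str = rng(eps_str), eps_sma = rng(eps_sma),
    w_neg = rng(w_neg), m_r = rng(m_r),
    mode = mode, subintervals = as.integer(subintervals)
  ), class = "group_spec")
}

#' Parameter points of a group specification
#'
#' @param group A [group_spec()].
#' @return A data frame of parameter points (one row in fixed/midpoint mode,
#'   `subintervals^4` rows in grid mode).
#' @export
group_points <- function(group) {
  stopifnot(inherits(group, "group_spec"))
  dims <- c("eps_str", "eps_sma", "w_neg", "m_r")
  if (group$mode == "grid") {
    k <- group$subintervals
    if (k < 1L) stop("subintervals must be >= 1")
    vals <- lapply(dims, function(d) {
      r <- group[[d]]
      # midpoints of k equal subintervals
      r[1] + (seq_len(k) - 0.5) * diff(r) / k
    })
    names(vals) <- dims
    out <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  } else if (group$mode == "midpoint") {
    out <- as.data.frame(lapply(setNames(dims, dims), function(d) mean(group[[d]])))
  } else {
    if (any(vapply(dims, function(d) diff(group[[d]]) > 0, logical(1))))
      stop("fixed mode requires single values, not ranges")
    out <- as.data.frame(lapply(setNames(dims, dims), function(d) group[[d]][1]))
  }
  out$group <- group$name
  out
}

#' Published parameter spaces for virtual HC and PD groups
#'
#' Healthy controls: `eps_str` 0.40--0.70, `eps_sma` 0.50--0.70, `w_neg`
#' 0.00--0.20, `m_r` 0.00--0.20. Parkinson's disease: `eps_str` 0.05--0.20,
#' `eps_sma` 0.30--0.50, `w_neg` 0.50--0.80, `m_r` 0.50--0.70.
#'
#' @param which `"HC"` or `"PD"`.
#' @param mode,subintervals Passed to [group_spec()].
#' @return A [group_spec()].
#' @export
parameter_space <- function(which = c("HC", "PD"),
                            mode = c("grid", "midpoint"), subintervals = 4L) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  if (which == "HC")
    group_spec("HC", eps_str = c(0.40, 0.70), eps_sma = c(0.50, 0.70),
               w_neg = c(0.00, 0.20), m_r = c(0.00, 0.20),
               mode = mode, subintervals = subintervals)
  else
    group_spec("PD", eps_str = c(0.05, 0.20), eps_sma = c(0.30, 0.50),
               w_neg = c(0.50, 0.80), m_r = c(0.50, 0.70),
               mode = mode, subintervals = subintervals)
}

#' The four single-point PD groups of the patient-group simulation
#'
#' PD_1: `eps_str` 0.10; PD_2: adds `w_neg` 0.65; PD_3: adds `m_r` 0.60;
#' PD_4: adds both.
#'
#' @return Named list of four [group_spec()] objects.
#' @export
pd_groups <- function() {
  list(
    PD_1 = group_spec("PD_1", eps_str = 0.10, w_neg = 0.00, m_r = 0.00),
    PD_2 = group_spec("PD_2", eps_str = 0.10, w_neg = 0.65, m_r = 0.00),
    PD_3 = group_spec("PD_3", eps_str = 0.10, w_neg = 0.00, m_r = 0.60),
    PD_4 = group_spec("PD_4", eps_str = 0.10, w_neg = 0.65, m_r = 0.60)
  )
}
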