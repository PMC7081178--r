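# Drivers reproducing the five simulation studies and the lagged
# GPi-sensorimotor control analysis.

#' Spearman rank correlation with large-sample p-value
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 (pairs with missing
#'   values are dropped).
#' @return `list(rho, p, n)`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Min-max normalisation to \[0, 1\]
#'
#' @param v Numeric vector with at least two distinct finite values.
#' @return `(v - min) / (max - min)`; constant vectors are undefined and
#'   return flagged `NA`s.
#' @export
minmax_normalise <- function(v) {
  r <- range(v, na.rm = TRUE, finite = TRUE)
  if (!is.finite(diff(r)) || diff(r) == 0) {
    warning("min-max normalisation undefined for a constant vector")
    return(rep(NA_real_, length(v)))
  }
  (v - r[1]) / diff(r)
}

.study_report <- function(id, ...) {
  structure(list(study = id, ...), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$study, "\n")
  for (nm in setdiff(names(x), c("study", "runs", "params"))) {
    cat("--", nm, "--\n")
    obj <- x[[nm]]
    if (is.data.frame(obj) || is.matrix(obj)) print(obj, digits = 3)
    else print(obj)
  }
  invisible(x)
}

#' Baseline performance at default parameters
#'
#' Sessions of 64 unambiguous cards under the criterion-10 schedule at
#' default parameters, summarised as mean (s.d.) of cards correctly sorted,
#' categories achieved, error counts and post-feedback response times.
#'
#' @param seed Master seed.
#' @param n_runs Number of sessions (default 100).
#' @param base Base parameters.
#' @return A `study_report` with elements `summary` (per-measure mean/s.d.)
#'   and `runs` (per-session measures).
#' @export
study1 <- function(seed = 1L, n_runs = 100L, base = wcst_params()) {
  runs <- run_group(NULL, n_runs = n_runs, base = base, seed = seed)
  .study_report("study1: defaults", summary = summarize_runs(runs),
                runs = runs, params = base)
}

#' Virtual Parkinson's-disease groups
#'
#' Four single-point groups sharing a reduced striatal learning rate
#' (`eps_str` 0.10) and differing in negative-reward sensitivity (`w_neg`)
#' and feedback memory (`m_r`); see [pd_groups()].
#'
#' @inheritParams study1
#' @return A `study_report` with a per-group summary table.
#' @export
study2 <- function(seed = 2L, n_runs = 100L, base = wcst_params()) {
  groups <- pd_groups()
  runs <- do.call(rbind, lapply(seq_along(groups), function(g)
    run_group(groups[[g]], n_runs = n_runs, base = base,
              seed = seed + g)))
  .study_report("study2: PD groups", summary = summarize_runs(runs),
                runs = runs, params = base)
}

#' Midpoint HC and PD groups: ERP proxy comparison
#'
#' Sessions at the midpoints of the healthy-control and Parkinson's
#' parameter spaces, with cycle traces; mean smoothed response-locked ERN
#' traces and ERN/PSP attenuation summaries per group.
#'
#' @inheritParams study1
#' @param n_per_group Virtual participants (sessions) per group.
#' @param smooth_window Smoothing window for the mean traces.
#' @return A `study_report` with `attenuation` (per-group means) and
#'   `traces` (per-group mean correct/incorrect ERN traces).
#' @export
study3 <- function(seed = 3L, n_per_group = 20L, base = wcst_params(),
                   smooth_window = 5L) {
  out_att <- list(); out_tr <- list()
  for (which in c("HC", "PD")) {
    sp <- parameter_space(which, mode = "midpoint")
    runs <- run_group(sp, n_runs = n_per_group, base = base,
                      seed = seed + match(which, c("HC", "PD")),
                      measure_erp = TRUE)
    # rebuild mean traces for the group from fresh sessions (same seeds)
    tr_c <- NULL; tr_i <- NULL; nc <- 0L; ni <- 0L
    for (rn in seq_len(n_per_group)) {
      pt <- group_points(sp)
      pp <- base
      pp$eps_str <- pt$eps_str[1]; pp$eps_sma <- pt$eps_sma[1]
      pp$w_neg <- pt$w_neg[1]; pp$m_r <- pt$m_r[1]
      run <- run_session(pp, seed = runs$seed[rn], record_traces = TRUE)
      tr <- ern_trace(run)
      if (!is.null(tr$correct)) {
        tr_c <- if (is.null(tr_c)) tr$correct * tr$n_correct
                else tr_c + tr$correct * tr$n_correct
        nc <- nc + tr$n_correct
      }
      if (!is.null(tr$incorrect)) {
        tr_i <- if (is.null(tr_i)) tr$incorrect * tr$n_incorrect
                else tr_i + tr$incorrect * tr$n_incorrect
        ni <- ni + tr$n_incorrect
      }
    }
    out_tr[[which]] <- list(
      cycles = seq(-20L, 40L),
      correct = smooth_signal(tr_c / nc, smooth_window),
      incorrect = smooth_signal(tr_i / ni, smooth_window))
    out_att[[which]] <- c(ern_att = mean(runs$ern_att, na.rm = TRUE),
                          psp_att = mean(runs$psp_att, na.rm = TRUE))
  }
  .study_report("study3: midpoint ERP comparison",
                attenuation = do.call(rbind, out_att), traces = out_tr)
}

#' Parameter-space grids: error counts versus ERP attenuation
#'
#' Evaluates the HC and PD parameter spaces on a `subintervals^4` grid
#' (midpoints of equal subintervals per dimension) with `runs_per_point`
#' sessions per grid point, computes per-session error counts and ERN/PSP
#' attenuations, and reports Spearman correlations between attenuations and
#' error frequencies within each space.
#'
#' @inheritParams study1
#' @param subintervals Subintervals per dimension (4 gives 256 points).
#' @param runs_per_point Sessions per grid point.
#' @param spaces Which spaces to run.
#' @return A `study_report` with `correlations` (one row per space x signal x
#'   error type with rho/p/n), `monotonicity` (sign-consistency of binned
#'   means, a scatter-inspection surrogate) and `runs`.
#' @export
study4 <- function(seed = 4L, subintervals = 4L, runs_per_point = 10L,
                   base = wcst_params(), spaces = c("HC", "PD")) {
  all_runs <- list()
  cors <- list()
  mono <- list()
  for (which in spaces) {
    sp <- parameter_space(which, mode = "grid", subintervals = subintervals)
    runs <- run_group(sp, n_runs = runs_per_point, base = base,
                      seed = seed + 17L * match(which, c("HC", "PD")),
                      measure_erp = TRUE)
    all_runs[[which]] <- runs
    for (sig in c("ern_att", "psp_att")) {
      for (err in c("PE", "SL", "IE")) {
        ct <- spearman_rho(runs[[sig]], runs[[err]])
        cors[[length(cors) + 1L]] <- data.frame(
          space = which, signal = sig, error = err,
          rho = ct$rho, p = ct$p, n = ct$n,
          stars = if (is.na(ct$p)) "" else if (ct$p < .001) "**"
                  else if (ct$p < .05) "*" else "")
        mono[[length(mono) + 1L]] <- data.frame(
          space = which, signal = sig, error = err,
          monotone = .binned_monotone(runs[[sig]], runs[[err]]))
      }
    }
  }
  .study_report("study4: grid correlations",
                correlations = do.call(rbind, cors),
                monotonicity = do.call(rbind, mono),
                runs = do.call(rbind, all_runs))
}

# sign-consistency of differences of binned means: TRUE when all successive
# differences of mean y over x-bins share one sign
.binned_monotone <- function(x, y, bins = 5L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < bins * 2L) return(NA)
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(qs) < 3L) return(NA)
  bin <- cut(x, qs, include.lowest = TRUE)
  m <- tapply(y, bin, mean)
  d <- diff(m[!is.na(m)])
  d <- d[d != 0]
  if (!length(d)) return(TRUE)
  all(d > 0) || all(d < 0)
}

#' Parameter sweeps of the ERP proxies
#'
#' Sweeps one learning parameter over \[0, 1\] in steps of `step` crossed
#' with three fixed values of a companion parameter, with
#' `runs_per_point` sessions per point; reports per-point mean ERN and PSP
#' attenuation with standard errors and min-max-normalised curves. Points
#' where the model never shifts schema have undefined PSP and are flagged.
#'
#' @inheritParams study1
#' @param runs_per_point Sessions per sweep point.
#' @param step Sweep step size.
#' @param sweeps Which sweeps to run: `eps_str` (x three `eps_sma` values),
#'   `eps_sma` and `w_neg` (each x three `eps_str` values).
#' @return A `study_report`; element `curves` is a data frame with columns
#'   `sweep`, `companion`, `value`, `ern_att`, `ern_se`, `psp_att`,
#'   `psp_se`, `psp_defined`, `ern_norm`, `psp_norm`.
#' @export
study5 <- function(seed = 5L, runs_per_point = 20L, step = 0.05,
                   base = wcst_params(),
                   sweeps = c("eps_str", "eps_sma", "w_neg")) {
  companions <- list(eps_str = c("eps_sma", 0.2, 0.5, 0.8),
                     eps_sma = c("eps_str", 0.2, 0.5, 0.8),
                     w_neg = c("eps_str", 0.2, 0.5, 0.8))
  grid_vals <- seq(0, 1, by = step)
  rows <- list()
  sidx <- 0L
  for (sw in sweeps) {
    comp_name <- companions[[sw]][1]
    comp_vals <- as.numeric(companions[[sw]][-1])
    for (cv in comp_vals) {
      for (v in grid_vals) {
        sidx <- sidx + 1L
        pp <- base
        pp[[sw]] <- v
        pp[[comp_name]] <- cv
        g <- group_spec(paste0(sw, "=", v, ",", comp_name, "=", cv),
                        eps_str = pp$eps_str, eps_sma = pp$eps_sma,
                        w_neg = pp$w_neg, m_r = pp$m_r)
        runs <- run_group(g, n_runs = runs_per_point, base = base,
                          seed = seed + sidx, measure_erp = TRUE)
        se <- function(x) {
          x <- x[is.finite(x)]
          if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
        }
        rows[[sidx]] <- data.frame(
          sweep = sw, companion = cv, value = v,
          ern_att = mean(runs$ern_att, na.rm = TRUE), ern_se = se(runs$ern_att),
          psp_att = mean(runs$psp_att, na.rm = TRUE), psp_se = se(runs$psp_att),
          psp_defined = mean(is.finite(runs$psp_att)))
      }
    }
  }
  curves <- do.call(rbind, rows)
  curves$ern_norm <- NA_real_
  curves$psp_norm <- NA_real_
  for (sw in unique(curves$sweep)) {
    i <- curves$sweep == sw
    curves$ern_norm[i] <- suppressWarnings(minmax_normalise(curves$ern_att[i]))
    curves$psp_norm[i] <- suppressWarnings(minmax_normalise(curves$psp_att[i]))
  }
  .study_report("study5: parameter sweeps", curves = curves)
}

#' Lagged correlation between GPi and sensorimotor cortical output
#'
#' For each value of the cortical learning rate `eps_sma`, runs sessions
#' with cycle traces and computes, per sensorimotor schema and per lag of
#' 1--10 cycles, the Spearman correlation between GPi output at cycle t and
#' cortical output at cycle t + lag; reports the extreme
#' (largest-magnitude, sign-preserved) coefficient per `eps_sma` value.
#' A near-constant, moderately strong negative value across the whole
#' `eps_sma` range indicates that BG selection operates independently of
#' cortical conflict adaptation.
#'
#' @param seed Master seed.
#' @param eps_sma_grid Values of `eps_sma` to evaluate.
#' @param lags Lags in cycles.
#' @param n_runs Sessions per value.
#' @param base Base parameters.
#' @return Data frame with `eps_sma`, `rho` (extreme lagged coefficient),
#'   `lag` and `schema` at which the extreme occurs.
#' @export
gpi_sma_lagged_correlation <- function(seed = 9L,
                                       eps_sma_grid = seq(0, 1, by = 0.05),
                                       lags = 1:10, n_runs = 20L,
                                       base = wcst_params()) {
  out <- vector("list", length(eps_sma_grid))
  for (k in seq_along(eps_sma_grid)) {
    pp <- base
    pp$eps_sma <- eps_sma_grid[k]
    # mean correlation over sessions, per (schema, lag)
    acc <- matrix(0, 4, length(lags))
    for (rn in seq_len(n_runs)) {
      run <- run_session(pp, seed = ((as.numeric(seed) + 37 * k) * 1009 + rn) %%
                           .Machine$integer.max,
                         record_traces = TRUE)
      gpi <- run$traces$gpi_sma
      smao <- run$traces$sma
      T <- nrow(gpi)
      if (T <= max(lags) + 2L) stop("trace shorter than maximum lag")
      for (li in seq_along(lags)) {
        L <- lags[li]
        for (s in 1:4) {
          acc[s, li] <- acc[s, li] +
            cor(gpi[1:(T - L), s], smao[(1 + L):T, s], method = "spearman")
        }
      }
    }
    acc <- acc / n_runs
    idx <- which(abs(acc) == max(abs(acc)), arr.ind = TRUE)[1, ]
    out[[k]] <- data.frame(eps_sma = eps_sma_grid[k],
                           rho = acc[idx[1], idx[2]],
                           schema = idx[1], lag = lags[idx[2]])
  }
  do.call(rbind, out)
}
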