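test_that("absmax preserves sign and breaks ties at the lowest index", {
  expect_equal(absmax(c(0.2, -0.5, 0.3)), -0.5)
  expect_equal(absmax(c(0, 0, 0)), 0)
  expect_equal(absmax(c(0.4, -0.4)), 0.4)
  expect_equal(absmax(-0.7), -0.7)
  expect_error(absmax(numeric(0)), "empty")
})

test_that("proxy signals are the extreme one-step output changes", {
  m <- matrix(0.3, nrow = 10, ncol = 4)
  expect_equal(ern_signal(m), rep(0, 10))
  expect_equal(spp_trace(m[, 1:3]), rep(0, 10))
  # single one-step jump of +0.3 in one schema
  m[6:10, 2] <- 0.6
  sig <- ern_signal(m)
  expect_equal(sig[6], -0.3, tolerance = 1e-12)
  expect_equal(sig[-6], rep(0, 9))
  sp <- spp_trace(m[, 1:3])
  expect_equal(sp[6], 0.3, tolerance = 1e-12)
  # bounded by the largest one-step change
  set.seed(2)
  r <- matrix(runif(60), 15, 4)
  expect_true(all(abs(ern_signal(r)) <= max(abs(diff(r))) + 1e-12))
})

test_that("smoothing is a centred moving average with shrunken endpoints", {
  x <- c(rep(0, 10), 1, rep(0, 10))
  s <- smooth_signal(x, 5)
  expect_equal(s[9:13], rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sum(s), sum(x), tolerance = 1e-12)
  expect_equal(smooth_signal(x, 1), x)
  expect_equal(smooth_signal(rep(2, 7), 5), rep(2, 7))
  expect_error(smooth_signal(x, 4), "odd")
})

test_that("attenuation summaries behave on constructed sessions", {
  r <- run_session(seed = 5, record_traces = TRUE)
  tr <- ern_trace(r)
  expect_equal(length(tr$cycles), 61L)
  expect_true(tr$n_correct > 0 && tr$n_incorrect > 0)
  expect_true(is.finite(ern_attenuation(r)))
  expect_true(is.finite(psp_attenuation(r)))

  # shift labels mark post-negative-feedback schema changes
  lab <- shift_labels(r$log)
  expect_true(all(lab %in% c("shift", "post_shift", "repeat")))
  expect_true(sum(lab == "shift") >= 1)

  # a session whose trials are all correct has no incorrect trials: the ERN
  # component is undefined and flagged
  fake <- r
  fake$log$feedback[] <- 1L
  fake$log$error_class[] <- "correct"
  expect_warning(out <- ern_attenuation(fake), "undefined")
  expect_true(is.na(out))
  # and without schema shifts the PSP is undefined
  fake2 <- r
  fake2$log$selected_cognitive[] <- 1L
  expect_warning(out2 <- psp_attenuation(fake2), "no schema shifts")
  expect_true(is.na(out2))
})

test_that("ERN shape criteria hold on default simulations", {
  # pooled response-locked traces over several sessions
  acc_c <- 0; acc_i <- 0; nc <- 0; ni <- 0; atts <- c()
  for (s in 1:8) {
    r <- run_session(seed = 400 + s, record_traces = TRUE)
    tr <- ern_trace(r)
    acc_c <- acc_c + tr$correct * tr$n_correct; nc <- nc + tr$n_correct
    acc_i <- acc_i + tr$incorrect * tr$n_incorrect; ni <- ni + tr$n_incorrect
    atts <- c(atts, ern_attenuation(r))
  }
  mc <- acc_c / nc; mi <- acc_i / ni
  off <- seq(-20, 40)
  iti <- wcst_params()$iti_cycles
  masked <- (off <= 0 | off > 8) & !(off > iti & off <= iti + 8)
  # (i) the outcome-dependent deflection is larger on incorrect trials
  expect_lt(mean(atts), 0)
  expect_gt(max(abs(mi[masked])), max(abs(mc[masked])))
  # (ii) the incorrect-trial signal dips below baseline just before the
  # response and peaks (much higher) after it
  expect_lt(min(mi[off >= -10 & off <= 0]), 0)
  expect_gt(max(mi[masked & off > 0]), max(abs(mi[off >= -10 & off <= 0])))
  # the extreme deflection lies after the response
  expect_gt(off[masked][which.max(abs(mi[masked]))], 0)
})

test_that("per-trial ERN magnitude tracks response conflict", {
  peaks <- c(); confl <- c()
  for (s in 1:6) {
    r <- run_session(seed = 950 + s, record_traces = TRUE)
    tr <- ern_trace(r)
    iti <- r$params$iti_cycles
    keep <- (tr$cycles <= 0 | tr$cycles > 8) &
      !(tr$cycles > iti & tr$cycles <= iti + 8)
    peaks <- c(peaks, apply(abs(tr$per_trial[, keep] - tr$baseline), 1, max))
    log <- r$log[r$log$error_class != "omission", ]
    ok <- log$response_cycle - 30 >= 1 &
      log$response_cycle + 40 <= nrow(r$traces$sma)
    log <- log[ok, ]
    confl <- c(confl, apply(r$traces$sma[log$response_cycle, , drop = FALSE],
                            1, function(o) prod(1 + r$params$eps_sma + o)))
  }
  rho <- spearman_rho(peaks, confl)
  expect_gt(abs(rho$rho), 0.15)
  expect_lt(rho$p, 0.01)
})

test_that("SPP peaks are higher on shift trials than on repeats", {
  diffs <- c()
  for (s in 1:6) {
    r <- run_session(seed = 500 + s, record_traces = TRUE)
    sig <- spp_trace(r$traces$pfc)
    log <- r$log
    lab <- shift_labels(log)
    n <- nrow(log)
    from <- c(log$onset_cycle[1], log$response_cycle[-n] + 1L)
    peak <- vapply(seq_len(n), function(t)
      max(sig[from[t]:log$response_cycle[t]]), numeric(1))
    if (any(lab == "shift") && any(lab == "repeat"))
      diffs <- c(diffs, mean(peak[lab == "shift"]) -
                   mean(peak[lab == "repeat"]))
  }
  expect_true(all(diffs > 0))
})
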