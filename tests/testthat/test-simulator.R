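test_that("sessions are deterministic given a seed", {
  a <- run_session(n_trials = 16, seed = 123)
  b <- run_session(n_trials = 16, seed = 123)
  expect_identical(a$log, b$log)
  expect_identical(a$summary, b$summary)
  c <- run_session(n_trials = 16, seed = 124)
  expect_false(identical(a$log$response, c$log$response))
})

test_that("the pure-R reference engine reproduces the compiled engine", {
  a <- run_session(n_trials = 6, seed = 77, record_traces = TRUE,
                   engine = "cpp")
  b <- run_session(n_trials = 6, seed = 77, record_traces = TRUE,
                   engine = "r")
  expect_equal(a$log, b$log)
  expect_equal(a$beta_str, b$beta_str, tolerance = 1e-12)
  expect_equal(a$alpha_sma, b$alpha_sma, tolerance = 1e-12)
  expect_lt(max(abs(a$traces$sma - b$traces$sma)), 1e-12)
  expect_lt(max(abs(a$traces$pfc - b$traces$pfc)), 1e-12)
  expect_lt(max(abs(a$traces$gpi_sma - b$traces$gpi_sma)), 1e-12)
})

test_that("session accounting identity holds", {
  for (seed in c(3, 14, 159)) {
    r <- run_session(seed = seed)
    s <- r$summary
    expect_equal(sum(s[c("cards_correct", "PE", "SL", "IE", "other_error",
                         "omissions")]), 64)
  }
})

test_that("responses follow an established rule with high probability", {
  # once a rule has been acquired (criterion run in progress), responses are
  # overwhelmingly consistent with it
  hits <- 0; tot <- 0
  for (seed in 1:5) {
    r <- run_session(seed = seed)
    log <- r$log
    streak <- 0
    for (t in seq_len(nrow(log))) {
      if (streak >= 3 && streak <= 8) {  # rule cannot have just switched
        tot <- tot + 1
        if (!is.na(log$applied_rule[t]) &&
            log$applied_rule[t] == log$active_rule[t]) hits <- hits + 1
      }
      fb <- log$feedback[t]
      streak <- if (!is.na(fb) && fb > 0) streak + 1 else 0
    }
  }
  expect_gt(hits / tot, 0.9)
})

test_that("rule schedule modes and trial counts are respected", {
  r <- run_session(n_trials = 30, seed = 5, schedule_mode = "random_run")
  expect_equal(nrow(r$log), 30L)
  expect_true(r$categories >= 0)
  expect_error(run_session(n_trials = 0, seed = 1), "n_trials")
})

test_that("group runs tag parameter points and summarise them", {
  g <- group_spec("toy", eps_str = c(0.2, 0.4), mode = "grid",
                  subintervals = 2)
  pts <- group_points(g)
  expect_equal(nrow(pts), 16L)  # 2^4 grid
  expect_equal(sort(unique(pts$eps_str)), c(0.25, 0.35))

  mid <- group_spec("m", eps_str = c(0.2, 0.4), mode = "midpoint")
  expect_equal(group_points(mid)$eps_str, 0.3)

  res <- run_group(group_spec("fix", eps_str = 0.4), n_runs = 3, seed = 5,
                   n_trials = 16)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$eps_str == 0.4))
  summ <- summarize_runs(res)
  expect_equal(summ$mean_cards_correct, mean(res$cards_correct))
  expect_equal(summ$sd_PE, sd(res$PE))
  one <- summarize_runs(res[1, ])
  expect_equal(one$sd_PE, 0)
  expect_true(attr(one, "single_run"))
  expect_error(summarize_runs(res[0, ]), "no results")
})

test_that("parameter set validates overrides and records them", {
  p <- wcst_params(eps_str = 0.1, w_neg = 0.65)
  expect_equal(p$eps_str, 0.1)
  expect_setequal(attr(p, "overrides"), c("eps_str", "w_neg"))
  expect_error(wcst_params(nonsense = 1), "unknown parameter")
})

test_that("response time decreases in the area scale", {
  rt_at <- function(scale) {
    pp <- wcst_params(area_scale = scale)
    mean(run_session(pp, n_trials = 20, seed = 8)$log$rt_cycles)
  }
  expect_gt(rt_at(20), rt_at(33))
  expect_gt(rt_at(33), rt_at(60))
})
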