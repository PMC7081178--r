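test_that("logistic saturation matches closed form", {
  expect_equal(logistic(0.5, 0.5, 8), 0.5, tolerance = 1e-9)
  expect_equal(logistic(1.0, 0.5, 8), 1 / (1 + exp(-4)), tolerance = 1e-9)
  expect_equal(logistic(0.0, 0.5, 8), 1 / (1 + exp(4)), tolerance = 1e-9)
  # symmetry about the threshold
  for (d in c(0.1, 0.3, 0.7))
    expect_equal(logistic(0.5 + d, 0.5, 8) + logistic(0.5 - d, 0.5, 8), 1,
                 tolerance = 1e-12)
})

test_that("cognitive layer update matches hand evaluation", {
  p <- wcst_params()
  st <- list(a = 0, o = 0)
  st <- step_cognitive(st, o_thal = 0, p)
  expect_equal(st$a, 0.30, tolerance = 1e-12)
  expect_equal(st$o, logistic(0.30, 0.5, 8), tolerance = 1e-12)
  # fixed point with quiescent thalamus
  for (k in 1:200) st <- step_cognitive(st, 0, p)
  expect_equal(st$a, 0.75, tolerance = 1e-9)
  expect_equal(st$o, logistic(0.75, 0.5, 8), tolerance = 1e-9)
  # fully inhibited thalamus
  st <- list(a = 0, o = 0)
  for (k in 1:200) st <- step_cognitive(st, -1, p)
  expect_equal(st$a, -0.25, tolerance = 1e-9)
  expect_equal(st$o, logistic(-0.25, 0.5, 8), tolerance = 1e-9)
})

test_that("smoothing recurrence converges geometrically at rate delta", {
  p <- wcst_params()
  u <- 0.75
  a <- 0.1
  for (t in 1:12) {
    a_closed <- u + p$delta^t * (0.1 - u)
    a <- p$delta * a + (1 - p$delta) * u
    expect_equal(a, a_closed, tolerance = 1e-12)
  }
})

test_that("sensorimotor layer routes top-down input by card and rule", {
  p <- wcst_params()
  card <- wcst_card("red", "cross", 2)
  routing <- rule_routing(card)
  expect_equal(dim(routing), c(4L, 3L))
  expect_equal(unname(routing[1, 1]), 1)  # colour -> target 1
  expect_equal(unname(routing[3, 2]), 1)  # shape  -> target 3
  expect_equal(unname(routing[2, 3]), 1)  # number -> target 2
  expect_equal(sum(routing), 3)

  st <- list(a = rep(0, 4), o = rep(0, 4))
  o_ctx <- c(0.9, 0, 0)
  stim <- c(0.5, 0, 0, 0)
  out <- step_sensorimotor(st, o_ctx, selected_mask = c(TRUE, FALSE, FALSE),
                           stim = stim, o_thal = rep(0, 4), p, routing)
  expect_equal(out$a[1], 0.4 * (0.4 * 0.9 + 0.5), tolerance = 1e-12)
  expect_equal(out$o[1], logistic(0.344, 0.4, 8), tolerance = 1e-9)
  # non-selected cognitive schemas pass nothing down
  out2 <- step_sensorimotor(st, o_ctx, selected_mask = rep(FALSE, 3),
                            stim = stim, o_thal = rep(0, 4), p, routing)
  expect_equal(out2$a, 0.4 * stim, tolerance = 1e-12)
  expect_error(step_sensorimotor(st, c(1, 0), rep(TRUE, 2), stim,
                                 rep(0, 4), p, routing),
               "dimension mismatch")
})

test_that("selection requires both thresholds, ties go to higher output", {
  th <- selection_thresholds(area_scale = 1)
  st <- list(o = c(0.6, 0.2, 0.2), area = c(5000, 5000, 5000))
  expect_equal(check_selection(st, th, 4000), 1L)
  st$area <- c(100, 5000, 5000)
  expect_true(is.na(check_selection(st, th, 4000)))
  st <- list(o = c(0.8, 0.6, 0.1), area = c(5000, 5000, 5000))
  expect_equal(check_selection(st, th, 4000), 1L)
  st <- list(o = c(0.6, 0.8, 0.1), area = c(5000, 5000, 5000))
  expect_equal(check_selection(st, th, 4000), 2L)
})

test_that("conflict-driven gain matches hand values and is monotone", {
  expect_equal(update_alpha_sma(rep(0, 4), 0.5, 0), 1.5^4, tolerance = 1e-9)
  expect_equal(update_alpha_sma(rep(1, 4), 0.5, 0), 2.5^4, tolerance = 1e-9)
  base <- update_alpha_sma(c(0.5, 0.5, 0.5, 0.5), 0.5, 0)
  # increasing any single output increases the gain; eps too
  for (i in 1:4) {
    o <- rep(0.5, 4); o[i] <- 0.9
    expect_gt(update_alpha_sma(o, 0.5, 0), base)
  }
  expect_gt(update_alpha_sma(rep(0.5, 4), 0.7, 0), base)
  # peaks when all activations peak
  set.seed(3)
  rand <- replicate(50, update_alpha_sma(runif(4), 0.5, 0))
  expect_true(all(rand <= update_alpha_sma(rep(1, 4), 0.5, 0)))
})
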