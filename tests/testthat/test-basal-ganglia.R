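test_that("nucleus updates match hand evaluations", {
  p <- wcst_params()
  w <- bg_weights()
  # striatum: copy of cortical output through the adapted threshold
  st <- step_striatum(list(a = 0, o = 0), 0.5, beta_str = 0.5, p)
  expect_equal(st$a, 0.2, tolerance = 1e-12)
  expect_equal(st$o, logistic(0.2, 0.5, 8.5), tolerance = 1e-9)
  st2 <- step_striatum(list(a = 0, o = 0), 0.5, beta_str = 0.2, p)
  expect_equal(st2$o, 0.5, tolerance = 1e-9)  # a lands on the threshold
  # monotone decreasing in the threshold at fixed activation
  betas <- seq(0.1, 0.9, by = 0.1)
  outs <- vapply(betas, function(b)
    step_striatum(list(a = 0, o = 0), 0.5, b, p)$o, numeric(1))
  expect_true(all(diff(outs) < 0))

  # subthalamic nucleus
  stn <- step_stn(list(a = 0, o = 0), 0.5, 0.3, w, p)
  expect_equal(stn$a, 0.4 * (1.2 * 0.5 - 0.3), tolerance = 1e-12)
  expect_equal(stn$o, logistic(0.12, 0.3, 8), tolerance = 1e-9)
  stn0 <- step_stn(list(a = 0, o = 0), 0.5, 0, w, p)
  expect_equal(stn0$a, 0.4 * 0.6, tolerance = 1e-12)
  gpe_levels <- seq(0, 1, by = 0.25)
  us <- vapply(gpe_levels, function(g)
    step_stn(list(a = 0, o = 0), 0.5, g, w, p)$a, numeric(1))
  expect_true(all(diff(us) < 0))

  # GPe: diffuse STN excitation, channel-wise D2 inhibition
  gpe <- step_gpe(list(a = rep(0, 3), o = rep(0, 3)),
                  o_stn = c(0.2, 0.2, 0.2), o_strd2_prev = rep(0, 3), w, p)
  expect_equal(gpe$a, rep(0.4 * 0.54, 3), tolerance = 1e-12)
  gpe2 <- step_gpe(list(a = rep(0, 3), o = rep(0, 3)),
                   o_stn = rep(0, 3), o_strd2_prev = c(1, 0, 0), w, p)
  expect_equal(gpe2$a[1], 0.4 * (-1), tolerance = 1e-12)

  # GPi: tonic activity at rest, shut down by D1
  expect_equal(steady_nucleus(0, 0.25, 8), logistic(0, 0.25, 8),
               tolerance = 1e-9)
  expect_equal(logistic(0, 0.25, 8), 0.119202922, tolerance = 1e-8)
  expect_equal(steady_nucleus(-0.8, 0.25, 8), logistic(-0.8, 0.25, 8),
               tolerance = 1e-9)
  expect_lt(logistic(-0.8, 0.25, 8), 3e-4)

  # thalamus: negated logistic in (-1, 0)
  th <- list(a = 0, o = 0)
  for (k in 1:300) th <- step_thalamus(th, 0.45, p)
  expect_equal(th$o, -0.5, tolerance = 1e-9)
  th <- list(a = 0, o = 0)
  for (k in 1:300) th <- step_thalamus(th, 0, p)
  expect_equal(th$o, -logistic(0, 0.45, 8), tolerance = 1e-9)
  gpi_levels <- seq(0, 1, by = 0.2)
  th_outs <- vapply(gpi_levels, function(g) {
    th <- list(a = 0, o = 0)
    for (k in 1:300) th <- step_thalamus(th, g, p)
    th$o
  }, numeric(1))
  expect_true(all(diff(th_outs) < 0))
  expect_true(all(th_outs > -1 & th_outs < 0))
})

test_that("feature match and striatal threshold update follow the learning rule", {
  p <- wcst_params()
  card <- wcst_card("red", "cross", 2)
  # response to target 1 applies colour: the colour channel matches
  expect_equal(feature_match(card, 1, "colour", p), 1)
  expect_equal(feature_match(card, 1, "shape", p), -1)
  p2 <- wcst_params(w_neg = 0.65)
  expect_equal(feature_match(card, 1, "shape", p2), 0.3, tolerance = 1e-9)
  # feedback memory carries the previous trial's signed match forward
  p3 <- wcst_params(m_r = 0.6)
  expect_equal(feature_match(card, 1, "shape", p3, f_prev = 1, r_prev = -1),
               -1 + 0.6, tolerance = 1e-9)

  # prediction error, both forms
  expect_equal(reward_prediction_error(1, 1, 0.9), 0.1, tolerance = 1e-12)
  expect_equal(reward_prediction_error(1, 0.9, 0.9), 0, tolerance = 1e-12)
  expect_equal(reward_prediction_error(-1, -1, 0.9, form = "parenthesized"),
               1.9, tolerance = 1e-12)
  expect_equal(reward_prediction_error(-1, 1, 0.9), -1.9, tolerance = 1e-12)

  # threshold update and clipping
  expect_equal(update_beta_str(0.5, 0.4, 0.1, 0), 0.46, tolerance = 1e-12)
  expect_equal(update_beta_str(0.5, 0.4, 0, 0), 0.5, tolerance = 1e-12)
  expect_equal(update_beta_str(0.05, 0.4, 1.9, 0), 0, tolerance = 1e-12)
  expect_equal(update_beta_str(0.9, 0.4, -1.5, 0), 1, tolerance = 1e-12)
})

test_that("threshold stays in [0,1] under long random update sequences", {
  set.seed(11)
  for (rep in 1:5) {
    b <- runif(1)
    for (k in 1:2000) {
      b <- update_beta_str(b, runif(1), runif(1, -2, 2), runif(1, -0.1, 0.1))
      if (b < 0 || b > 1) break
    }
    expect_true(b >= 0 && b <= 1)
  }
})

test_that("standalone layer selects the channel with the largest input", {
  # steady-state GPi is lowest for the max-input channel; equal inputs give
  # equal outputs; the margin grows with the input difference
  s <- bg_layer_steady(c(0.8, 0.4, 0.4))
  expect_equal(which.min(s$gpi$o), 1L)
  expect_equal(s$gpi$o[2], s$gpi$o[3], tolerance = 1e-9)

  sym <- bg_layer_steady(c(0.5, 0.5, 0.5))
  expect_equal(sym$gpi$o, rep(sym$gpi$o[1], 3), tolerance = 1e-9)

  margins <- vapply(c(0.5, 0.65, 0.8), function(s1) {
    st <- bg_layer_steady(c(s1, 0.4, 0.4))
    st$gpi$o[2] - st$gpi$o[1]
  }, numeric(1))
  expect_true(all(margins > 0))
  expect_true(all(diff(margins) > 0))
})

test_that("lowering a channel's striatal threshold disinhibits it", {
  p <- wcst_params()
  lo <- bg_layer_steady(c(0.5, 0.5, 0.5), beta_str = c(0.2, 0.5, 0.5))
  hi <- bg_layer_steady(c(0.5, 0.5, 0.5), beta_str = c(0.5, 0.5, 0.5))
  expect_gt(lo$d1$o[1], hi$d1$o[1])
  expect_lt(lo$gpi$o[1], hi$gpi$o[1])
  expect_gt(lo$thal$o[1], hi$thal$o[1])  # less negative: disinhibited
})
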