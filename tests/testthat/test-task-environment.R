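test_that("deck matches the brute-force enumeration and is unambiguous", {
  deck <- wcst_deck()
  expect_equal(nrow(deck), 24L)
  expect_equal(card_key(deck), card_key(enumerate_deck_bruteforce()))
  # every deck card matches exactly three targets, and its three feature
  # dimensions form an ordered triple of distinct target indices
  triples <- deck[, c("t_colour", "t_shape", "t_number")]
  expect_true(all(apply(triples, 1, function(x) length(unique(x)) == 3L)))
  expect_equal(nrow(unique(triples)), 24L)
  for (i in seq_len(nrow(deck))) {
    mv <- stimulus_match_vector(deck[i, ])
    expect_equal(sum(mv), 3L)
  }
  # the worked example: two red crosses match targets 1 (colour), 2 (number)
  # and 3 (shape) but not 4
  ex <- wcst_card("red", "cross", 2)
  expect_equal(stimulus_match_vector(ex), c(1L, 1L, 1L, 0L))
})

test_that("applied rule is unique for deck cards and NA otherwise", {
  ex <- wcst_card("red", "cross", 2)
  expect_equal(applied_rule(ex, 1), "colour")
  expect_equal(applied_rule(ex, 2), "number")
  expect_equal(applied_rule(ex, 3), "shape")
  expect_true(is.na(applied_rule(ex, 4)))
  deck <- wcst_deck()
  for (i in seq_len(nrow(deck))) {
    card <- deck[i, ]
    for (resp in which(stimulus_match_vector(card) == 1L)) {
      rule <- applied_rule(card, resp)
      expect_false(is.na(rule))
      expect_equal(rule_target(card, rule), resp)
    }
  }
})

test_that("trial sequences are shuffled deck copies, deterministic by seed", {
  s1 <- build_trial_sequence(64, seed = 5)
  s2 <- build_trial_sequence(64, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 64L)
  # a 24-card sequence is a permutation of the full deck
  perm <- build_trial_sequence(24, seed = 9)
  expect_equal(card_key(perm), card_key(wcst_deck()))
  # each consecutive block of 24 cards within a longer sequence is too
  long <- build_trial_sequence(48, seed = 2)
  expect_equal(card_key(long[1:24, ]), card_key(wcst_deck()))
  expect_equal(card_key(long[25:48, ]), card_key(wcst_deck()))
  expect_error(build_trial_sequence(0), "n_trials")
})

test_that("feedback follows the active rule and switches at criterion", {
  set.seed(1)
  sch <- new_rule_schedule("criterion", criterion_length = 10,
                           active_rule = "colour")
  ex <- wcst_card("red", "cross", 2)
  fb <- give_feedback(ex, 1, sch)   # colour applied under colour
  expect_equal(fb$feedback, 1L)
  fb2 <- give_feedback(ex, 3, sch)  # shape applied under colour
  expect_equal(fb2$feedback, -1L)
  # ten consecutive correct sorts complete a category and switch the rule
  sch <- new_rule_schedule("criterion", criterion_length = 10,
                           active_rule = "colour")
  for (k in 1:10) {
    out <- give_feedback(ex, 1, sch)
    expect_equal(out$feedback, 1L)
    sch <- out$schedule
  }
  expect_equal(sch$categories, 1L)
  expect_true(sch$active_rule != "colour")
  expect_equal(sch$run_counter, 0L)
})

test_that("random-run lengths are uniform on {2,3,4,5} with median 3.5", {
  set.seed(42)
  draws <- replicate(10000, {
    s <- new_rule_schedule("random_run", active_rule = "colour")
    s$run_target
  })
  expect_true(all(draws %in% 2:5))
  # distribution median 3.5: mass splits evenly around it, mean matches,
  # frequencies are uniform
  expect_lt(abs(mean(draws <= 3) - 0.5), 0.02)
  expect_lt(abs(mean(draws) - 3.5), 0.05)
  expect_true(all(abs(table(draws) / 10000 - 0.25) < 0.02))
})

test_that("error taxonomy classifies the canonical fixtures", {
  # PE: previously successful rule repeated despite negative feedback
  log <- make_log(c("colour", "colour", "colour"), c(1, -1, -1))
  expect_equal(classify_errors(log), c("correct", "other_error", "PE"))
  # SL: rule change despite positive feedback on the previous trial
  log <- make_log(c("colour", "shape"), c(1, -1))
  expect_equal(classify_errors(log)[2], "SL")
  # IE: switch, after negative feedback, to a rule punished two trials back
  log <- make_log(c("shape", "colour", "shape"), c(-1, -1, -1))
  expect_equal(classify_errors(log)[3], "IE")
  # returning to the previously successful rule takes PE precedence over IE
  log <- make_log(c("colour", "colour", "shape", "colour"), c(1, -1, -1, -1))
  expect_equal(classify_errors(log), c("correct", "other_error", "other_error", "PE"))
  # positive-feedback exclusion only counts as IE when enabled
  log <- make_log(c("colour", "colour", "shape"), c(1, -1, -1))
  expect_equal(classify_errors(log)[3], "other_error")
  expect_equal(classify_errors(log, ie_positive_exclusion = TRUE)[3], "IE")
  # omissions and out-of-range access
  log <- make_log(c("colour", NA), c(1, NA))
  expect_equal(classify_errors(log)[2], "omission")
  expect_error(classify_error(log, 3), "out of range")
})

test_that("classification is total on negative-feedback trials", {
  set.seed(7)
  rules <- c("colour", "shape", "number")
  for (rep in 1:20) {
    n <- 30
    log <- make_log(sample(rules, n, replace = TRUE),
                    sample(c(1, -1), n, replace = TRUE))
    cls <- classify_errors(log)
    expect_true(all(cls[log$feedback < 0] %in%
                      c("PE", "SL", "IE", "other_error")))
    expect_true(all(cls[log$feedback > 0] == "correct"))
  }
})

test_that("categories count completed criterion runs", {
  fb <- c(rep(1, 10), -1, rep(1, 10), -1, rep(1, 10), -1)
  expect_equal(count_categories(data.frame(feedback = fb)), 3L)
  expect_equal(count_categories(data.frame(feedback = rep(-1, 20))), 0L)
  expect_equal(count_categories(data.frame(feedback = rep(1, 25))), 2L)
})
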