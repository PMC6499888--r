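# Detection-window scoring, scrambled chance level, grouping, contrasts.

test_that("the one-and-only-one-press rule is applied to the window", {
  sched <- fake_schedule(c(10000, 60000))

  # single press 500 ms after the second presentation: detected, RT = 500
  sc <- score_block(sched, 10500)
  expect_true(sc$detected[1])
  expect_equal(sc$rt_ms[1], 500)
  expect_identical(sc$n_in_window[1], 1L)

  # two presses in the same window: not detected, n = 2
  sc2 <- score_block(sched, c(10500, 11000))
  expect_false(sc2$detected[1])
  expect_identical(sc2$n_in_window[1], 2L)
  expect_true(is.na(sc2$rt_ms[1]))

  # press at offset 100 < 200: outside the window
  sc3 <- score_block(sched, 10100)
  expect_false(sc3$detected[1])
  expect_identical(sc3$n_in_window[1], 0L)

  # boundary: offsets exactly 200 and 2500 are outside (open interval)
  sc4 <- score_block(sched, c(10200, 12500))
  expect_identical(sc4$n_in_window[1], 0L)

  expect_error(score_block(sched, c(11000, 10500)), "sorted")
})

test_that("a press inside two overlapping windows counts for the earlier sequence", {
  sched <- fake_schedule(c(10000, 11000))   # windows overlap from 11200
  sc <- score_block(sched, 11500)
  expect_true(sc$detected[1])
  expect_false(sc$detected[2])
  expect_identical(sc$n_in_window, c(1L, 0L))
})

test_that("score_block matches the brute-force press-by-window scan", {
  set.seed(404)
  for (rep in 1:200) {
    n_seq <- sample(1:8, 1)
    t2 <- sort(runif(n_seq, 0, 40000))          # windows may overlap
    k <- sample(0:10, 1)
    presses <- sort(runif(k, 0, 45000))
    sched <- fake_schedule(t2)
    got <- score_block(sched, presses)
    want <- brute_force_score(t2, presses, 200, 2500)
    expect_identical(got$n_in_window, want$n_in)
    expect_identical(got$detected, want$detected)
    expect_equal(got$rt_ms, want$rt)
  }
})

test_that("every reported RT lies inside the open window", {
  s <- build_stream(standard_block_conditions(), seed = 8)
  for (k in 1:20) {
    sc <- score_block(s, simulate_presses(s, observer_params(), seed = k))
    rts <- sc$rt_ms[sc$detected]
    expect_true(all(rts > 200 & rts < 2500))
  }
})

test_that("scrambling preserves the press count and sorts times", {
  out <- scramble_log(c(100, 5000, 9000, 20000, 33000, 40000, 41000,
                        50000, 60000, 61000, 70000, 80000, 88000),
                      t_max = 91300, seed = 1)
  expect_length(out, 13L)
  expect_false(is.unsorted(out))
  expect_true(all(out >= 0 & out <= 91300))
  expect_length(scramble_log(numeric(0), t_max = 91300, seed = 1), 0L)
})

test_that("condition grouping keys regular by d and irregular by first gap", {
  expect_identical(condition_group(regular_condition(4)), "R4")
  expect_identical(condition_group(irregular_condition(c(3, 1, 5, 2, 4))), "I3")
  expect_identical(condition_group(irregular_condition(c(5, 4, 3, 2, 1))), "I5")
  s <- build_stream(standard_block_conditions(), seed = 2)
  expect_identical(condition_group(s$sequences[[1]]),
                   condition_group(s$sequences[[1]]$condition))
})

test_that("scrambled chance rate follows the analytic binomial form", {
  # P(exactly one of k uniform presses in a width-w window on [0, T])
  #   = k (w/T) (1 - w/T)^(k-1)
  s <- build_stream(standard_block_conditions(), seed = 10)
  w <- 2300
  t_max <- s$events$onset_ms[s$n_events] + 58.3 + 2500
  k <- 13
  presses <- sort(runif(k, 0, t_max))
  ch <- chance_level(s, presses, n_scrambles = 2000, seed = 11)
  observed <- sum(ch$chance_rate * ch$n_trials) / sum(ch$n_trials)
  expected <- k * (w / t_max) * (1 - w / t_max)^(k - 1)
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("chance level separates from real performance and handles empty logs", {
  s <- build_stream(standard_block_conditions(), seed = 12)
  log <- simulate_presses(s, perfect_observer(), seed = 13)
  sc <- score_block(s, log)
  ch <- chance_level(s, log, n_scrambles = 200, seed = 14)
  expect_lt(sum(ch$chance_rate * ch$n_trials) / sum(ch$n_trials),
            mean(sc$detected))
  ch0 <- chance_level(s, numeric(0), n_scrambles = 5, seed = 15)
  expect_true(all(ch0$chance_rate == 0))
})

test_that("chance-level noise shrinks as scrambles accumulate", {
  s <- build_stream(standard_block_conditions(), seed = 16)
  presses <- sort(runif(13, 0, 91000))
  overall <- function(n_scr, seed) {
    ch <- chance_level(s, presses, n_scrambles = n_scr, seed = seed)
    sum(ch$chance_rate * ch$n_trials) / sum(ch$n_trials)
  }
  few <- vapply(1:30, function(k) overall(1, 100 + k), 0)
  many <- vapply(1:30, function(k) overall(50, 200 + k), 0)
  expect_lt(stats::sd(many), stats::sd(few))
})

test_that("pp difference identity holds in the condition summary", {
  d <- build_session("p1", seed = 21)
  sim <- simulate_session(d, observer_params(), seed = 22)
  ch <- chance_session(d, sim$presses, n_scrambles = 2, seed = 23)
  sm <- summarize_detection(sim$scores, ch)
  expect_equal(sm$pp_difference,
               100 * (sm$detection_rate - sm$chance_rate))
  expect_true(all(sm$detection_rate >= 0 & sm$detection_rate <= 1))
  expect_identical(sum(sm$n_trials), 240L)
})

test_that("contrasts count trials as designed and are seed-reproducible", {
  d <- build_session("p1", seed = 24)
  sim <- simulate_session(d, observer_params(), seed = 25)

  r3 <- contrast_r3_vs_irregular(sim$scores, seed = 26)
  expect_identical(r3$n_regular, 24L)      # 24 R3 trials per session
  expect_identical(r3$n_irregular, 24L)    # equal-size irregular subsample
  expect_identical(r3, contrast_r3_vs_irregular(sim$scores, seed = 26))

  allc <- contrast_all_regular_vs_all_irregular(sim$scores)
  expect_identical(allc$n_regular, 120L)
  expect_identical(allc$n_irregular, 120L)

  # error when irregular pool is smaller than the R3 trial set
  few <- sim$scores[sim$scores$cond_group %in% c("R3", "I1"), ]
  few <- few[cumsum(grepl("^I", few$cond_group)) <= 10 | grepl("^R", few$cond_group), ]
  expect_error(contrast_r3_vs_irregular(few, seed = 1), "fewer irregular")
})

test_that("an all-detected observer gives exactly zero rate difference", {
  d <- build_session("p1", seed = 27)
  sim <- simulate_session(d, perfect_observer(), seed = 28)
  allc <- contrast_all_regular_vs_all_irregular(sim$scores)
  expect_identical(allc$diff_detection, 0)
})

test_that("exchangeable groups give near-zero mean contrast over many seeds", {
  d <- build_session("p1", seed = 29)
  sim <- simulate_session(d, symmetric_observer(), seed = 30)
  diffs <- vapply(1:40, function(k) {
    contrast_r3_vs_irregular(sim$scores, seed = 600 + k)$diff_detection
  }, 0)
  # single-session subsampling noise: SE of the mean over 40 draws is small;
  # the bound only needs to rule out a systematic offset
  expect_lt(abs(mean(diffs) - mean(sim$scores$detected[grepl("^I", sim$scores$cond_group)]) +
                  mean(sim$scores$detected[sim$scores$cond_group == "R3"])), 0.06)
})
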