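test_that("the default conditioning protocol has the published geometry", {
  sched <- build_pavlovian_schedule(seed = 1)
  expect_identical(sched$n_steps, 160000L) # 16 s of simulated time
  expect_identical(sched$epochs, c(1L, 40001L, 80001L, 120001L))
  cs1 <- sched$pulses[sched$pulses$label == "CS1", ]
  r1 <- sched$reinforcements[sched$reinforcements$q == 1, ]
  # reinforcement onset = CS offset + 250 steps; duration 750
  expect_identical(r1$onset[1], cs1$onset[1] + 1000L + 250L)
  expect_true(all(r1$duration == 750L))
  expect_true(all(sched$pulses$duration[sched$pulses$label != "distractor"] == 1000L))
  # epoch 1: four presentations of each appetitive CS, alternating
  ep1 <- sched$pulses[sched$pulses$onset < 40000, ]
  expect_identical(ep1$label, rep(c("CS1", "CS2"), 4))
  # epoch 2: aversive CS with the aversive reinforcer
  ep2 <- sched$pulses[sched$pulses$onset >= 40000 & sched$pulses$onset < 80000, ]
  expect_true(all(ep2$label == "CS3"))
  expect_identical(nrow(ep2), 8L)
  expect_true(all(sched$reinforcements$q[sched$reinforcements$onset > 40000] == 2))
  # testing phases follow the CS1-CS3-CS2-CS3 sequence, unreinforced
  ep3 <- sched$pulses[sched$pulses$onset >= 80000 & sched$pulses$label != "distractor", ]
  expect_identical(ep3$label[1:4], c("CS1", "CS3", "CS2", "CS3"))
  expect_identical(max(sched$reinforcements$onset) < 80000, TRUE)
})

test_that("conditioned stimuli never overlap in time", {
  sched <- build_pavlovian_schedule(seed = 3, n_distractors = 8)
  cs <- sched$pulses[sched$pulses$label != "distractor", ]
  cs <- cs[order(cs$onset), ]
  expect_true(all(diff(cs$onset) >= 1000))
  # distractors live on non-CS channels
  d <- sched$pulses[sched$pulses$label == "distractor", ]
  expect_true(all(!d$channel %in% 1:3))
  expect_true(all(d$duration == 600L))
})

test_that("distractors are seed-deterministic and configurable", {
  a <- build_pavlovian_schedule(seed = 9)
  b <- build_pavlovian_schedule(seed = 9)
  c <- build_pavlovian_schedule(seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$pulses, c$pulses))
  none <- build_pavlovian_schedule(seed = 9, n_distractors = 0)
  expect_true(all(none$pulses$label != "distractor"))
  expect_error(build_pavlovian_schedule(n_channels = 2), "at least 3")
})

test_that("the motivation drive covers exactly the second testing phase", {
  sched <- build_pavlovian_schedule(seed = 1, motivation = c(160, 0))
  m <- schedule_matrices(sched)$M
  expect_identical(unique(m[1:120000, 1]), 0)
  expect_identical(unique(m[120001:160000, 1]), 160)
  expect_identical(max(m[, 2]), 0)
})

test_that("rubbernecking trials have the published span and geometry", {
  sched <- build_rubbernecking_schedule(lag_steps = 500, n_trials = 20, seed = 1)
  expect_identical(sched$n_steps, 400000L) # 20 s prefix + 20 s of trials
  expect_identical(nrow(sched$trials), 20L)
  expect_identical(sched$trials$s2_onset - (sched$trials$s1_onset + 1000L), rep(500L, 20))
  long <- build_rubbernecking_schedule(lag_steps = 4000, n_trials = 20, seed = 1)
  expect_identical(long$trials$s2_onset - (long$trials$s1_onset + 1000L), rep(4000L, 20))
  # thresholds drawn inside [0.05, 0.35], one per trial, seed-stable
  expect_true(all(sched$trials$threshold >= 0.05 & sched$trials$threshold <= 0.35))
  again <- build_rubbernecking_schedule(lag_steps = 500, n_trials = 20, seed = 1)
  expect_identical(sched$trials$threshold, again$trials$threshold)
  one <- build_rubbernecking_schedule(lag_steps = 500, n_trials = 1, seed = 2)
  expect_identical(nrow(one$trials), 1L)
  expect_error(build_rubbernecking_schedule(lag_steps = 9000), "lag too long")
})

test_that("detection scoring respects the per-trial thresholds", {
  fix <- generate_fixture("single-trial-detection")
  tr <- simulate(fix$schedule, fix$params)
  # activity is bounded by B = 10: an impossible threshold detects nothing
  trials_hi <- fix$schedule$trials
  trials_hi$threshold <- 11
  expect_identical(score_detection(tr, trials_hi)$rate, 0)
  trials_lo <- fix$schedule$trials
  trials_lo$threshold <- -1
  expect_identical(score_detection(tr, trials_lo)$rate, 1)
  expect_error(score_detection(tr, channel = 99), "missing")
})
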