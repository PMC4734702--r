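test_that("an empty drive leaves the trace identically zero", {
  sched <- build_pavlovian_schedule(
    n_channels = 3, seed = 1, n_distractors = 0, epoch_steps = 250L,
    cs_duration = 1L, r_duration = 1L, r_delay = 1L, ep1_reps = 1L,
    ep2_reps = 1L, test_cycles = 1L, amplitude = 0
  )
  tr <- simulate(sched, tiny_params())
  m <- as.matrix(tr[, c(activity_cols(tr), weight_cols(tr))])
  expect_identical(max(abs(m)), 0)
})

test_that("conditioning drives valence-specific saturating learning", {
  tr <- simulate(small_sched(), tiny_params())
  fs <- attr(tr, "final_state")
  # CS1/CS2 channels learned into the appetitive subgroup, CS3 aversive
  expect_gt(fs$WstLA[1], 0.9)
  expect_gt(fs$WstLA[2], 0.9)
  expect_identical(fs$WstLA[3], 0)
  expect_identical(fs$WstLA[4:5], c(0, 0))
  expect_gt(fs$WstLA[6], 0.9)
  # feed plan dominates during the appetitive conditioning phase
  ep1 <- tr$time <= 1.0
  expect_gt(max(tr$x_PC.q1[ep1]), 1)
  # the fear plan never meaningfully activates during appetitive pairing
  expect_lt(max(tr$x_PC.q2[ep1]), 0.01)
})

test_that("weights are non-decreasing and never exceed their ceilings", {
  tr <- simulate(tiny_sched(), tiny_params())
  for (cn in weight_cols(tr)) {
    w <- tr[[cn]]
    expect_true(all(diff(w) >= 0), label = paste(cn, "monotone"))
    ceiling_ <- if (grepl("^W_ST_LA", cn)) 1 else 1
    expect_true(all(w <= ceiling_ + 1e-12), label = paste(cn, "bounded"))
  }
})

test_that("every shunting activity stays inside [-C, B]", {
  tr <- simulate(tiny_sched(), tiny_params())
  m <- as.matrix(tr[, activity_cols(tr)])
  expect_true(all(m <= 10 + 1e-9))
  expect_true(all(m >= -10 - 1e-9))
})

test_that("simulation is deterministic given schedule and seed", {
  s1 <- build_pavlovian_schedule(n_channels = 10, seed = 5)
  s2 <- build_pavlovian_schedule(n_channels = 10, seed = 5)
  expect_identical(s1, s2)
  t1 <- simulate(tiny_sched(), tiny_params())
  t2 <- simulate(tiny_sched(), tiny_params())
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("schedule and parameter channel counts must agree", {
  expect_error(simulate(tiny_sched(), rate_params(N = 10)), "channels")
})
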