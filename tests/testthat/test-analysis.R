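# a hand-built trace: plan activity columns plus the minimal metadata the
# analysis verbs need
fake_trace <- function(pc1, pc2, dt = 0.001) {
  n <- length(pc1)
  tr <- tibble::tibble(
    time = seq_len(n) * dt,
    x_PC.q1 = pc1, x_PC.q2 = pc2
  )
  class(tr) <- c("amygate_trace", class(tr))
  attr(tr, "variant") <- "rate"
  attr(tr, "h") <- 1e-4
  attr(tr, "record_stride") <- 10L
  tr
}

test_that("plan labeling is argmax-above-threshold with a none state", {
  tr <- fake_trace(c(rep(5, 100), rep(0.1, 100)), c(rep(0.1, 100), rep(0.2, 100)))
  pl <- plan_timeline(tr, activation_threshold = 1)
  expect_identical(pl$timeline$active[1], "feed")
  expect_identical(pl$timeline$active[150], "none")
  expect_identical(pl$switches, 0L)
  # x_PC = (5, 0.1) -> feed; (0.2, 0.2) -> none at threshold 1
  tr2 <- fake_trace(rep(0.2, 100), rep(0.2, 100))
  expect_true(all(plan_timeline(tr2, 1)$timeline$active == "none"))
})

test_that("switches are counted on label changes, skipping none gaps", {
  pc1 <- c(rep(5, 200), rep(0, 100), rep(5, 200), rep(0, 300))
  pc2 <- c(rep(0, 300), rep(0, 0), rep(0, 200), rep(5, 300))
  pl <- plan_timeline(fake_trace(pc1, pc2), activation_threshold = 1)
  expect_identical(pl$switches, 1L) # feed .. feed -> fear: one real switch
  # none gaps between same-label periods are bridged, so the two feed
  # stretches form one period
  expect_identical(pl$periods$label, c("feed", "fear"))
})

test_that("brief flicker below the dwell time does not count as switching", {
  pc1 <- c(rep(5, 300), rep(0, 10), rep(5, 300))
  pc2 <- c(rep(0, 300), rep(5, 10), rep(0, 300))
  pl <- plan_timeline(fake_trace(pc1, pc2), activation_threshold = 1, min_dwell = 0.05)
  expect_identical(pl$switches, 0L)
})

test_that("a zero trace yields zero attention integrals", {
  sched <- tiny_sched()
  tr <- simulate(sched, tiny_params())
  zero <- tr
  for (cn in grep("^x_SC", names(zero), value = TRUE)) zero[[cn]] <- 0
  at <- attention_summary(zero)
  expect_true(all(at$presentations$integral == 0))
  expect_identical(sum(at$within_plan$attended_switches), 0L)
})

test_that("plan classification is robust across activation thresholds", {
  tr <- simulate(build_pavlovian_schedule(seed = 1), rate_params(reset = "slow"))
  counts <- sapply(c(0.5, 1, 1.5, 2), function(thr) {
    plan_timeline(tr, activation_threshold = thr, t_range = c(8, 12))$switches
  })
  expect_true(all(counts == counts[1]))
  expect_gt(counts[1], 0)
})

test_that("lesion comparison refuses mismatched schedules", {
  t1 <- simulate(tiny_sched(), tiny_params())
  t2 <- simulate(tiny_sched(seed = 43L), tiny_params())
  expect_error(lesion_phenotype(list(a = t1, b = t2)), "share one schedule")
})
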