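rs <- list(a = 0.02, b = 0.2, c = -65, d = 8)

test_that("the after-spike reset fires at the reset threshold", {
  r <- izhikevich_step(v = 31, u = 0, E = 0, I = 0, izh = rs)
  expect_identical(r$v, -65)
  expect_equal(r$u, (1e-4 / 1e-3) * (0.02 * (0.2 * 31)) + 8)
  # below the reset threshold (with recovery holding the upstroke), the
  # voltage is integrated without resetting
  r2 <- izhikevich_step(v = 29.9, u = 330, E = 0, I = 0, izh = rs)
  expect_false(r2$spiked)
  expect_lt(r2$v, 30)
  expect_gt(r2$v, 20)
})

test_that("the quadratic nullcline fixed point is stationary", {
  # v = -70 solves 0.04 v^2 + 5 v + 140 - u = 0 with u = b v = -14
  r <- izhikevich_step(v = -70, u = -14, E = 0, I = 0, izh = rs)
  expect_equal(r$v, -70)
  expect_equal(r$u, -14)
})

test_that("spike emission is edge-triggered at the emission threshold", {
  r <- izhikevich_step(v = 19, u = -14, E = 200, I = 0, izh = rs)
  expect_true(r$spiked) # upward crossing of 20
  r2 <- izhikevich_step(v = 21, u = -14, E = 200, I = 0, izh = rs)
  expect_false(r2$spiked) # already above: no retrigger
})

test_that("regular-spiking cells have a rheobase between 1 and 10", {
  fire_count <- function(I_in) {
    v <- -65; u <- 0.2 * v; n <- 0
    for (s in 1:20000) {
      r <- izhikevich_step(v, u, E = I_in, I = 0, izh = rs)
      v <- r$v; u <- r$u
      n <- n + r$spiked
    }
    n
  }
  expect_equal(fire_count(1), 0) # a unit current is subthreshold
  expect_gt(fire_count(10), 3) # the calibrated input current fires tonically
})

test_that("the synaptic signal is silent without spikes and bounded always", {
  T <- 0; g <- 0
  for (s in 1:1000) {
    r <- sd_synapse_step(T, g, K = 0)
    T <- r$T; g <- r$g
  }
  expect_identical(c(T, g), c(0, 0))

  # saturation under arbitrary spike trains
  withr::with_seed(11, {
    ok <- TRUE
    for (rep in 1:5) {
      T <- 0; g <- 0
      K <- rbinom(5000, 1, 0.2) # unphysiologically dense train
      for (s in seq_along(K)) {
        r <- sd_synapse_step(T, g, K[s])
        T <- r$T; g <- r$g
        ok <- ok && T >= 0 && T <= 1 && g >= 0 && g <= 1
      }
      expect_true(ok)
      expect_gt(g, 0.5) # driven towards saturation, not collapse
    }
  })
})

test_that("single-spike postsynaptic response matches a dense-step oracle", {
  # one spike leaves the transmitter at T = 0.1 (the h/tau_s kick); from
  # there the coupled decay/rise ODEs are integrated at the production
  # step and, independently, at a 10x finer step as the reference
  run_sd <- function(h) {
    n <- round(0.2 / h)
    T <- 0.1; g <- 0
    tpk <- 0; gpk <- 0
    for (s in 1:n) {
      r <- sd_synapse_step(T, g, K = 0, h = h)
      T <- r$T; g <- r$g
      if (g > gpk) {
        gpk <- g
        tpk <- s * h
      }
    }
    c(peak = gpk, t_peak = tpk)
  }
  coarse <- run_sd(1e-4)
  fine <- run_sd(1e-5)
  expect_equal(coarse[["peak"]], fine[["peak"]], tolerance = 0.02)
  expect_equal(coarse[["t_peak"]], fine[["t_peak"]], tolerance = 0.1)
  # rise and decay timescales bracket the time to peak
  expect_gt(coarse[["t_peak"]], 0.002)
  expect_lt(coarse[["t_peak"]], 0.03)
})

test_that("recorded voltages never exceed the reset threshold", {
  tr <- simulate(tiny_sched(400L), spiking_params(N = 3))
  v <- as.matrix(tr[, grep("^v_", names(tr))])
  expect_lt(max(v), 30)
  expect_identical(min(as.matrix(tr[, grep("^(T|x)_(ST|SC)", names(tr))])) >= 0, TRUE)
})

test_that("zero drive leaves the spiking network silent", {
  sched <- build_pavlovian_schedule(
    n_channels = 3, seed = 1, n_distractors = 0, epoch_steps = 250L,
    cs_duration = 1L, r_duration = 1L, r_delay = 1L, ep1_reps = 1L,
    ep2_reps = 1L, test_cycles = 1L, amplitude = 0
  )
  tr <- simulate(sched, spiking_params(N = 3))
  expect_identical(nrow(attr(tr, "spikes")), 0L)
  g <- as.matrix(tr[, grep("^x_(ST|SC|SR|LA|BA|PT|PC|PR)", names(tr))])
  expect_identical(max(abs(g)), 0)
})
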