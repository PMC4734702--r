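test_that("rectification clamps negative values elementwise", {
  expect_identical(rectify(3.5), 3.5)
  expect_identical(rectify(-2), 0)
  expect_identical(rectify(c(-1, 0, 2)), c(0, 0, 2))
})

test_that("shunting step reproduces hand-computed Euler updates", {
  # quiescence is a fixed point
  expect_identical(shunting_step(0, 0, 0, A = 1, B = 10, C = 10, tau = 0.05, h = 1e-4), 0)
  # (h/tau) * B * E = 0.002 * 10
  expect_equal(
    shunting_step(0, E = 1, I = 0, A = 1, B = 10, C = 10, tau = 0.05, h = 1e-4),
    0.02
  )
})

test_that("iterated shunting updates converge to the closed-form equilibrium", {
  withr::with_seed(7, {
    for (k in 1:50) {
      E <- runif(1, 0, 8)
      I <- runif(1, 0, 8)
      A <- runif(1, 0.5, 100)
      x <- 0
      for (s in 1:200000) {
        x_new <- shunting_step(x, E, I, A, B = 10, C = 10, tau = 0.05, h = 1e-4)
        if (abs(x_new - x) < 1e-13) {
          x <- x_new
          break
        }
        x <- x_new
      }
      expect_lt(abs(x - shunting_fixed_point(E, I, A, B = 10, C = 10)), 1e-6)
    }
  })
})

test_that("weight updates are reinforcement-gated and saturating", {
  p <- tiny_params()
  st <- rate_state0(3)
  st$ST <- c(1, 0, 0)

  # closed reinforcement gate: unchanged
  w0 <- update_weights(st, st, drive = list(S = numeric(3), R = c(0, 0), M = c(0, 0)), p, h = 1e-4)
  expect_identical(w0$WstLA, numeric(6))

  # single Euler step of the thalamo-amygdalar law:
  # (h/tau_w) * (B - 0) * [1 - 0.75]+ * R = 0.002 * 1 * 0.25
  w1 <- update_weights(st, st, drive = list(S = numeric(3), R = c(1, 0), M = c(0, 0)), p, h = 1e-4)
  expect_equal(w1$WstLA[1], 5e-4)
  expect_identical(w1$WstLA[2:6], numeric(5))

  # saturation: a weight at its ceiling cannot grow
  st$WstLA[] <- p$B_ST_LA
  w2 <- update_weights(st, st, drive = list(S = numeric(3), R = c(1, 1), M = c(0, 0)), p, h = 1e-4)
  expect_identical(w2$WstLA, st$WstLA)
})
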