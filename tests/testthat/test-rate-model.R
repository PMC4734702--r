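test_that("a silent network has zero drives everywhere", {
  p <- rate_params()
  st <- rate_state0(p$N)
  d <- compute_drives(st, st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p)
  for (nm in names(d$E)) {
    expect_identical(d$E[[nm]], numeric(length(d$E[[nm]])), label = paste("E", nm))
    expect_identical(d$I[[nm]], numeric(length(d$I[[nm]])), label = paste("I", nm))
  }
})

test_that("an isolated stimulus feeds forward only to its thalamic channel", {
  p <- rate_params()
  st <- rate_state0(p$N)
  S <- numeric(10)
  S[3] <- 1
  d <- compute_drives(st, st, list(S = S, R = c(0, 0), M = c(0, 0)), p)
  expect_identical(d$E$ST, c(0, 0, 1, rep(0, 7)))
  for (nm in setdiff(names(d$E), "ST")) {
    expect_identical(d$E[[nm]], numeric(length(d$E[[nm]])), label = nm)
  }
})

test_that("TRN inhibition sums over off-diagonal channels only", {
  p <- rate_params()
  st <- rate_state0(p$N)
  st$SR <- rep(1, 10)
  d <- compute_drives(st, st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p)
  # independent oracle: explicit double loop over the weight matrix
  oracle <- sapply(1:10, function(i) {
    tot <- 0
    for (j in 1:10) {
      w_ji <- if (j == i) 0 else p$W_SR_ST # zero diagonal
      tot <- tot + w_ji * max(st$SR[j], 0)
    }
    tot
  })
  expect_equal(d$I$ST, oracle)
  expect_identical(d$I$ST, rep(3 * 9, 10)) # 3 * (N - 1) for N = 10
})

test_that("open-loop topology: a lone TRN unit never inhibits its own loop", {
  p <- rate_params()
  for (i in c(1, 4, 10)) {
    st <- rate_state0(p$N)
    st$SR[i] <- 2
    d <- compute_drives(st, st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p)
    expect_identical(d$I$ST[i], 0)
    expect_identical(d$I$SR[i], 0)
    expect_true(all(d$I$ST[-i] == p$W_SR_ST * 2))
  }
  # same for the two-channel plan map
  st <- rate_state0(p$N)
  st$PR <- c(1.5, 0)
  d <- compute_drives(st, st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p)
  expect_identical(d$I$PT, c(0, p$W_PR_PT * 1.5))
  expect_identical(d$I$PR, c(0, p$W_PR_PR * 1.5))
})

test_that("state/drive dimension mismatches are rejected", {
  p <- rate_params()
  st <- rate_state0(5)
  expect_error(
    compute_drives(st, st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p),
    "dimensions"
  )
  st10 <- rate_state0(10)
  expect_error(
    compute_drives(st10, st10, list(S = numeric(4), R = c(0, 0), M = c(0, 0)), p),
    "length"
  )
})

test_that("one synchronous step from rest only moves the stimulated channel", {
  p <- rate_params()
  st <- rate_state0(p$N)
  S <- numeric(10)
  S[3] <- 1
  st2 <- rate_step(st, list(S = S, R = c(0, 0), M = c(0, 0)), p)
  expect_equal(st2$ST[3], 0.02)
  st2$ST[3] <- 0
  expect_identical(unlist(st2), unlist(rate_state0(p$N)))
})

test_that("the EV hard nonlinearity clamps at zero after resetting", {
  p <- rate_params()
  st <- rate_state0(p$N)
  st$Lv[1] <- 0.01
  st$Lc[1] <- 9 # strong confirmation inhibition would drive Lv negative
  st2 <- rate_step(st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p)
  raw <- shunting_step(0.01,
    E = 0, I = p$W_Lcv * 9, A = p$A_Lv_Pv,
    B = p$B, C = p$C, tau = p$tau_Lv_Lvr, h = 1e-4
  )
  expect_lt(raw, 0)
  expect_identical(st2$Lv[1], 0)
})

test_that("non-finite activities abort with the population named", {
  p <- rate_params()
  st <- rate_state0(p$N)
  st$ST[2] <- Inf
  expect_error(
    rate_step(st, list(S = numeric(10), R = c(0, 0), M = c(0, 0)), p),
    "non-finite activity in population"
  )
})
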