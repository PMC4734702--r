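test_that("default parameters equal the published operating point", {
  p <- rate_params()
  expect_identical(p$W_SR_ST, 3)
  expect_identical(p$W_SC_ST, 0.8)
  expect_identical(p$W_yB, 30)
  expect_identical(p$W_yy, 80)
  expect_identical(p$W_vv, 20)
  expect_identical(p$Gamma_ST, 0.75)
  expect_identical(p$Gamma_r, 1)
  expect_identical(p$A_r, 200)
  expect_identical(p$B, 10)
  expect_identical(p$C, 10)
  expect_identical(p$tau_Pv_Pvr, 12.5)
  expect_identical(rate_params(reset = "fast")$tau_Pv_Pvr, 2.5)

  s <- spiking_params()
  expect_identical(s$W_SR_ST, 100)
  expect_identical(s$B_ST_LA, 100)
  expect_identical(s$B_PC_BA, 40)
  expect_identical(s$tau_w, 0.025)
  expect_identical(s$tau_s, 0.001)
  expect_identical(s$tau_Pv_Pvr, 10)
  expect_identical(spiking_params(reset = "fast")$tau_Pv_Pvr, 1.33)
  expect_identical(s$izh_rs_a, 0.02)
  expect_identical(s$izh_fs_a, 0.1)
  expect_identical(s$tau_rise, 0.004)
  expect_identical(s$tau_fall, 0.040)
})

test_that("parameter tables satisfy their structural invariants", {
  for (v in c("rate", "spiking")) {
    tab <- param_table(v)
    w <- tab[!is.na(tab$lo), ]
    # every weight default lies inside its robustness range
    expect_true(all(w$value >= w$lo & w$value <= w$hi))
    expect_true(all(w$lo < w$hi))
    k <- setNames(tab$value, tab$symbol)
    expect_gt(k[["B"]], 0)
    expect_gte(k[["C"]], 0)
    taus <- k[grepl("^tau", names(k))]
    expect_true(all(taus > 0))
    As <- k[grepl("^A_", names(k))]
    expect_true(all(As >= 0))
  }
})

test_that("unknown overrides are rejected with the known-symbol list", {
  err <- expect_error(rate_params(W_FOO = 1), "unknown parameter symbol")
  expect_match(conditionMessage(err), "W_SC_ST") # lists known symbols
  expect_error(experiment_config(overrides = list(W_FOO = 1)), "W_FOO")
})

test_that("overrides outside the robustness range warn but apply", {
  expect_warning(p <- rate_params(W_SR_ST = 10), "robustness range")
  expect_identical(p$W_SR_ST, 10)
  expect_silent(p2 <- rate_params(W_SR_ST = 2))
  expect_identical(p2$W_SR_ST, 2)
})
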