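# The compiled integrators are validated against the scalar R reference
# steppers, which transcribe the model equations population by population
# with explicit loops. Agreement is required bit-for-bit.

test_that("compiled rate core matches the scalar reference bit-for-bit", {
  sched <- tiny_sched(250L) # 1000 steps across all four epochs
  p <- tiny_params()
  fast <- simulate(sched, p, engine = "fast")
  ref <- simulate(sched, p, engine = "reference")
  expect_identical(as.data.frame(fast), as.data.frame(ref))
  expect_identical(attr(fast, "final_state"), attr(ref, "final_state"))
})

test_that("compiled spiking core matches the scalar reference bit-for-bit", {
  sched <- tiny_sched(400L)
  p <- spiking_params(N = 3)
  fast <- simulate(sched, p, engine = "fast")
  ref <- simulate(sched, p, engine = "reference")
  expect_identical(as.data.frame(fast), as.data.frame(ref))
  expect_gt(nrow(attr(fast, "spikes")), 0) # the comparison is not vacuous
  expect_identical(
    as.data.frame(attr(fast, "spikes")),
    as.data.frame(attr(ref, "spikes"))
  )
})
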