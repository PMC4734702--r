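---
title: "Model and methods: amygdala-gated attention through the thalamic reticular nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(amygate)
```

## The circuit

`amygate` simulates a neural circuit in which the amygdala controls
selective attention by exciting the inhibitory thalamic reticular nucleus
(TRN). Three interacting maps are modeled:

* a **sensory map** of `N` parallel cortex–TRN–thalamus (CRT) loops, one
  per stimulus channel. Each thalamic relay excites its cortical partner
  and its TRN sector; TRN units inhibit every thalamic (and TRN) unit
  *except* their own loop (open-loop, zero-diagonal off-surround
  inhibition). Elevated sensory-cortical activity in a channel is the
  model's operational definition of attention to that stimulus.
* a **salience map** — the amygdala. The lateral nucleus (LA) receives
  topographic thalamic input through learned weights; the basal nucleus
  (BA) relays LA activity to the sensory TRN/thalamus/cortex and to the
  plan map. LA and BA each hold an appetitive and an aversive subgroup of
  `N` cells. BA activity is what makes a stimulus "salient": it biases the
  CRT competition toward conditioned channels and, through the TRN,
  actively suppresses everything else.
* a **plan map** — a two-channel CRT circuit (feed plan, fear plan) in
  which loop competition implements decision-making. Each BA subgroup
  provides converging "evidence" for its plan; plan cortex projects back
  to BA, holding the salience of plan-relevant stimuli high (top-down
  attention).

### Shunting dynamics

Every rate-coded unit obeys the bounded (shunting) membrane equation

$$\tau \dot x = -A x + (B - x)E - (x + C)I,$$

with excitatory drive $E$, inhibitory drive $I$, passive decay $A$, and
hard bounds $-C \le x \le B$ ($B = C = 10$). Under frozen drives the
equilibrium is $x^\* = (BE - CI)/(A + E + I)$; `shunting_fixed_point()`
exposes this closed form and the test suite checks convergence to it at
$10^{-6}$. Drives are assembled population by population by
`compute_drives()`; most presynaptic terms are positively rectified
(`rectify()`), and the Heaviside gates treat zero as closed (`H(0) = 0`).

### Learning

Two weight families are plastic, both reinforcement-gated, saturating, and
decay-free (weights never decrease):

* thalamus → LA: grows when presynaptic thalamic activity exceeds its
  threshold (0.75) while the matching reinforcement signal $R_q$ is on;
  ceiling `B_ST_LA` = 1.
* plan cortex → BA: additionally gated by postsynaptic BA activity;
  ceiling `B_PC_BA` = 1.

The learning time constant is 0.05 s, so a single 75-ms reinforcement
pulse essentially saturates an eligible weight — conditioning in this
model is rapid by design.

### Expectation signals and resetting

Persistent activity in BA and in plan cortex is interrupted by local
inhibitory interneurons, driven by two phenomenological signals computed
per LA cell (stimulus-specific) and per plan-cortex cell (plan-specific):

* **expectation confirmation (EC)**: presynaptic activity multiplied by
  the reinforcement signal; fast (0.25 s), active only while the expected
  outcome actually arrives. EC both excites the interneuron (resetting
  the principal cell after a *confirmed* prediction) and inhibits the EV
  signal.
* **expectation violation (EV)**: builds while the cell is active above
  threshold *without* reinforcement; slow (3.33 s amygdala; 12.5 s slow /
  2.5 s fast plan cortex), with self-excitation above 0.1 that makes the
  build-up autonomous once started. A companion reset unit with strong
  self-excitation (gated by a Heaviside on the EV level) terminates the EV
  excursion; a hard nonlinearity clamps EV at zero after resetting.

The EV build-up rate is the model's flexibility dial: slow build-up gives
a "patient" decision process that persists through several unconfirmed
stimuli; fast build-up re-decides after a single violation. Lesion
switches (`lesion_config()`) zero the interneuron-to-principal synapse —
the interneurons keep integrating and appear in traces; only their effect
is removed.

## Spiking variant

`spiking_params()` swaps every rate unit for an Izhikevich point neuron
(regular-spiking constants 0.02/0.2/−65/8 for principal cells,
fast-spiking 0.1/0.2/−65/2 for all interneurons, including TRN), keeping
the wiring. Presynaptic activities are replaced by each neuron's
saturating-differentials postsynaptic signal $g \in [0,1]$ (rise 4 ms,
fall 40 ms), driven by an edge-triggered spike indicator (one event per
upward crossing of 20 mV; after-spike reset at 30 mV). EC/EV signals stay
rate-style — point-neuron dynamics cannot express a slowly building,
self-resetting scalar — and reuse the rate model's decay rates and bounds
with the spiking weight table's gains and thresholds.

One calibration is the package's own: the external stimulus amplitude
(1 in both weight tables) is far below the regular-spiking rheobase
(about 4 current units), so a literal injection leaves the network
permanently silent. Stimuli are therefore scaled into current by a gain
`W_S`. Its value (14) was fixed by requiring the spiking variant to
reproduce the rate variant's qualitative behaviors — valence-tracking
plan selection and all four interneuron-lesion phenotypes — robustly
across schedule seeds; this mirrors the design requirement that the two
variants behave alike. At lower gains the stimulus cannot re-capture
attention against BA-driven TRN inhibition in a lesion-insensitive way,
and the lesion contrasts degenerate.

## Protocols (the synthetic-data generators)

All inputs are generated programmatically; there is no external data.

**Pavlovian conditioning** (`build_pavlovian_schedule()`): 160000 Euler
steps of $h = 10^{-4}$ s (16 s), four equal epochs. Epoch 1: CS1 and CS2
alternate (4 presentations each, 1000-step pulses of amplitude 1), each
followed after 250 steps by the appetitive reinforcer (750 steps).
Epoch 2: CS3 ×8 with the aversive reinforcer. Epochs 3–4: the sequence
CS1–CS3–CS2–CS3 with no reinforcement plus rectangular distractor pulses
(600 steps) on uniformly random non-CS channels at uniformly random
onsets — the only stochastic element, drawn once from the schedule seed.
Epoch 4 optionally adds the tonic motivation drive $M_q = 160$ to one
plan's thalamus.

Two scheduling details are free choices the source protocol leaves open:

* *testing-phase density*: 5 CS1–CS3–CS2–CS3 cycles per testing epoch
  (one presentation every 0.2 s, cycle period 0.8 s). This spacing was
  chosen so that one and the same schedule exhibits the published
  behavior under *both* reset speeds, which is how the source figures
  are constructed. Periods commensurate with either expectation-violation
  cycle fail in characteristic ways: a 1.0-s cycle phase-locks with the
  ~1.5-s slow build-up so reset windows always close a few milliseconds
  after CS3 onset and the fear plan can never win, while a 4/3-s cycle
  resonates with the ~0.35-s fast reset so each stimulus arrives exactly
  when the just-reset plan's loop still simmers and the feed plan can
  never re-ignite. Both are resonance artifacts of particular spacings,
  not circuit properties.
* *distractor law*: count 6 by default, duration 600 steps, amplitude 1.

**Emotion-induced blindness** (`build_rubbernecking_schedule()`,
`run_rubbernecking()`): a 200000-step conditioning prefix pairs S1 with
the aversive reinforcer (8 evenly spaced pairings, reusing the epoch-2
recipe), then 20 trials over 200000 steps: S1 pulse (1000 steps), gap of
`lag_steps` (500 short / 4000 long), S2 pulse; one detection threshold
per trial from $U[0.05, 0.35]$ (the model's stand-in for unmodeled
arousal variability). Detection = the S2 channel's sensory-cortical
activity strictly exceeds the threshold anywhere in the S2 window (onset
to offset). These runs use the fast plan-reset time constant: with slow
resetting the fear plan triggered by S1 outlives even the 400-ms lag and
both lags would be suppressed; fast resetting restores salience-map
control between 150 ms and 400 ms, separating the two lags.

## What the generators do and do not emulate

The schedules reproduce the structure of the source experiments —
timing, amplitudes, valence assignments, threshold stochasticity — so a
passing test shows the circuit mechanisms (inhibitory selection,
reinforcement labeling, expectation-driven resetting) behave as claimed
under those conditions. They do not emulate sensory preprocessing, noisy
spike input, graded stimulus intensity, or trial-to-trial biological
variability beyond the detection threshold; conclusions about real
behavioral data are outside what these tests can support.

Two empirical departures from idealized expectations are worth knowing:

* the *neutral-S1 control* (prefix omitted) is not fully lag-independent:
  the thalamic trace of even a neutral S1 decays slowly ($A = 1$,
  ~50 ms) and keeps driving the TRN, so purely sensory forward masking
  leaves the short-lag control rate intermediate — well above the
  conditioned short-lag rate but below the long-lag ceiling. The
  emotional effect proper is the large gap between the conditioned and
  neutral short-lag rates, which is what the test suite asserts.
* detection is *not monotone* in lag at intermediate values: an S2
  arriving ~300–400 ms after S1 onset meets the rebound of BA activity
  that follows the first stimulus-specific EV reset (the fear plan is
  still on and re-excites BA top-down), and can be suppressed more than
  at 100 ms. The short-vs-long contrast is unaffected.

## Numerical choices

* Forward Euler, $h = 10^{-4}$ s, synchronous updates: all drives are
  assembled from the previous state, then weights, then every population
  advances. This removes any dependence on within-step ordering.
* EV nonnegativity is a post-step clamp at 0; Heaviside gates are closed
  at exactly zero; the plan/attention argmax breaks ties toward the
  first (feed / lower-numbered) channel.
* The compiled (Rcpp) integrators mirror the scalar R reference steppers
  (`rate_step()`, `spiking_step()`) expression for expression, and the
  test suite asserts bit-for-bit agreement between the two over the
  miniature fixture — the reference, written as explicit loops straight
  from the model equations, is the package's correctness oracle.
* Traces record every 10th step (1 ms) by default; CSV output fixes
  floats at 9 significant digits so identical configurations yield
  byte-identical files.
* Non-finite activities abort the run naming the offending population.

## Analysis conventions

`plan_timeline()` labels a plan active when its cortical activity exceeds
1.0 (rate; activities saturate near 4.5) or 0.1 (spiking; postsynaptic
signals live in [0, 1]); classification is insensitive to this threshold
over at least [0.5, 2] in the rate model, which the tests assert. Label
runs shorter than 50 ms are treated as boundary flicker. Within-plan
attention switching is counted among the channels *relevant* to the
active plan (CS1/CS2 for feed, CS3 for fear) so that leakage of an
irrelevant channel through a reset window does not register as an
attention shift. Lesion phenotypes score plan switching over the
bottom-up testing phase and within-feed-plan attention switching over
both testing phases (the top-down phase holds the feed plan active long
enough for divided attention to express itself).

## Problem sizes

The test suite runs the full-size protocols (N = 10, 160000 steps;
rubbernecking 400000 steps) for the behavioral checks — each such run
takes well under a second with the compiled core — and a 3-channel,
4000-step miniature for the oracle-equivalence and serialization checks,
where the scalar R reference (three orders of magnitude slower) must also
run. Property-style checks use 50 random draws (shunting equilibrium) and
5 random spike trains (synaptic saturation) under fixed seeds.

## Known limitations

* The EV/reset pair is phenomenological; it does not learn expected
  reinforcement timing, and its parameters were taken as published, not
  fitted.
* Plan execution is not modeled — plan-cortex activation is where the
  model stops.
* The spiking variant's input-current calibration (`W_S`) is a package
  choice; other values in the explored range preserve spiking per se but
  lose one or another lesion contrast.
* Short-lag detection rates sit at the low end of the suppressed regime:
  the per-trial cortical peaks straddle the lower bound of the threshold
  distribution, so the scored rate is sensitive to protocol details
  (pairing count, trial spacing) that the source description does not
  pin down. `scripts/acceptance.R` reports the rates actually obtained
  for a given seed.
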