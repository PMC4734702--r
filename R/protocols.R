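# Experiment schedule builders. A schedule is a time-indexed description of
# all external inputs: rectangular stimulus pulses S_i, reinforcement
# pulses R_q, and tonic motivation drives M_q, plus epoch boundaries and
# the seed that generated any stochastic elements (distractors, detection
# thresholds). Step indices are 1-based; step s covers time ((s-1)h, sh].

new_schedule <- function(kind, n_steps, pulses, reinforcements, motivation,
                         epochs, n_channels, cs_channels, seed, extra = list()) {
  structure(
    c(
      list(
        kind = kind, n_steps = as.integer(n_steps), pulses = pulses,
        reinforcements = reinforcements, motivation = motivation,
        epochs = as.integer(epochs), n_channels = as.integer(n_channels),
        cs_channels = as.integer(cs_channels), seed = as.integer(seed)
      ),
      extra
    ),
    class = "amygate_schedule"
  )
}

#' @export
print.amygate_schedule <- function(x, ...) {
  cat(sprintf(
    "<amygate_schedule> %s: %d steps, %d channels, %d pulses, %d reinforcements, seed %d\n",
    x$kind, x$n_steps, x$n_channels, nrow(x$pulses), nrow(x$reinforcements), x$seed
  ))
  invisible(x)
}

.empty_pulses <- function() {
  tibble::tibble(
    channel = integer(0), onset = integer(0), duration = integer(0),
    amplitude = numeric(0), label = character(0)
  )
}

#' Pavlovian conditioning schedule
#'
#' Four equal epochs. Epoch 1 (appetitive conditioning): CS1 and CS2
#' alternate, `ep1_reps` presentations each; each pulse is followed, after
#' `r_delay` steps, by the appetitive reinforcer R1. Epoch 2 (aversive
#' conditioning): CS3 is presented `ep2_reps` times, each followed by the
#' aversive reinforcer R2. Epochs 3 and 4 (testing): the sequence
#' CS1-CS3-CS2-CS3 repeats with no reinforcement and with neutral
#' distractor pulses on non-CS channels; epoch 4 adds the configured tonic
#' motivation drives. Conditioned stimuli never overlap in time.
#'
#' Distractor channels and onsets are drawn uniformly (non-CS channels,
#' onsets within the testing epochs) from a generator seeded by `seed`, so
#' the schedule is fully reproducible.
#'
#' @param n_channels Sensory channels `N` (must be at least 3).
#' @param seed Integer seed for the distractor draws.
#' @param n_distractors Number of distractor pulses across both testing
#'   epochs.
#' @param motivation Length-2 numeric, the tonic drive `(M1, M2)` applied
#'   during testing phase 2 (epoch 4); the operating value is 160.
#' @param epoch_steps Steps per epoch (default 40000; total 160000 steps of
#'   `h = 1e-4` s, i.e. 16 s).
#' @param cs_duration,r_duration Stimulus and reinforcement pulse durations
#'   in steps (1000 and 750).
#' @param r_delay Delay from CS offset to reinforcement onset (250 steps).
#' @param distractor_duration Distractor pulse duration (600 steps).
#' @param ep1_reps Presentations of each of CS1, CS2 in epoch 1.
#' @param ep2_reps Presentations of CS3 in epoch 2.
#' @param test_cycles Repetitions of the CS1-CS3-CS2-CS3 block per testing
#'   epoch.
#' @param amplitude Pulse amplitude (1).
#' @return An `amygate_schedule`.
#' @examples
#' sched <- build_pavlovian_schedule(seed = 1)
#' sched$epochs
#' @export
build_pavlovian_schedule <- function(n_channels = 10, seed = 1L,
                                     n_distractors = 6,
                                     motivation = c(0, 0),
                                     epoch_steps = 40000L,
                                     cs_duration = 1000L, r_duration = 750L,
                                     r_delay = 250L,
                                     distractor_duration = 600L,
                                     ep1_reps = 4L, ep2_reps = 8L,
                                     test_cycles = 5L,
                                     amplitude = 1) {
  if (n_channels < 3) {
    stop("the protocol needs at least 3 sensory channels for CS1-CS3", call. = FALSE)
  }
  stopifnot(length(motivation) == 2, epoch_steps >= 1)
  epoch_steps <- as.integer(epoch_steps)
  cs_duration <- as.integer(cs_duration)
  r_duration <- as.integer(r_duration)
  r_delay <- as.integer(r_delay)
  distractor_duration <- as.integer(distractor_duration)
  cs <- c(1L, 2L, 3L)

  place <- function(k, slot, slot0, need) {
    # centre the CS(+reinforcer) block inside its slot
    pad <- max(0L, (slot - need) %/% 2L)
    slot0 + (k - 1L) * slot + pad + 1L
  }

  pulses <- list(); reinf <- list()
  # epoch 1: CS1/CS2 alternation, each followed by R1
  n1 <- 2L * ep1_reps
  slot1 <- epoch_steps %/% n1
  need1 <- cs_duration + r_delay + r_duration
  for (k in seq_len(n1)) {
    ch <- if (k %% 2L == 1L) 1L else 2L
    on <- place(k, slot1, 0L, need1)
    pulses[[length(pulses) + 1]] <- tibble::tibble(
      channel = ch, onset = on, duration = cs_duration,
      amplitude = amplitude, label = paste0("CS", ch)
    )
    reinf[[length(reinf) + 1]] <- tibble::tibble(
      q = 1L, onset = on + cs_duration + r_delay, duration = r_duration
    )
  }
  # epoch 2: CS3 followed by R2
  slot2 <- epoch_steps %/% ep2_reps
  for (k in seq_len(ep2_reps)) {
    on <- place(k, slot2, epoch_steps, need1)
    pulses[[length(pulses) + 1]] <- tibble::tibble(
      channel = 3L, onset = on, duration = cs_duration,
      amplitude = amplitude, label = "CS3"
    )
    reinf[[length(reinf) + 1]] <- tibble::tibble(
      q = 2L, onset = on + cs_duration + r_delay, duration = r_duration
    )
  }
  # epochs 3-4: CS1-CS3-CS2-CS3, no reinforcement
  test_seq <- c(1L, 3L, 2L, 3L)
  n_test <- 4L * test_cycles
  slot3 <- epoch_steps %/% n_test
  for (ep in c(2L, 3L)) { # 0-based epoch index of testing phases
    for (k in seq_len(n_test)) {
      ch <- test_seq[(k - 1L) %% 4L + 1L]
      on <- place(k, slot3, ep * epoch_steps, cs_duration)
      pulses[[length(pulses) + 1]] <- tibble::tibble(
        channel = ch, onset = on, duration = cs_duration,
        amplitude = amplitude, label = paste0("CS", ch)
      )
    }
  }
  pulses <- dplyr::bind_rows(pulses)
  reinf <- dplyr::bind_rows(reinf)

  # distractors: uniformly random non-CS channels and onsets in epochs 3-4
  if (n_distractors > 0) {
    free <- setdiff(seq_len(n_channels), cs)
    if (length(free) == 0) {
      stop("no non-CS channels available for distractors; set n_distractors = 0",
        call. = FALSE
      )
    }
    d <- withr::with_seed(seed, {
      tibble::tibble(
        channel = as.integer(sample(free, n_distractors, replace = TRUE)),
        onset = as.integer(floor(runif(
          n_distractors,
          min = 2 * epoch_steps + 1,
          max = 4 * epoch_steps - distractor_duration
        ))),
        duration = as.integer(distractor_duration),
        amplitude = amplitude, label = "distractor"
      )
    })
    pulses <- dplyr::bind_rows(pulses, d)
  }

  motiv <- tibble::tibble(
    onset = 3L * epoch_steps + 1L, duration = epoch_steps,
    M1 = motivation[1], M2 = motivation[2]
  )
  new_schedule(
    "pavlovian", 4L * epoch_steps, pulses, reinf, motiv,
    epochs = c(0L, 1L, 2L, 3L) * epoch_steps + 1L,
    n_channels = n_channels, cs_channels = cs, seed = seed
  )
}

#' Emotion-induced blindness (attentional rubbernecking) schedule
#'
#' A conditioning prefix pairs stimulus S1 with the aversive reinforcer R2
#' (`n_pairings` pairings, evenly spaced over `cond_steps`), then a testing
#' span presents `n_trials` two-stimulus trials: an S1 pulse, a gap of
#' `lag_steps`, then the neutral target S2. One detection threshold per
#' trial is drawn from a uniform distribution on `threshold_range`. With
#' `conditioned = FALSE` the prefix timing is kept but no pairings are
#' delivered, so S1 stays neutral (the control condition).
#'
#' @param lag_steps Gap between S1 offset and S2 onset, in steps (500 =
#'   50 ms short lag; 4000 = 400 ms long lag).
#' @param n_trials Number of detection trials (20).
#' @param seed Integer seed for the threshold draws.
#' @param conditioned Pair S1 with the aversive reinforcer in the prefix?
#' @param n_channels Sensory channels.
#' @param s1_channel,s2_channel Channels carrying S1 and S2.
#' @param cond_steps Conditioning prefix length (200000 steps = 20 s).
#' @param trial_steps Steps allotted per testing trial (10000; 20 trials
#'   span 200000 steps).
#' @param n_pairings S1-R2 pairings in the prefix.
#' @param cs_duration,r_duration,r_delay Pulse geometry as in the Pavlovian
#'   schedule (stimuli last 1000 steps = 100 ms).
#' @param threshold_range Bounds of the per-trial detection threshold draw.
#' @param amplitude Pulse amplitude.
#' @return An `amygate_schedule` with a `trials` tibble field (columns
#'   `trial`, `s1_onset`, `s2_onset`, `s2_offset`, `threshold`).
#' @export
build_rubbernecking_schedule <- function(lag_steps, n_trials = 20L, seed = 1L,
                                         conditioned = TRUE,
                                         n_channels = 10, s1_channel = 1L,
                                         s2_channel = 2L,
                                         cond_steps = 200000L,
                                         trial_steps = 10000L,
                                         n_pairings = 8L,
                                         cs_duration = 1000L,
                                         r_duration = 750L, r_delay = 250L,
                                         threshold_range = c(0.05, 0.35),
                                         amplitude = 1) {
  stopifnot(lag_steps > 0, n_trials >= 1, s1_channel != s2_channel)
  lag_steps <- as.integer(lag_steps)
  n_trials <- as.integer(n_trials)
  cond_steps <- as.integer(cond_steps)
  trial_steps <- as.integer(trial_steps)
  cs_duration <- as.integer(cs_duration)
  r_duration <- as.integer(r_duration)
  r_delay <- as.integer(r_delay)
  pulses <- list(); reinf <- list()
  if (conditioned) {
    slot <- cond_steps %/% n_pairings
    need <- cs_duration + r_delay + r_duration
    pad <- max(0L, (slot - need) %/% 2L)
    for (k in seq_len(n_pairings)) {
      on <- (k - 1L) * slot + pad + 1L
      pulses[[length(pulses) + 1]] <- tibble::tibble(
        channel = as.integer(s1_channel), onset = on, duration = cs_duration,
        amplitude = amplitude, label = "S1"
      )
      reinf[[length(reinf) + 1]] <- tibble::tibble(
        q = 2L, onset = on + cs_duration + r_delay, duration = r_duration
      )
    }
  }
  trial_need <- 2L * cs_duration + lag_steps
  if (trial_need > trial_steps) {
    stop("lag too long for the trial slot: need ", trial_need,
      " steps but trial_steps = ", trial_steps,
      call. = FALSE
    )
  }
  pad <- max(0L, (trial_steps - trial_need) %/% 4L)
  trials <- withr::with_seed(seed, {
    tibble::tibble(
      trial = seq_len(n_trials),
      s1_onset = cond_steps + (seq_len(n_trials) - 1L) * trial_steps + pad + 1L,
      threshold = runif(n_trials, threshold_range[1], threshold_range[2])
    )
  })
  trials$s2_onset <- trials$s1_onset + as.integer(cs_duration) + as.integer(lag_steps)
  trials$s2_offset <- trials$s2_onset + as.integer(cs_duration) - 1L
  for (k in seq_len(n_trials)) {
    pulses[[length(pulses) + 1]] <- tibble::tibble(
      channel = as.integer(s1_channel), onset = trials$s1_onset[k],
      duration = cs_duration, amplitude = amplitude, label = "S1"
    )
    pulses[[length(pulses) + 1]] <- tibble::tibble(
      channel = as.integer(s2_channel), onset = trials$s2_onset[k],
      duration = cs_duration, amplitude = amplitude, label = "S2"
    )
  }
  pulses <- dplyr::bind_rows(pulses)
  reinf <- if (length(reinf) > 0) dplyr::bind_rows(reinf) else {
    tibble::tibble(q = integer(0), onset = integer(0), duration = integer(0))
  }
  n_steps <- cond_steps + n_trials * trial_steps
  motiv <- tibble::tibble(
    onset = integer(0), duration = integer(0), M1 = numeric(0), M2 = numeric(0)
  )
  new_schedule(
    "rubbernecking", n_steps, pulses, reinf, motiv,
    epochs = c(1L, cond_steps + 1L),
    n_channels = n_channels, cs_channels = c(s1_channel, s2_channel),
    seed = seed,
    extra = list(
      trials = trials, lag_steps = as.integer(lag_steps),
      s1_channel = as.integer(s1_channel), s2_channel = as.integer(s2_channel),
      conditioned = conditioned
    )
  )
}

#' Expand a schedule into per-step drive matrices
#'
#' @param schedule An `amygate_schedule`.
#' @return List with `S` (`n_steps x N`), `R` (`n_steps x 2`) and `M`
#'   (`n_steps x 2`) matrices.
#' @export
schedule_matrices <- function(schedule) {
  n <- schedule$n_steps
  N <- schedule$n_channels
  S <- matrix(0, n, N)
  R <- matrix(0, n, 2)
  M <- matrix(0, n, 2)
  pu <- schedule$pulses
  for (k in seq_len(nrow(pu))) {
    a <- pu$onset[k]
    b <- min(n, pu$onset[k] + pu$duration[k] - 1L)
    if (a <= n) S[a:b, pu$channel[k]] <- S[a:b, pu$channel[k]] + pu$amplitude[k]
  }
  re <- schedule$reinforcements
  for (k in seq_len(nrow(re))) {
    a <- re$onset[k]
    b <- min(n, re$onset[k] + re$duration[k] - 1L)
    if (a <= n) R[a:b, re$q[k]] <- 1
  }
  mo <- schedule$motivation
  for (k in seq_len(nrow(mo))) {
    a <- mo$onset[k]
    b <- min(n, mo$onset[k] + mo$duration[k] - 1L)
    if (a <= n) {
      M[a:b, 1] <- mo$M1[k]
      M[a:b, 2] <- mo$M2[k]
    }
  }
  list(S = S, R = R, M = M)
}
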