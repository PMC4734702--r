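# Trace analysis: plan timelines, attention summaries, lesion phenotype
# classification, and detection scoring for the emotion-induced-blindness
# paradigm. All functions take a trace tibble first and return tibble-based
# results.

.trace_steps <- function(trace) {
  as.integer(round(trace$time / attr(trace, "h")))
}

.default_plan_threshold <- function(trace) {
  # plan-cortex activity is ~4.5 (rate, bounded by B = 10) when a plan is
  # active, ~0 otherwise; the spiking analog g_PC lives in [0, 1]
  if (identical(attr(trace, "variant"), "spiking")) 0.1 else 1.0
}

.default_attention_threshold <- function(trace) {
  if (identical(attr(trace, "variant"), "spiking")) 0.05 else 0.1
}

# collapse a label sequence into runs, dropping runs shorter than min_len
.debounced_runs <- function(labels, min_len) {
  r <- rle(labels)
  keep <- r$lengths >= min_len
  vals <- r$values[keep]
  lens <- r$lengths[keep]
  ends <- cumsum(r$lengths)[keep]
  if (length(vals) == 0) {
    return(tibble::tibble(
      label = character(0), start = integer(0), end = integer(0)
    ))
  }
  # merge adjacent equal labels left after dropping glitches
  m <- rle(vals)
  idx <- cumsum(m$lengths)
  starts0 <- ends - lens + 1L
  tibble::tibble(
    label = m$values,
    start = starts0[c(1L, head(idx, -1) + 1L)],
    end = ends[idx]
  )
}

#' Plan-activation timeline of a trace
#'
#' Labels every recorded step with the active behavioral plan: the
#' plan-cortex unit with the larger activity, provided it exceeds the
#' activation threshold, else `none`. Switches are counted on transitions
#' between `feed` and `fear` (ignoring `none` gaps), after removing label
#' runs shorter than `min_dwell` seconds (transient flicker at reset
#' boundaries, spiking-synapse ripple).
#'
#' @param trace An `amygate_trace`.
#' @param activation_threshold Activity level above which a plan counts as
#'   active. Default 1.0 for rate traces (activities up to B = 10), 0.1
#'   for spiking traces (postsynaptic signals in `[0, 1]`). Classification
#'   is insensitive to this choice over a broad range.
#' @param min_dwell Minimum dwell time (s) for a plan label to count.
#' @param t_range Optional length-2 time window (s) to restrict scoring.
#' @return A `plan_timeline` object: list with `timeline` (tibble: time,
#'   active), `periods` (tibble: label, t_start, t_end), `switches`
#'   (count), `occupancy` (named fractions of scored time).
#' @export
plan_timeline <- function(trace, activation_threshold = NULL,
                          min_dwell = 0.05, t_range = NULL) {
  thr <- activation_threshold %||% .default_plan_threshold(trace)
  stopifnot(thr > 0)
  tt <- trace
  if (!is.null(t_range)) tt <- tt[tt$time > t_range[1] & tt$time <= t_range[2], ]
  pc1 <- tt$x_PC.q1
  pc2 <- tt$x_PC.q2
  lab <- ifelse(pmax(pc1, pc2) < thr, "none", ifelse(pc1 >= pc2, "feed", "fear"))
  dt <- attr(trace, "h") * attr(trace, "record_stride")
  min_len <- max(1L, as.integer(ceiling(min_dwell / dt)))
  active_rows <- which(lab != "none")
  runs <- .debounced_runs(lab[active_rows], min_len)
  if (nrow(runs) > 0) {
    runs$t_start <- tt$time[active_rows[runs$start]]
    runs$t_end <- tt$time[active_rows[runs$end]]
  } else {
    runs$t_start <- numeric(0)
    runs$t_end <- numeric(0)
  }
  occ <- c(
    feed = mean(lab == "feed"), fear = mean(lab == "fear"),
    none = mean(lab == "none")
  )
  structure(
    list(
      timeline = tibble::tibble(time = tt$time, active = lab),
      periods = runs[, c("label", "t_start", "t_end", "start", "end")],
      switches = if (nrow(runs) > 1) sum(runs$label[-1] != runs$label[-nrow(runs)]) else 0L,
      occupancy = occ,
      threshold = thr,
      min_dwell = min_dwell
    ),
    class = "plan_timeline"
  )
}

#' @export
print.plan_timeline <- function(x, ...) {
  cat(sprintf(
    "<plan_timeline> %d plan periods, %d switches; occupancy feed %.2f / fear %.2f / none %.2f\n",
    nrow(x$periods), x$switches, x$occupancy["feed"], x$occupancy["fear"],
    x$occupancy["none"]
  ))
  invisible(x)
}

#' @export
tidy.plan_timeline <- function(x, ...) x$timeline

#' @export
glance.plan_timeline <- function(x, ...) {
  tibble::tibble(
    switches = x$switches,
    occupancy_feed = x$occupancy[["feed"]],
    occupancy_fear = x$occupancy[["fear"]],
    occupancy_none = x$occupancy[["none"]],
    threshold = x$threshold
  )
}

# attended channel per recorded row among the CS channels
.attended_channel <- function(trace, channels, threshold) {
  sc <- as.matrix(trace[, paste0("x_SC.i", channels), drop = FALSE])
  top <- max.col(sc, ties.method = "first")
  ifelse(sc[cbind(seq_len(nrow(sc)), top)] > threshold, channels[top], 0L)
}

#' Attention summary of a trace
#'
#' Quantifies sensory attention: the time-integrated sensory-cortical
#' activity of each conditioned stimulus' channel over each of its
#' presentation windows (elevated cortical activity = attention), and the
#' number of attended-stimulus changes within each contiguous plan period
#' (within-plan attentional flexibility).
#'
#' @inheritParams plan_timeline
#' @param attention_threshold Sensory-cortical activity above which a
#'   channel counts as attended.
#' @param plan Optionally a precomputed [plan_timeline()] for the same
#'   trace (computed if missing).
#' @return An `attention_summary` object: list with `presentations`
#'   (tibble: label, channel, onset_time, integral), `within_plan`
#'   (tibble: plan label, period times, attended switches).
#' @export
attention_summary <- function(trace, activation_threshold = NULL,
                              attention_threshold = NULL,
                              plan = NULL, t_range = NULL) {
  schedule <- attr(trace, "schedule")
  if (is.null(schedule)) stop("trace carries no embedded schedule", call. = FALSE)
  athr <- attention_threshold %||% .default_attention_threshold(trace)
  plan <- plan %||% plan_timeline(trace, activation_threshold, t_range = t_range)
  h <- attr(trace, "h")
  dt <- h * attr(trace, "record_stride")
  steps <- .trace_steps(trace)

  cs <- schedule$pulses[schedule$pulses$label != "distractor", ]
  pres <- purrr::map_dfr(seq_len(nrow(cs)), function(k) {
    a <- cs$onset[k]
    b <- cs$onset[k] + cs$duration[k] - 1L
    w <- steps >= a & steps <= b
    col <- paste0("x_SC.i", cs$channel[k])
    if (!col %in% names(trace)) {
      stop("channel ", cs$channel[k], " missing from trace", call. = FALSE)
    }
    tibble::tibble(
      label = cs$label[k], channel = cs$channel[k],
      onset_time = a * h,
      integral = sum(pmax(trace[[col]][w], 0)) * dt
    )
  })
  if (!is.null(t_range)) {
    pres <- pres[pres$onset_time > t_range[1] & pres$onset_time <= t_range[2], ]
  }

  att <- .attended_channel(trace, schedule$cs_channels, athr)
  min_len <- max(1L, as.integer(ceiling(plan$min_dwell / dt)))
  # stimuli relevant to each plan: the appetitively conditioned channels
  # for feed, the aversively conditioned channel for fear
  relevant <- list(
    feed = unique(cs$channel[cs$label %in% c("CS1", "CS2", "S2")]),
    fear = unique(cs$channel[cs$label %in% c("CS3", "S1")])
  )
  within <- purrr::map_dfr(seq_len(nrow(plan$periods)), function(k) {
    per <- plan$periods[k, ]
    w <- trace$time >= per$t_start & trace$time <= per$t_end
    aw <- att[w]
    aw <- aw[aw %in% relevant[[per$label]]]
    runs <- .debounced_runs(as.character(aw), min_len)
    tibble::tibble(
      plan = per$label, t_start = per$t_start, t_end = per$t_end,
      attended_switches = if (nrow(runs) > 1) {
        sum(runs$label[-1] != runs$label[-nrow(runs)])
      } else 0L
    )
  })
  structure(
    list(presentations = pres, within_plan = within, threshold = athr),
    class = "attention_summary"
  )
}

#' @export
print.attention_summary <- function(x, ...) {
  cat(sprintf(
    "<attention_summary> %d presentations scored; within-plan attended switches: %d\n",
    nrow(x$presentations), sum(x$within_plan$attended_switches)
  ))
  invisible(x)
}

#' @export
tidy.attention_summary <- function(x, ...) x$presentations

#' @export
glance.attention_summary <- function(x, ...) {
  agg <- dplyr::summarise(
    dplyr::group_by(x$presentations, .data$label),
    mean_integral = mean(.data$integral), .groups = "drop"
  )
  out <- tidyr::pivot_wider(
    agg,
    names_from = "label", values_from = "mean_integral", names_prefix = "mean_"
  )
  out$attended_switches <- sum(x$within_plan$attended_switches)
  out$feed_plan_attended_switches <-
    sum(x$within_plan$attended_switches[x$within_plan$plan == "feed"])
  out
}

#' Classify lesion phenotypes across matched runs
#'
#' Given traces of the same schedule under different interneuron lesion
#' conditions, classifies each run from its plan-switch count and its
#' within-feed-plan attended-stimulus switch count (both scored over the
#' first testing phase, where behavior is bottom-up):
#' `flexible` (both kinds of switching), `plan-rigid` (no plan switches
#' after the first plan onset, attention still shifts), `attention-rigid`
#' (plans shift, attention fixed within feed-plan periods), `fully-rigid`
#' (neither).
#'
#' @param traces Named list of `amygate_trace` objects sharing one
#'   schedule (e.g. intact, plan lesion, BA lesion, both).
#' Plan switching is scored over the first testing phase (bottom-up mode,
#' where an intact system re-decides after each reset); within-feed-plan
#' attention switching is scored over the whole testing span, which
#' includes the top-down phase where the feed plan is held active long
#' enough for attention to alternate between both food-predicting stimuli.
#'
#' @param activation_threshold,attention_threshold See [plan_timeline()]
#'   and [attention_summary()].
#' @param t_plan Scoring window (s) for plan switches; defaults to the
#'   first testing phase of the embedded Pavlovian schedule.
#' @param t_attention Scoring window (s) for within-plan attended
#'   switches; defaults to both testing phases.
#' @return Tibble: condition, plan_switches, feed_attended_switches,
#'   phenotype.
#' @export
lesion_phenotype <- function(traces, activation_threshold = NULL,
                             attention_threshold = NULL, t_plan = NULL,
                             t_attention = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1)
  scheds <- purrr::map(traces, attr, "schedule")
  ref <- scheds[[1]]
  same <- purrr::map_lgl(scheds, function(s) {
    identical(s$n_steps, ref$n_steps) && identical(s$seed, ref$seed) &&
      identical(s$kind, ref$kind) && identical(s$pulses, ref$pulses)
  })
  if (!all(same)) {
    stop("lesion runs must share one schedule (same kind, length, seed)",
      call. = FALSE
    )
  }
  h <- attr(traces[[1]], "h")
  ep <- ref$epochs
  if (is.null(t_plan)) {
    t_plan <- if (length(ep) >= 4) c(ep[3] - 1, ep[4] - 1) * h else c(0, ref$n_steps * h)
  }
  if (is.null(t_attention)) {
    t_attention <- if (length(ep) >= 4) c(ep[3] - 1, ref$n_steps) * h else c(0, ref$n_steps * h)
  }
  purrr::map_dfr(names(traces), function(nm) {
    tr <- traces[[nm]]
    pl <- plan_timeline(tr, activation_threshold, t_range = t_plan)
    at <- attention_summary(tr, activation_threshold, attention_threshold,
      plan = plan_timeline(tr, activation_threshold, t_range = t_attention),
      t_range = t_attention
    )
    psw <- pl$switches
    asw <- sum(at$within_plan$attended_switches[at$within_plan$plan == "feed"])
    tibble::tibble(
      condition = nm,
      plan_switches = psw,
      feed_attended_switches = asw,
      phenotype = dplyr::case_when(
        psw > 0 & asw > 0 ~ "flexible",
        psw == 0 & asw > 0 ~ "plan-rigid",
        psw > 0 & asw == 0 ~ "attention-rigid",
        TRUE ~ "fully-rigid"
      )
    )
  })
}

#' Run the four-condition lesion experiment
#'
#' Simulates one Pavlovian schedule under the four interneuron-lesion
#' conditions (intact, plan-cortex lesion, BA lesion, both) and classifies
#' the phenotypes.
#'
#' @param params A [rate_params()] or [spiking_params()] object (slow reset
#'   is the operating condition for these experiments).
#' @param seed Schedule seed.
#' @param motivation Testing-phase-2 drive, default `c(160, 0)` (feed bias).
#' @param record_stride Recording stride (steps).
#' @param ... Passed to [build_pavlovian_schedule()].
#' @return List with `phenotypes` (classification tibble) and `traces`.
#' @export
run_lesion_suite <- function(params = rate_params(reset = "slow"), seed = 1L,
                             motivation = c(160, 0), record_stride = 10L, ...) {
  sched <- build_pavlovian_schedule(
    n_channels = params$N, seed = seed,
    motivation = motivation, ...
  )
  conds <- list(
    intact = lesion_config(),
    plan_lesion = lesion_config(plan_interneurons = TRUE),
    ba_lesion = lesion_config(ba_interneurons = TRUE),
    both = lesion_config(TRUE, TRUE)
  )
  traces <- purrr::map(conds, function(l) {
    simulate(sched, params, lesion = l, record_stride = record_stride)
  })
  list(phenotypes = lesion_phenotype(traces), traces = traces)
}

#' Score stimulus detection over rubbernecking trials
#'
#' A trial counts as detected when the sensory-cortical activity of the
#' target's channel strictly exceeds the trial's threshold at any recorded
#' step of the target window (onset to offset).
#'
#' @param trace An `amygate_trace` from a rubbernecking schedule.
#' @param trials Trial table (tibble with `s2_onset`, `s2_offset`,
#'   `threshold`); defaults to the table embedded in the trace's schedule.
#' @param channel Target channel; defaults to the schedule's `s2_channel`.
#' @return A `detection_result`: list with `trials` (tibble adding `peak`,
#'   `detected`) and `rate` (fraction detected in `[0, 1]`).
#' @export
score_detection <- function(trace, trials = NULL, channel = NULL) {
  schedule <- attr(trace, "schedule")
  trials <- trials %||% schedule$trials
  if (is.null(trials)) stop("no trial table available", call. = FALSE)
  channel <- channel %||% schedule$s2_channel
  col <- paste0("x_SC.i", channel)
  if (!col %in% names(trace)) {
    stop("channel ", channel, " missing from trace", call. = FALSE)
  }
  steps <- .trace_steps(trace)
  if (max(trials$s2_offset) > max(steps)) {
    stop("trace does not cover all trial windows", call. = FALSE)
  }
  x <- trace[[col]]
  res <- purrr::map_dfr(seq_len(nrow(trials)), function(k) {
    w <- steps >= trials$s2_onset[k] & steps <= trials$s2_offset[k]
    peak <- max(x[w])
    tibble::tibble(peak = peak, detected = peak > trials$threshold[k])
  })
  out <- dplyr::bind_cols(trials, res)
  structure(
    list(trials = out, rate = mean(out$detected)),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %d trials, %.0f%% detected\n",
    nrow(x$trials), 100 * x$rate
  ))
  invisible(x)
}

#' @export
tidy.detection_result <- function(x, ...) x$trials

#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials), detected = sum(x$trials$detected),
    rate = x$rate
  )
}

#' Run one emotion-induced-blindness experiment
#'
#' Builds the rubbernecking schedule for a lag, simulates it (fast plan
#' resetting is the operating condition), and scores detection.
#'
#' @param lag_steps Lag between S1 offset and S2 onset, in steps.
#' @param seed Seed for the per-trial threshold draws.
#' @param params Model parameters; default fast-reset rate model.
#' @param conditioned Pair S1 with the aversive reinforcer in the prefix?
#' @param n_trials Number of trials.
#' @param record_stride Recording stride.
#' @param ... Passed to [build_rubbernecking_schedule()].
#' @return List with `trace`, `detection` (a `detection_result`), `rate`,
#'   `lag_steps`, `seed`.
#' @export
run_rubbernecking <- function(lag_steps, seed = 1L,
                              params = rate_params(reset = "fast"),
                              conditioned = TRUE, n_trials = 20L,
                              record_stride = 10L, ...) {
  sched <- build_rubbernecking_schedule(
    lag_steps = lag_steps, n_trials = n_trials, seed = seed,
    conditioned = conditioned, n_channels = params$N, ...
  )
  tr <- simulate(sched, params, record_stride = record_stride)
  det <- score_detection(tr)
  list(
    trace = tr, detection = det, rate = det$rate,
    lag_steps = lag_steps, seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
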