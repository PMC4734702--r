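# Simulation front end: expands a schedule into drive matrices, runs the
# requested integrator, and wraps the recorded matrix as a tibble trace
# carrying its provenance (schedule, parameters, lesions, step size) as
# attributes.

new_trace <- function(mat, colnames, variant, schedule, params, lesion,
                      h, record_stride, spikes = NULL) {
  colnames(mat) <- colnames
  tr <- tibble::as_tibble(mat)
  class(tr) <- c("amygate_trace", class(tr))
  attr(tr, "variant") <- variant
  attr(tr, "schedule") <- schedule
  attr(tr, "params") <- params
  attr(tr, "lesion") <- lesion
  attr(tr, "h") <- h
  attr(tr, "record_stride") <- as.integer(record_stride)
  if (!is.null(spikes)) attr(tr, "spikes") <- tibble::as_tibble(spikes)
  tr
}

#' Run a simulation
#'
#' Integrates the circuit over a schedule from the all-zero (rate) or
#' resting (spiking) initial condition with the forward Euler method, and
#' returns the recorded trace. The `engine` selects the compiled core
#' (`"fast"`) or the scalar R reference stepper (`"reference"`); the two
#' produce identical results and the reference serves as the oracle in the
#' test suite.
#'
#' @param schedule An `amygate_schedule` from [build_pavlovian_schedule()]
#'   or [build_rubbernecking_schedule()].
#' @param params A [rate_params()] or [spiking_params()] object; its
#'   variant decides which model runs.
#' @param lesion A [lesion_config()].
#' @param h Euler step size in seconds (1e-4).
#' @param record_stride Record every this-many steps (10, i.e. 1 ms).
#' @param engine `"fast"` (compiled) or `"reference"` (scalar R loops).
#' @return An `amygate_trace` tibble: one row per recorded step, columns
#'   named by model symbol with subgroup/channel suffixes (e.g.
#'   `x_BA.q1.i3`), plus the schedule columns `S.i*`, `R.q*`, `M.q*`.
#'   Spiking traces additionally carry `v_*`/`u_*` columns and a spike
#'   raster in `attr(trace, "spikes")`.
#' @examples
#' \donttest{
#' sched <- build_pavlovian_schedule(n_channels = 3, seed = 1,
#'   n_distractors = 0, epoch_steps = 1000, cs_duration = 200,
#'   r_duration = 150, r_delay = 50, ep1_reps = 2, ep2_reps = 4,
#'   test_cycles = 1)
#' tr <- simulate(sched, rate_params(N = 3))
#' }
#' @export
simulate <- function(schedule, params, lesion = lesion_config(),
                     h = 1e-4, record_stride = 10L,
                     engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(schedule, "amygate_schedule"), inherits(params, "amygate_params"))
  if (schedule$n_channels != params$N) {
    stop("schedule has ", schedule$n_channels, " channels but params$N = ",
      params$N,
      call. = FALSE
    )
  }
  if (schedule$n_steps < 1) stop("schedule must cover at least 1 step", call. = FALSE)
  m <- schedule_matrices(schedule)
  variant <- attr(params, "variant")
  if (variant == "rate") {
    st0 <- rate_state0(params$N)
    res <- if (engine == "fast") {
      run_rate_cpp(
        unclass(params), lesion$ba_interneurons, lesion$plan_interneurons,
        m$S, m$R, m$M, st0, h, as.integer(record_stride)
      )
    } else {
      .run_rate_reference(params, lesion, m$S, m$R, m$M, st0, h, record_stride)
    }
    tr <- new_trace(
      res$trace, .trace_colnames_rate(params$N), "rate",
      schedule, params, lesion, h, record_stride
    )
  } else {
    st0 <- spiking_state0(params$N, params)
    res <- if (engine == "fast") {
      run_spiking_cpp(
        unclass(params), lesion$ba_interneurons, lesion$plan_interneurons,
        m$S, m$R, m$M, st0, h, as.integer(record_stride)
      )
    } else {
      .run_spiking_reference(params, lesion, m$S, m$R, m$M, st0, h, record_stride)
    }
    tr <- new_trace(
      res$trace, .trace_colnames_spiking(params$N), "spiking",
      schedule, params, lesion, h, record_stride, spikes = res$spikes
    )
  }
  attr(tr, "final_state") <- res$state
  tr
}

#' @export
print.amygate_trace <- function(x, ...) {
  cat(sprintf(
    "<amygate_trace> %s model, %d recorded steps (stride %d, h = %g s), %d columns\n",
    attr(x, "variant"), nrow(x), attr(x, "record_stride"), attr(x, "h"), ncol(x)
  ))
  NextMethod()
}

#' Spike raster of a spiking trace
#'
#' @param trace A spiking `amygate_trace`.
#' @return Tibble with columns `time` (s), `population`, `q`, `channel`.
#' @export
spike_raster <- function(trace) {
  spk <- attr(trace, "spikes")
  if (is.null(spk)) stop("trace carries no spike raster (rate model?)", call. = FALSE)
  h <- attr(trace, "h")
  tibble::tibble(
    time = spk$step * h,
    population = .spike_pop_names[spk$pop],
    q = spk$q,
    channel = spk$channel
  )
}

#' Tidy a trace into long format
#'
#' @param x An `amygate_trace`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `variable` (symbol family),
#'   `q` (valence subgroup or NA), `channel` (or NA), `value`.
#' @export
tidy.amygate_trace <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x), -"time",
    names_to = "name", values_to = "value"
  )
  parts <- stringr_like_split(long$name)
  dplyr::bind_cols(long["time"], parts, long["value"])
}

# minimal column-name parser: "x_BA.q1.i3" -> variable x_BA, q 1, channel 3
stringr_like_split <- function(nm) {
  variable <- sub("\\..*$", "", nm)
  q <- rep(NA_integer_, length(nm))
  ch <- rep(NA_integer_, length(nm))
  mq <- regmatches(nm, regexpr("\\.q[12]", nm))
  has_q <- grepl("\\.q[12]", nm)
  q[has_q] <- as.integer(sub("\\.q", "", regmatches(nm, regexpr("\\.q[12]", nm))))
  has_i <- grepl("\\.i[0-9]+", nm)
  ch[has_i] <- as.integer(sub("\\.i", "", regmatches(nm, regexpr("\\.i[0-9]+", nm))))
  tibble::tibble(variable = variable, q = q, channel = ch)
}

#' One-row summary of a trace
#'
#' @param x An `amygate_trace`.
#' @param ... Unused.
#' @return Tibble with the run geometry and the final plastic-weight
#'   maxima.
#' @export
glance.amygate_trace <- function(x, ...) {
  fs <- attr(x, "final_state")
  tibble::tibble(
    variant = attr(x, "variant"),
    paradigm = attr(x, "schedule")$kind,
    n_steps = attr(x, "schedule")$n_steps,
    n_recorded = nrow(x),
    h = attr(x, "h"),
    seed = attr(x, "schedule")$seed,
    ba_lesion = attr(x, "lesion")$ba_interneurons,
    plan_lesion = attr(x, "lesion")$plan_interneurons,
    max_W_ST_LA = max(fs$WstLA),
    max_W_PC_BA = max(fs$WpcBA)
  )
}
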