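# Parameter tables for the rate-coded and spiking circuit variants.
# Each symbol keeps the notation used throughout the package's equations:
# W_<from>_<to> for fixed connection weights, Gamma_* for activation
# thresholds, A_* for passive decay rates, tau_* for integration time
# constants, B/C for the global shunting bounds.

.rate_weight_table <- function() {
  tibble::tribble(
    ~symbol,    ~value, ~lo,    ~hi,
    "W_SC_ST",   0.8,   0.01,   1.00,
    "W_ST_SC",   0.8,   0.01,   1.00,
    "W_SC_SR",   0.15,  0.01,   0.30,
    "W_ST_SR",   0.1,   0.01,   0.40,
    "W_SR_ST",   3,     1.50,   4.50,
    "W_SR_SR",   3,     1.50,   9.00,
    "W_BA_ST",   0.01,  0.001,  0.030,
    "W_BA_SC",   0.01,  0.001,  0.030,
    "W_BA_SR",   0.25,  0.125,  0.375,
    "W_PC_PT",   9,     6,      16,
    "W_PT_PC",   9,     6,      16,
    "W_PC_PR",   0.5,   0.05,   2.00,
    "W_PT_PR",   0.1,   0.01,   0.40,
    "W_PR_PT",   1,     0.10,   4.00,
    "W_PR_PR",   1,     0.10,   4.00,
    "W_BA_PT",   0.5,   0.05,   1.50,
    "W_BA_PC",   0.5,   0.05,   1.50,
    "W_BA_PR",   1,     0.01,   4.00,
    "W_LA_BA",   3,     2.25,   3.75,
    "W_yB",      30,    22.50,  45,
    "W_Lcy",     3,     0.03,   12,
    "W_Lvy",     1,     0.75,   1.50,
    "W_Lc",      5,     0.05,   10.00,
    "W_Lv",      1,     0.50,   1.10,
    "W_Ly",      5,     1.25,   12.50,
    "W_vv",      20,    15,     20,
    "W_yy",      80,    40,     80,
    "W_Lcv",     10,    1,      40,
    "W_Lyv",     10,    5,      40,
    "W_yP",      60,    45,     120,
    "W_Pcy",     5,     1.25,   15.00,
    "W_Pvy",     2,     1.50,   5.00,
    "W_Pc",      10,    1,      30,
    "W_Pv",      0.1,   0.075,  0.40,
    "W_Py",      1,     0.25,   1.25,
    "W_Pcv",     10,    1,      40,
    "W_Pyv",     8,     6,      20
  )
}

.rate_constant_table <- function(reset = "slow") {
  tibble::tribble(
    ~symbol,        ~value,
    "Gamma_PCB",    1,
    "Gamma_PCT",    0.10,
    "Gamma_L",      0.03,
    "Gamma_v",      0.10,
    "Gamma_yv",     0.10,
    "Gamma_y",      0.10,
    "Gamma_r",      1,
    "Gamma_P",      2,
    "Gamma_ST",     0.75,
    "Gamma_BA",     0.10,
    "B_ST_LA",      1,
    "B_PC_BA",      1,
    "tau_main",     0.05,
    "tau_w",        0.05,
    "tau_Lc_Pc",    0.25,
    "tau_Lv_Lvr",   3.33,
    "tau_Pv_Pvr",   if (reset == "slow") 12.50 else 2.50,
    "A_ST",         1,
    "A_SC_PC_LA_y", 100,
    "A_SR_PR_BA",   10,
    "A_PT",         5,
    "A_r",          200,
    "A_Lv_Pv",      0.2,
    "A_Lc_Pc",      3,
    "B",            10,
    "C",            10,
    "S_amp",        1,
    "R_amp",        1,
    "M_amp",        160
  )
}

.spiking_weight_table <- function() {
  tibble::tribble(
    ~symbol,    ~value, ~lo,    ~hi,
    "W_SC_ST",   40,    4,      160,
    "W_ST_SC",   40,    4,      160,
    "W_SC_SR",   1,     0.01,   4.00,
    "W_ST_SR",   1,     0.01,   4.00,
    "W_SR_ST",   100,   75,     200,
    "W_SR_SR",   80,    60,     240,
    "W_BA_ST",   0.3,   0.03,   1.20,
    "W_BA_SC",   0.3,   0.03,   1.20,
    "W_BA_SR",   80,    40,     120,
    "W_PC_PT",   200,   100,    300,
    "W_PT_PC",   200,   150,    220,
    "W_PC_PR",   100,   25,     300,
    "W_PT_PR",   10,    1,      40,
    "W_PR_PT",   16,    4,      20,
    "W_PR_PR",   16,    4,      64,
    "W_BA_PT",   20,    15,     25,
    "W_BA_PC",   5,     0.05,   20.00,
    "W_BA_PR",   12,    1.2,    48.0,
    "W_LA_BA",   100,   25,     400,
    "W_yB",      70,    60,     105,
    "W_Lcy",     50,    5,      200,
    "W_Lvy",     3,     2.25,   9.00,
    "W_Lc",      1,     0.1,    3.0,
    "W_Lv",      1,     0.9,    1.5,
    "W_Ly",      1,     0.50,   1.25,
    "W_vv",      5,     4.5,    7.5,
    "W_yy",      100,   50,     200,
    "W_Lcv",     25,    2.5,    75,
    "W_Lyv",     10,    5,      12.5,
    "W_yP",      180,   170,    360,
    "W_Pcy",     100,   25,     300,
    "W_Pvy",     10,    2.5,    20.0,
    "W_Pc",      0.1,   0.025,  0.300,
    "W_Pv",      1,     0.75,   2.00,
    "W_Py",      1,     0.25,   1.50,
    "W_Pcv",     25,    2.5,    100.00,
    "W_Pyv",     10,    5,      15
  )
}

.spiking_constant_table <- function(reset = "slow") {
  tibble::tribble(
    ~symbol,        ~value,
    "Gamma_PCB",    0,
    "Gamma_PCT",    0,
    "Gamma_L",      0.1,
    "Gamma_v",      0.1,
    "Gamma_yv",     0.1,
    "Gamma_y",      0.1,
    "Gamma_r",      1.0,
    "Gamma_P",      0.5,
    "Gamma_ST",     0,
    "Gamma_BA",     0,
    "B_ST_LA",      100,
    "B_PC_BA",      40,
    "tau_w",        0.025,
    "tau_s",        0.001,
    "tau_Lc_Pc",    0.25,
    "tau_Lv_Lvr",   3.33,
    "tau_Pv_Pvr",   if (reset == "slow") 10 else 1.33,
    "tau_rise",     0.004,
    "tau_fall",     0.040,
    # Expectation-related signals keep the rate-model decay rates and
    # shunting bounds (they use the same class of bounded equations).
    "A_r",          200,
    "A_Lv_Pv",      0.2,
    "A_Lc_Pc",      3,
    "B",            10,
    "C",            10,
    # Izhikevich cell classes: regular-spiking principal cells and
    # fast-spiking interneurons (a, b, c, d).
    "izh_rs_a",     0.02,
    "izh_rs_b",     0.2,
    "izh_rs_c",     -65,
    "izh_rs_d",     8,
    "izh_fs_a",     0.1,
    "izh_fs_b",     0.2,
    "izh_fs_c",     -65,
    "izh_fs_d",     2,
    "v_init",       -65,
    "spike_thresh", 20,
    "reset_thresh", 30,
    # Injected-current gain for the external sensory input S_i: a unit
    # stimulus must be suprathreshold for a regular-spiking cell (rheobase
    # about 4), so the stimulus is scaled into current by W_S. Calibrated
    # so the spiking variant reproduces the rate variant's qualitative
    # attention/plan flexibility and its loss under interneuron lesions.
    "W_S",          14,
    "S_amp",        1,
    "R_amp",        1,
    "M_amp",        160
  )
}

#' Parameter table for a model variant
#'
#' Returns every constant of the selected variant with its default value
#' and, for connection weights, the robustness range inside which individual
#' perturbations leave the qualitative behavior intact (outside these ranges
#' the behavior breaks down).
#'
#' @param variant `"rate"` or `"spiking"`.
#' @param reset Reset speed for the plan-cortex expectation-violation time
#'   constant `tau_Pv_Pvr`: `"slow"` or `"fast"`.
#' @return A tibble with columns `symbol`, `value`, `lo`, `hi` (the latter
#'   two `NA` for non-weight constants).
#' @export
param_table <- function(variant = c("rate", "spiking"), reset = c("slow", "fast")) {
  variant <- match.arg(variant)
  reset <- match.arg(reset)
  if (variant == "rate") {
    w <- .rate_weight_table()
    k <- .rate_constant_table(reset)
  } else {
    w <- .spiking_weight_table()
    k <- .spiking_constant_table(reset)
  }
  dplyr::bind_rows(w, dplyr::mutate(k, lo = NA_real_, hi = NA_real_))
}

.apply_overrides <- function(values, table, overrides, variant) {
  if (length(overrides) == 0) return(values)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, table$symbol)
  if (length(unknown) > 0) {
    stop(
      "unknown parameter symbol(s): ", paste(unknown, collapse = ", "),
      "\nknown symbols: ", paste(table$symbol, collapse = ", "),
      call. = FALSE
    )
  }
  for (s in nm) {
    v <- as.numeric(overrides[[s]])
    row <- table[table$symbol == s, ]
    if (!is.na(row$lo) && (v < row$lo || v > row$hi)) {
      warning(
        sprintf(
          "%s = %g is outside the tested robustness range [%g, %g]; qualitative behavior may break down",
          s, v, row$lo, row$hi
        ),
        call. = FALSE
      )
    }
    values[[s]] <- v
  }
  values
}

#' Rate-coded model parameters
#'
#' Assembles the full parameter set of the rate-coded circuit: fixed
#' connection weights, activation thresholds, decay rates, shunting bounds
#' and time constants. Defaults are the published operating point; any
#' symbol from [param_table()] can be overridden by name. Overrides outside
#' a weight's robustness range trigger a warning.
#'
#' @param N Number of channels per sensory map (thalamus, cortex, TRN each
#'   contain `N` units; the amygdala contains `2 x N` units split into an
#'   appetitive and an aversive subgroup).
#' @param reset `"slow"` (tau_Pv_Pvr = 12.50 s) or `"fast"` (2.50 s) build-up
#'   of the plan-cortex expectation-violation signal; slow resetting lets a
#'   plan persist across several unconfirmed stimuli, fast resetting shifts
#'   the plan after a single violation.
#' @param ... Named parameter overrides (e.g. `W_SR_ST = 2`).
#' @return An object of class `amygate_params`.
#' @examples
#' p <- rate_params(N = 10, reset = "slow")
#' p$W_SR_ST
#' @export
rate_params <- function(N = 10, reset = c("slow", "fast"), ...) {
  reset <- match.arg(reset)
  tab <- param_table("rate", reset)
  values <- as.list(setNames(tab$value, tab$symbol))
  values <- .apply_overrides(values, tab, list(...), "rate")
  stopifnot(N >= 1)
  values$N <- as.integer(N)
  structure(values,
    class = "amygate_params",
    variant = "rate", reset = reset, table = tab
  )
}

#' Spiking model parameters
#'
#' Parameter set for the spiking variant: Izhikevich point neurons
#' (regular-spiking principal cells, fast-spiking interneurons) coupled by
#' a saturating-differentials postsynaptic signal, with the circuit wiring
#' and thresholds of the rate variant. Expectation-related signals remain
#' rate-style. See [rate_params()] for the override interface.
#'
#' @inheritParams rate_params
#' @return An object of class `amygate_params`.
#' @export
spiking_params <- function(N = 10, reset = c("slow", "fast"), ...) {
  reset <- match.arg(reset)
  tab <- param_table("spiking", reset)
  values <- as.list(setNames(tab$value, tab$symbol))
  values <- .apply_overrides(values, tab, list(...), "spiking")
  stopifnot(N >= 1)
  values$N <- as.integer(N)
  structure(values,
    class = "amygate_params",
    variant = "spiking", reset = reset, table = tab
  )
}

#' @export
print.amygate_params <- function(x, ...) {
  cat(
    sprintf(
      "<amygate_params> %s variant, N = %d, %s reset (tau_Pv_Pvr = %g)\n",
      attr(x, "variant"), x$N, attr(x, "reset"), x$tau_Pv_Pvr
    )
  )
  invisible(x)
}

#' Lesion configuration
#'
#' Switches that silence the inhibitory interneuron input onto principal
#' cells, emulating interneuron lesions. The interneurons themselves keep
#' integrating (their activity still appears in traces); only their synaptic
#' effect on the principal cell is removed.
#'
#' @param ba_interneurons Lesion the basal-amygdala interneurons (removes
#'   stimulus-specific resetting of affective salience; attention fixates on
#'   the first relevant stimulus).
#' @param plan_interneurons Lesion the plan-cortex interneurons (removes
#'   plan resetting; the first chosen plan persists).
#' @return An object of class `amygate_lesion`.
#' @export
lesion_config <- function(ba_interneurons = FALSE, plan_interneurons = FALSE) {
  structure(
    list(
      ba_interneurons = isTRUE(ba_interneurons),
      plan_interneurons = isTRUE(plan_interneurons)
    ),
    class = "amygate_lesion"
  )
}

#' @export
print.amygate_lesion <- function(x, ...) {
  cat(sprintf(
    "<amygate_lesion> BA interneurons: %s, plan interneurons: %s\n",
    if (x$ba_interneurons) "lesioned" else "intact",
    if (x$plan_interneurons) "lesioned" else "intact"
  ))
  invisible(x)
}
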