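# Scalar reference implementation of the rate-coded circuit. This is the
# readable, loop-by-loop transcription of the model equations: every
# population's excitatory and inhibitory drive assembled term by term, one
# shunting Euler step per population, one saturating Hebbian step per
# plastic weight. The compiled core (src/rate_core.cpp) mirrors this code
# expression-for-expression; their agreement is asserted bit-for-bit in the
# test suite, so this file doubles as the specification of the dynamics.

.pos <- function(a) if (a > 0) a else 0
.hside <- function(a) if (a > 0) 1 else 0

#' Excitatory and inhibitory drives for every population
#'
#' Assembles, from the current state, the `(E, I)` input pair of each
#' population: the feedforward/feedback wiring of the sensory map, the
#' amygdala salience map (with its expectation-confirmation and
#' expectation-violation circuitry), and the two-plan decision map. TRN
#' inhibition is open-loop: a TRN unit inhibits every loop but its own
#' (the inhibition matrices have exactly zero diagonals). Lesion flags
#' silence the interneuron term of the corresponding principal cells.
#'
#' @param state Named list of activity vectors (see [rate_state0()]).
#' @param weights List with plastic fields `WstLA` and `WpcBA` (q-major
#'   length-2N vectors); usually `state` itself.
#' @param drive List with `S` (length N), `R` (length 2), `M` (length 2).
#' @param params A [rate_params()] object.
#' @param lesion A [lesion_config()] object.
#' @return List with components `E` and `I`, each a named list of vectors
#'   parallel to the state.
#' @export
compute_drives <- function(state, weights = state, drive, params,
                           lesion = lesion_config()) {
  p <- params
  N <- p$N
  if (length(state$ST) != N || length(state$LA) != 2 * N) {
    stop("state dimensions do not match params$N = ", N, call. = FALSE)
  }
  if (length(drive$S) != N) {
    stop("drive$S has length ", length(drive$S), " but params$N = ", N,
      call. = FALSE
    )
  }

  posSR <- numeric(N); posST <- numeric(N)
  posBA1 <- numeric(N); posBA2 <- numeric(N)
  for (i in seq_len(N)) {
    posSR[i] <- .pos(state$SR[i])
    posST[i] <- .pos(state$ST[i])
    posBA1[i] <- .pos(state$BA[i])
    posBA2[i] <- .pos(state$BA[N + i])
  }

  E <- list(); I <- list()
  E$ST <- numeric(N); I$ST <- numeric(N)
  E$SC <- numeric(N); I$SC <- numeric(N)
  E$SR <- numeric(N); I$SR <- numeric(N)
  for (i in seq_len(N)) {
    E$ST[i] <- drive$S[i] + p$W_SC_ST * state$SC[i] + p$W_BA_ST * (posBA1[i] + posBA2[i])
    acc <- 0
    for (j in seq_len(N)) if (j != i) acc <- acc + p$W_SR_ST * posSR[j]
    I$ST[i] <- acc
    E$SC[i] <- p$W_ST_SC * posST[i] + p$W_BA_SC * (posBA1[i] + posBA2[i])
    E$SR[i] <- p$W_SC_SR * state$SC[i] + p$W_ST_SR * posST[i] + p$W_BA_SR * (posBA1[i] + posBA2[i])
    acc <- 0
    for (j in seq_len(N)) if (j != i) acc <- acc + p$W_SR_SR * posSR[j]
    I$SR[i] <- acc
  }

  E$LA <- numeric(2 * N); I$LA <- numeric(2 * N)
  E$BA <- numeric(2 * N); I$BA <- numeric(2 * N)
  E$BAIN <- numeric(2 * N); I$BAIN <- numeric(2 * N)
  E$Lc <- numeric(2 * N); I$Lc <- numeric(2 * N)
  E$Lv <- numeric(2 * N); I$Lv <- numeric(2 * N)
  E$Lvr <- numeric(2 * N); I$Lvr <- numeric(2 * N)
  sumBA <- numeric(2)
  for (q in 1:2) {
    Rq <- drive$R[q]
    sB <- 0
    for (j in seq_len(N)) sB <- sB + .pos(state$BA[(q - 1) * N + j])
    sumBA[q] <- sB
    for (i in seq_len(N)) {
      k <- (q - 1) * N + i
      E$LA[k] <- weights$WstLA[k] * posST[i]
      E$BA[k] <- p$W_LA_BA * .pos(state$LA[k]) + weights$WpcBA[k] * .pos(state$PC[q] - p$Gamma_PCB)
      I$BA[k] <- if (lesion$ba_interneurons) 0 else p$W_yB * state$BAIN[k]
      E$BAIN[k] <- p$W_Lcy * .pos(state$Lc[k]) + p$W_Lvy * .pos(state$Lv[k])
      E$Lc[k] <- p$W_Lc * .pos(state$LA[k]) * Rq
      E$Lv[k] <- p$W_Lv * .pos(state$LA[k] - p$Gamma_L) + p$W_vv * .pos(state$Lv[k] - p$Gamma_v)
      I$Lv[k] <- p$W_Lcv * state$Lc[k] + p$W_Lyv * .pos(state$Lvr[k] - p$Gamma_yv)
      E$Lvr[k] <- p$W_Ly * .pos(state$Lv[k]) + p$W_yy * .pos(state$Lvr[k] - p$Gamma_y) * .hside(state$Lv[k] - p$Gamma_r)
    }
  }

  E$PT <- numeric(2); I$PT <- numeric(2)
  E$PC <- numeric(2); I$PC <- numeric(2)
  E$PR <- numeric(2); I$PR <- numeric(2)
  E$PCIN <- numeric(2); I$PCIN <- numeric(2)
  E$Pc <- numeric(2); I$Pc <- numeric(2)
  E$Pv <- numeric(2); I$Pv <- numeric(2)
  E$Pvr <- numeric(2); I$Pvr <- numeric(2)
  for (q in 1:2) {
    Rq <- drive$R[q]
    o <- 3 - q
    E$PT[q] <- drive$M[q] + p$W_PC_PT * .pos(state$PC[q] - p$Gamma_PCT) + p$W_BA_PT * sumBA[q]
    I$PT[q] <- p$W_PR_PT * .pos(state$PR[o])
    E$PC[q] <- p$W_PT_PC * .pos(state$PT[q]) + p$W_BA_PC * sumBA[q]
    I$PC[q] <- if (lesion$plan_interneurons) 0 else p$W_yP * state$PCIN[q]
    E$PR[q] <- p$W_PC_PR * state$PC[q] + p$W_PT_PR * .pos(state$PT[q]) + p$W_BA_PR * sumBA[q]
    I$PR[q] <- p$W_PR_PR * .pos(state$PR[o])
    E$PCIN[q] <- p$W_Pcy * .pos(state$Pc[q]) + p$W_Pvy * .pos(state$Pv[q])
    E$Pc[q] <- p$W_Pc * .pos(state$PC[q]) * Rq
    E$Pv[q] <- p$W_Pv * .pos(state$PC[q] - p$Gamma_P) + p$W_vv * .pos(state$Pv[q] - p$Gamma_v)
    I$Pv[q] <- p$W_Pcv * state$Pc[q] + p$W_Pyv * .pos(state$Pvr[q] - p$Gamma_yv)
    E$Pvr[q] <- p$W_Py * .pos(state$Pv[q]) + p$W_yy * .pos(state$Pvr[q] - p$Gamma_y) * .hside(state$Pv[q] - p$Gamma_v)
  }

  list(E = E, I = I)
}

#' Reinforcement-gated Hebbian weight update
#'
#' One Euler step of the two saturating learning laws. The sensory-thalamus
#' to lateral-amygdala weights grow when presynaptic thalamic activity
#' exceeds its threshold while the matching reinforcement signal is on; the
#' plan-cortex to basal-amygdala weights additionally require postsynaptic
#' BA activity above threshold. Both laws saturate at their ceiling
#' (`B_ST_LA`, `B_PC_BA`) and contain no decay term, so weights never
#' decrease.
#'
#' @inheritParams compute_drives
#' @param h Euler step size (s).
#' @return List with updated `WstLA` and `WpcBA`.
#' @export
update_weights <- function(state, weights = state, drive, params, h) {
  p <- params
  N <- p$N
  WstLA <- weights$WstLA
  WpcBA <- weights$WpcBA
  for (q in 1:2) {
    Rq <- drive$R[q]
    for (i in seq_len(N)) {
      k <- (q - 1) * N + i
      WstLA[k] <- WstLA[k] + (h / p$tau_w) * (p$B_ST_LA - WstLA[k]) * .pos(state$ST[i] - p$Gamma_ST) * Rq
      WpcBA[k] <- WpcBA[k] + (h / p$tau_w) * (p$B_PC_BA - WpcBA[k]) * .pos(state$BA[k] - p$Gamma_BA) * .pos(state$PC[q]) * Rq
    }
  }
  list(WstLA = WstLA, WpcBA = WpcBA)
}

# population -> (A, tau) lookup for the rate model
.rate_Atau <- function(p) {
  list(
    ST = c(p$A_ST, p$tau_main),
    SC = c(p$A_SC_PC_LA_y, p$tau_main),
    SR = c(p$A_SR_PR_BA, p$tau_main),
    LA = c(p$A_SC_PC_LA_y, p$tau_main),
    BA = c(p$A_SR_PR_BA, p$tau_main),
    BAIN = c(p$A_SC_PC_LA_y, p$tau_main),
    Lc = c(p$A_Lc_Pc, p$tau_Lc_Pc),
    Lv = c(p$A_Lv_Pv, p$tau_Lv_Lvr),
    Lvr = c(p$A_r, p$tau_Lv_Lvr),
    PT = c(p$A_PT, p$tau_main),
    PC = c(p$A_SC_PC_LA_y, p$tau_main),
    PR = c(p$A_SR_PR_BA, p$tau_main),
    PCIN = c(p$A_SC_PC_LA_y, p$tau_main),
    Pc = c(p$A_Lc_Pc, p$tau_Lc_Pc),
    Pv = c(p$A_Lv_Pv, p$tau_Pv_Pvr),
    Pvr = c(p$A_r, p$tau_Pv_Pvr)
  )
}

#' One synchronous step of the rate-coded circuit
#'
#' Assembles all drives from the previous state, advances the plastic
#' weights, then advances every population with its own decay rate and time
#' constant under the global shunting bounds. The expectation-violation
#' signals are clamped at zero after the update (the hard nonlinearity that
#' keeps them nonnegative after resetting). Fully deterministic.
#'
#' @inheritParams compute_drives
#' @param h Euler step size (s).
#' @return List with updated `state` (which carries the weights in its
#'   `WstLA`/`WpcBA` fields).
#' @export
rate_step <- function(state, drive, params, lesion = lesion_config(), h = 1e-4) {
  p <- params
  d <- compute_drives(state, state, drive, p, lesion)
  w <- update_weights(state, state, drive, p, h)
  at <- .rate_Atau(p)
  new <- state
  for (nm in names(at)) {
    A <- at[[nm]][1]; tau <- at[[nm]][2]
    x <- state[[nm]]
    xn <- numeric(length(x))
    for (k in seq_along(x)) {
      xn[k] <- shunting_step(x[k], d$E[[nm]][k], d$I[[nm]][k], A, p$B, p$C, tau, h)
      if ((nm == "Lv" || nm == "Pv") && xn[k] < 0) xn[k] <- 0
      if (!is.finite(xn[k])) {
        stop("non-finite activity in population ", nm, call. = FALSE)
      }
    }
    new[[nm]] <- xn
  }
  new$WstLA <- w$WstLA
  new$WpcBA <- w$WpcBA
  new
}

# Reference integrator: loops rate_step and records with the same schema as
# the compiled core. Used as the independent oracle in tests.
.run_rate_reference <- function(params, lesion, S, R, M, state0, h, record_stride) {
  N <- params$N
  n_steps <- nrow(S)
  n_rec <- if (record_stride > 0) n_steps %/% record_stride else 0
  n_cols <- 1 + 20 * N + 18
  trace <- matrix(0, n_rec, n_cols)
  rec <- 0
  st <- state0
  for (s in seq_len(n_steps)) {
    drive <- list(S = S[s, ], R = R[s, ], M = M[s, ])
    st <- tryCatch(
      rate_step(st, drive, params, lesion, h),
      error = function(e) stop(conditionMessage(e), " at step ", s, call. = FALSE)
    )
    if (record_stride > 0 && s %% record_stride == 0 && rec < n_rec) {
      rec <- rec + 1
      trace[rec, ] <- c(
        s * h, st$ST, st$SC, st$SR, st$LA, st$BA, st$BAIN,
        st$Lc, st$Lv, st$Lvr, st$PT, st$PC, st$PR, st$PCIN,
        st$Pc, st$Pv, st$Pvr, st$WstLA, st$WpcBA,
        S[s, ], R[s, ], M[s, ]
      )
    }
  }
  list(trace = trace, state = st)
}
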