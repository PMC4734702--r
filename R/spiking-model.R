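# Scalar reference implementation of the spiking circuit, mirroring
# src/spiking_core.cpp expression-for-expression (see R/rate-model.R for
# the role of these reference steppers).

#' One Euler step of an Izhikevich point neuron
#'
#' \deqn{\tau_s \dot v = 0.04 v^2 + 5 v + 140 - u + E - I}
#' \deqn{\tau_s \dot u = a (b v - u)}
#' with the after-spike reset `v <- c`, `u <- u + d` applied when the
#' updated voltage reaches the reset threshold (30 mV). A spike is emitted
#' at the step where the voltage crosses the emission threshold (20 mV)
#' from below; the edge trigger guarantees one spike event per action
#' potential.
#'
#' @param v,u Membrane voltage (mV) and recovery variable.
#' @param E,I Excitatory and inhibitory input current.
#' @param izh Named list or vector with `a`, `b`, `c`, `d`.
#' @param tau_s Integration time constant (s).
#' @param h Euler step size (s).
#' @param spike_thresh,reset_thresh Emission (20) and reset (30) thresholds.
#' @return List with `v`, `u`, and logical `spiked`.
#' @examples
#' izhikevich_step(v = 31, u = 0, E = 0, I = 0,
#'   izh = list(a = 0.02, b = 0.2, c = -65, d = 8))
#' @export
izhikevich_step <- function(v, u, E, I, izh, tau_s = 0.001, h = 1e-4,
                            spike_thresh = 20, reset_thresh = 30) {
  stopifnot(h > 0)
  vn <- v + (h / tau_s) * (0.04 * v * v + 5 * v + 140 - u + (E - I))
  un <- u + (h / tau_s) * (izh$a * (izh$b * v - u))
  spiked <- (v <= spike_thresh && vn > spike_thresh)
  if (vn >= reset_thresh) {
    vn <- izh$c
    un <- un + izh$d
  }
  if (!is.finite(vn)) stop("non-finite voltage", call. = FALSE)
  list(v = vn, u = un, spiked = spiked)
}

#' One Euler step of the saturating-differentials synapse
#'
#' Converts a presynaptic spike train into a bounded postsynaptic signal.
#' The transmitter variable `T` is kicked by the discrete spike indicator
#' `K` (1 only at the step of an upward threshold crossing) and decays with
#' `tau_rise`; the postsynaptic signal `g` follows
#' \deqn{\dot g = \frac{\tau_{fall}+\tau_{rise}}{\tau_{fall}}
#'   \left[\frac{2}{\tau_{rise}}(1-g)T - \frac{g}{\tau_{fall}}\right]}
#' Both variables are saturating and stay in `[0, 1]` for any spike train.
#'
#' @param T Transmitter variable in `[0, 1]`.
#' @param g Postsynaptic signal in `[0, 1]`.
#' @param K Spike indicator, 0 or 1.
#' @param tau_rise,tau_fall Rise (0.004 s) and fall (0.040 s) times.
#' @param tau_s Integration time constant scaling the spike impulse (s).
#' @param h Euler step size (s).
#' @return List with updated `T` and `g`.
#' @export
sd_synapse_step <- function(T, g, K, tau_rise = 0.004, tau_fall = 0.040,
                            tau_s = 0.001, h = 1e-4) {
  stopifnot(K %in% c(0, 1))
  Tn <- T + h * ((1 - T) * K / tau_s - T / tau_rise)
  gn <- g + h * ((tau_fall + tau_rise) / tau_fall) *
    ((2 / tau_rise) * (1 - g) * T - g / tau_fall)
  list(T = Tn, g = gn)
}

# advance (v, u, T, g) of one neuron; mirrors the compiled core's lambda
.izh_advance <- function(sv, k, E, I, fs, p, h) {
  izh <- if (fs) {
    list(a = p$izh_fs_a, b = p$izh_fs_b, c = p$izh_fs_c, d = p$izh_fs_d)
  } else {
    list(a = p$izh_rs_a, b = p$izh_rs_b, c = p$izh_rs_c, d = p$izh_rs_d)
  }
  r <- izhikevich_step(sv$v[k], sv$u[k], E, I, izh, p$tau_s, h,
    p$spike_thresh, p$reset_thresh
  )
  K <- if (r$spiked) 1 else 0
  s2 <- sd_synapse_step(sv$T[k], sv$g[k], K, p$tau_rise, p$tau_fall, p$tau_s, h)
  list(v = r$v, u = r$u, T = s2$T, g = s2$g, K = K)
}

#' One synchronous step of the spiking circuit
#'
#' Evaluates the circuit's drive structure with every presynaptic activity
#' replaced by that neuron's postsynaptic signal `g`, advances the plastic
#' weights (gated on `g` analogues), integrates all Izhikevich neurons and
#' their synaptic signals, then advances the rate-style expectation signals.
#'
#' @param state Named list from [spiking_state0()].
#' @param drive List with `S`, `R`, `M` for this step.
#' @param params A [spiking_params()] object.
#' @param lesion A [lesion_config()] object.
#' @param h Euler step size (s).
#' @return List with updated `state` and a `spikes` tibble for this step
#'   (columns `pop`, `q`, `channel`).
#' @export
spiking_step <- function(state, drive, params, lesion = lesion_config(), h = 1e-4) {
  p <- params
  N <- p$N
  if (length(state$g_ST) != N) {
    stop("state dimensions do not match params$N = ", N, call. = FALSE)
  }
  st <- state

  # --- drives from previous postsynaptic signals ---
  E_ST <- numeric(N); I_ST <- numeric(N); E_SC <- numeric(N)
  E_SR <- numeric(N); I_SR <- numeric(N)
  for (i in seq_len(N)) {
    E_ST[i] <- p$W_S * drive$S[i] + p$W_SC_ST * st$g_SC[i] + p$W_BA_ST * (st$g_BA[i] + st$g_BA[N + i])
    acc <- 0
    for (j in seq_len(N)) if (j != i) acc <- acc + p$W_SR_ST * st$g_SR[j]
    I_ST[i] <- acc
    E_SC[i] <- p$W_ST_SC * st$g_ST[i] + p$W_BA_SC * (st$g_BA[i] + st$g_BA[N + i])
    E_SR[i] <- p$W_SC_SR * st$g_SC[i] + p$W_ST_SR * st$g_ST[i] + p$W_BA_SR * (st$g_BA[i] + st$g_BA[N + i])
    acc <- 0
    for (j in seq_len(N)) if (j != i) acc <- acc + p$W_SR_SR * st$g_SR[j]
    I_SR[i] <- acc
  }
  E_LA <- numeric(2 * N); E_BA <- numeric(2 * N); I_BA <- numeric(2 * N)
  E_BAIN <- numeric(2 * N)
  E_Lc <- numeric(2 * N); E_Lv <- numeric(2 * N); I_Lv <- numeric(2 * N)
  E_Lvr <- numeric(2 * N)
  sumBA <- numeric(2)
  for (q in 1:2) {
    Rq <- drive$R[q]
    sB <- 0
    for (j in seq_len(N)) sB <- sB + st$g_BA[(q - 1) * N + j]
    sumBA[q] <- sB
    for (i in seq_len(N)) {
      k <- (q - 1) * N + i
      E_LA[k] <- st$WstLA[k] * st$g_ST[i]
      E_BA[k] <- p$W_LA_BA * st$g_LA[k] + st$WpcBA[k] * .pos(st$g_PC[q] - p$Gamma_PCB)
      I_BA[k] <- if (lesion$ba_interneurons) 0 else p$W_yB * st$g_BAIN[k]
      E_BAIN[k] <- p$W_Lcy * .pos(st$Lc[k]) + p$W_Lvy * .pos(st$Lv[k])
      E_Lc[k] <- p$W_Lc * st$g_LA[k] * Rq
      E_Lv[k] <- p$W_Lv * .pos(st$g_LA[k] - p$Gamma_L) + p$W_vv * .pos(st$Lv[k] - p$Gamma_v)
      I_Lv[k] <- p$W_Lcv * st$Lc[k] + p$W_Lyv * .pos(st$Lvr[k] - p$Gamma_yv)
      E_Lvr[k] <- p$W_Ly * .pos(st$Lv[k]) + p$W_yy * .pos(st$Lvr[k] - p$Gamma_y) * .hside(st$Lv[k] - p$Gamma_r)
    }
  }
  E_PT <- numeric(2); I_PT <- numeric(2); E_PC <- numeric(2); I_PC <- numeric(2)
  E_PR <- numeric(2); I_PR <- numeric(2); E_PCIN <- numeric(2)
  E_Pc <- numeric(2); E_Pv <- numeric(2); I_Pv <- numeric(2); E_Pvr <- numeric(2)
  for (q in 1:2) {
    Rq <- drive$R[q]
    o <- 3 - q
    E_PT[q] <- drive$M[q] + p$W_PC_PT * .pos(st$g_PC[q] - p$Gamma_PCT) + p$W_BA_PT * sumBA[q]
    I_PT[q] <- p$W_PR_PT * st$g_PR[o]
    E_PC[q] <- p$W_PT_PC * st$g_PT[q] + p$W_BA_PC * sumBA[q]
    I_PC[q] <- if (lesion$plan_interneurons) 0 else p$W_yP * st$g_PCIN[q]
    E_PR[q] <- p$W_PC_PR * st$g_PC[q] + p$W_PT_PR * st$g_PT[q] + p$W_BA_PR * sumBA[q]
    I_PR[q] <- p$W_PR_PR * st$g_PR[o]
    E_PCIN[q] <- p$W_Pcy * .pos(st$Pc[q]) + p$W_Pvy * .pos(st$Pv[q])
    E_Pc[q] <- p$W_Pc * st$g_PC[q] * Rq
    E_Pv[q] <- p$W_Pv * .pos(st$g_PC[q] - p$Gamma_P) + p$W_vv * .pos(st$Pv[q] - p$Gamma_v)
    I_Pv[q] <- p$W_Pcv * st$Pc[q] + p$W_Pyv * .pos(st$Pvr[q] - p$Gamma_yv)
    E_Pvr[q] <- p$W_Py * .pos(st$Pv[q]) + p$W_yy * .pos(st$Pvr[q] - p$Gamma_y) * .hside(st$Pv[q] - p$Gamma_v)
  }

  # --- plastic weights ---
  for (q in 1:2) {
    Rq <- drive$R[q]
    for (i in seq_len(N)) {
      k <- (q - 1) * N + i
      st$WstLA[k] <- st$WstLA[k] + (h / p$tau_w) * (p$B_ST_LA - st$WstLA[k]) * .pos(st$g_ST[i] - p$Gamma_ST) * Rq
      st$WpcBA[k] <- st$WpcBA[k] + (h / p$tau_w) * (p$B_PC_BA - st$WpcBA[k]) * .pos(st$g_BA[k] - p$Gamma_BA) * .pos(st$g_PC[q]) * Rq
    }
  }

  # --- membrane + synapse integration ---
  spk_pop <- integer(0); spk_q <- integer(0); spk_ch <- integer(0)
  adv <- function(nm, k, E, I, fs, pop_code, q, ch) {
    sv <- list(
      v = st[[paste0("v_", nm)]], u = st[[paste0("u_", nm)]],
      T = st[[paste0("T_", nm)]], g = st[[paste0("g_", nm)]]
    )
    r <- .izh_advance(sv, k, E, I, fs, p, h)
    st[[paste0("v_", nm)]][k] <<- r$v
    st[[paste0("u_", nm)]][k] <<- r$u
    st[[paste0("T_", nm)]][k] <<- r$T
    st[[paste0("g_", nm)]][k] <<- r$g
    if (r$K == 1) {
      spk_pop <<- c(spk_pop, pop_code); spk_q <<- c(spk_q, q); spk_ch <<- c(spk_ch, ch)
    }
  }
  for (i in seq_len(N)) {
    adv("ST", i, E_ST[i], I_ST[i], FALSE, 1L, 0L, i)
    adv("SC", i, E_SC[i], 0, FALSE, 2L, 0L, i)
    adv("SR", i, E_SR[i], I_SR[i], TRUE, 3L, 0L, i)
  }
  for (q in 1:2) {
    for (i in seq_len(N)) {
      k <- (q - 1) * N + i
      adv("LA", k, E_LA[k], 0, FALSE, 4L, q, i)
      adv("BA", k, E_BA[k], I_BA[k], FALSE, 5L, q, i)
      adv("BAIN", k, E_BAIN[k], 0, TRUE, 6L, q, i)
    }
    adv("PT", q, E_PT[q], I_PT[q], FALSE, 7L, q, 1L)
    adv("PC", q, E_PC[q], I_PC[q], FALSE, 8L, q, 1L)
    adv("PR", q, E_PR[q], I_PR[q], TRUE, 9L, q, 1L)
    adv("PCIN", q, E_PCIN[q], 0, TRUE, 10L, q, 1L)
  }

  # --- rate-style expectation signals ---
  for (k in seq_len(2 * N)) {
    st$Lc[k] <- shunting_step(state$Lc[k], E_Lc[k], 0, p$A_Lc_Pc, p$B, p$C, p$tau_Lc_Pc, h)
    st$Lv[k] <- shunting_step(state$Lv[k], E_Lv[k], I_Lv[k], p$A_Lv_Pv, p$B, p$C, p$tau_Lv_Lvr, h)
    if (st$Lv[k] < 0) st$Lv[k] <- 0
    st$Lvr[k] <- shunting_step(state$Lvr[k], E_Lvr[k], 0, p$A_r, p$B, p$C, p$tau_Lv_Lvr, h)
  }
  for (q in 1:2) {
    st$Pc[q] <- shunting_step(state$Pc[q], E_Pc[q], 0, p$A_Lc_Pc, p$B, p$C, p$tau_Lc_Pc, h)
    st$Pv[q] <- shunting_step(state$Pv[q], E_Pv[q], I_Pv[q], p$A_Lv_Pv, p$B, p$C, p$tau_Pv_Pvr, h)
    if (st$Pv[q] < 0) st$Pv[q] <- 0
    st$Pvr[q] <- shunting_step(state$Pvr[q], E_Pvr[q], 0, p$A_r, p$B, p$C, p$tau_Pv_Pvr, h)
  }

  list(
    state = st,
    spikes = tibble::tibble(pop = spk_pop, q = spk_q, channel = spk_ch)
  )
}

# Reference integrator for the spiking model (oracle for the compiled core).
.run_spiking_reference <- function(params, lesion, S, R, M, state0, h, record_stride) {
  N <- params$N
  n_steps <- nrow(S)
  n_rec <- if (record_stride > 0) n_steps %/% record_stride else 0
  n_izh <- 9 * N + 8
  n_cols <- 1 + 20 * N + 18 + 2 * n_izh
  trace <- matrix(0, n_rec, n_cols)
  rec <- 0
  st <- state0
  spikes <- list()
  for (s in seq_len(n_steps)) {
    drive <- list(S = S[s, ], R = R[s, ], M = M[s, ])
    r <- spiking_step(st, drive, params, lesion, h)
    st <- r$state
    if (nrow(r$spikes) > 0) {
      spikes[[length(spikes) + 1]] <- dplyr::mutate(r$spikes, step = s, .before = 1)
    }
    if (record_stride > 0 && s %% record_stride == 0 && rec < n_rec) {
      rec <- rec + 1
      izh_cols <- function(prefix) {
        c(
          st[[paste0(prefix, "_ST")]], st[[paste0(prefix, "_SC")]],
          st[[paste0(prefix, "_SR")]], st[[paste0(prefix, "_LA")]],
          st[[paste0(prefix, "_BA")]], st[[paste0(prefix, "_BAIN")]],
          st[[paste0(prefix, "_PT")]], st[[paste0(prefix, "_PC")]],
          st[[paste0(prefix, "_PR")]], st[[paste0(prefix, "_PCIN")]]
        )
      }
      trace[rec, ] <- c(
        s * h, izh_cols("g")[seq_len(3 * N)],
        st$g_LA, st$g_BA, st$g_BAIN,
        st$Lc, st$Lv, st$Lvr,
        st$g_PT, st$g_PC, st$g_PR, st$g_PCIN,
        st$Pc, st$Pv, st$Pvr, st$WstLA, st$WpcBA,
        S[s, ], R[s, ], M[s, ],
        izh_cols("v"), izh_cols("u")
      )
    }
  }
  spikes <- if (length(spikes) > 0) dplyr::bind_rows(spikes) else {
    tibble::tibble(step = integer(0), pop = integer(0), q = integer(0), channel = integer(0))
  }
  list(trace = trace, state = st, spikes = spikes)
}
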