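# State containers. Valenced quantities (amygdala subgroups, their
# expectation signals, plastic weights) are stored as length-2N vectors in
# q-major order: entries 1..N are the appetitive subgroup (q = 1), entries
# N+1..2N the aversive subgroup (q = 2). Helper accessors keep indexing in
# one place.

qm_index <- function(q, i, N) (q - 1L) * N + i

#' All-zero initial state for the rate-coded circuit
#'
#' Every activity and both plastic weight families start at zero.
#'
#' @param N Channels per sensory map.
#' @return Named list of state vectors.
#' @export
rate_state0 <- function(N) {
  z1 <- numeric(N)
  z2 <- numeric(2 * N)
  zp <- numeric(2)
  list(
    ST = z1, SC = z1, SR = z1,
    LA = z2, BA = z2, BAIN = z2,
    Lc = z2, Lv = z2, Lvr = z2,
    PT = zp, PC = zp, PR = zp, PCIN = zp,
    Pc = zp, Pv = zp, Pvr = zp,
    WstLA = z2, WpcBA = z2
  )
}

#' Initial state for the spiking circuit
#'
#' Voltages start at the resting value (-65 mV), recovery variables at
#' `b * v` for the cell class, transmitter and postsynaptic signals at zero;
#' the rate-style expectation signals and plastic weights start at zero.
#'
#' @param N Channels per sensory map.
#' @param params A `spiking_params()` object (for the cell-class constants).
#' @return Named list of state vectors.
#' @export
spiking_state0 <- function(N, params) {
  v0 <- params$v_init
  mk <- function(n, fs) {
    b <- if (fs) params$izh_fs_b else params$izh_rs_b
    list(v = rep(v0, n), u = rep(b * v0, n), T = numeric(n), g = numeric(n))
  }
  pops <- list(
    ST = mk(N, FALSE), SC = mk(N, FALSE), SR = mk(N, TRUE),
    LA = mk(2 * N, FALSE), BA = mk(2 * N, FALSE), BAIN = mk(2 * N, TRUE),
    PT = mk(2, FALSE), PC = mk(2, FALSE), PR = mk(2, TRUE), PCIN = mk(2, TRUE)
  )
  out <- list()
  for (nm in names(pops)) {
    out[[paste0("v_", nm)]] <- pops[[nm]]$v
    out[[paste0("u_", nm)]] <- pops[[nm]]$u
    out[[paste0("T_", nm)]] <- pops[[nm]]$T
    out[[paste0("g_", nm)]] <- pops[[nm]]$g
  }
  out$Lc <- numeric(2 * N); out$Lv <- numeric(2 * N); out$Lvr <- numeric(2 * N)
  out$Pc <- numeric(2); out$Pv <- numeric(2); out$Pvr <- numeric(2)
  out$WstLA <- numeric(2 * N); out$WpcBA <- numeric(2 * N)
  out
}

# trace column names, matching the recording order of the C++ cores
.per2N <- function(prefix, N) {
  c(paste0(prefix, ".q1.i", seq_len(N)), paste0(prefix, ".q2.i", seq_len(N)))
}
.per2 <- function(prefix) paste0(prefix, c(".q1", ".q2"))

.trace_colnames_rate <- function(N) {
  c(
    "time",
    paste0("x_ST.i", seq_len(N)), paste0("x_SC.i", seq_len(N)),
    paste0("x_SR.i", seq_len(N)),
    .per2N("x_LA", N), .per2N("x_BA", N), .per2N("y_BAIN", N),
    .per2N("x_Lc", N), .per2N("x_Lv", N), .per2N("y_Lvr", N),
    .per2("x_PT"), .per2("x_PC"), .per2("x_PR"), .per2("y_PCIN"),
    .per2("x_Pc"), .per2("x_Pv"), .per2("y_Pvr"),
    .per2N("W_ST_LA", N), .per2N("W_PC_BA", N),
    paste0("S.i", seq_len(N)), .per2("R"), .per2("M")
  )
}

.trace_colnames_spiking <- function(N) {
  izh <- function(prefix) {
    c(
      paste0(prefix, "_ST.i", seq_len(N)), paste0(prefix, "_SC.i", seq_len(N)),
      paste0(prefix, "_SR.i", seq_len(N)),
      .per2N(paste0(prefix, "_LA"), N), .per2N(paste0(prefix, "_BA"), N),
      .per2N(paste0(prefix, "_BAIN"), N),
      .per2(paste0(prefix, "_PT")), .per2(paste0(prefix, "_PC")),
      .per2(paste0(prefix, "_PR")), .per2(paste0(prefix, "_PCIN"))
    )
  }
  c(.trace_colnames_rate(N), izh("v"), izh("u"))
}

.spike_pop_names <- c(
  "x_ST", "x_SC", "x_SR", "x_LA", "x_BA", "y_BAIN",
  "x_PT", "x_PC", "x_PR", "y_PCIN"
)
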