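#' Positive rectification
#'
#' `[a]^+`: elementwise half-wave rectification, the nonlinearity applied to
#' most presynaptic activities before they drive other populations.
#'
#' @param a Numeric scalar or vector.
#' @return `a` where `a >= 0`, else 0, elementwise.
#' @examples
#' rectify(c(-1, 0, 2))
#' @export
rectify <- function(a) {
  ifelse(a > 0, a, 0)
}

# Heaviside step: 1 for strictly positive arguments, 0 otherwise (H(0) = 0).
heaviside <- function(a) {
  ifelse(a > 0, 1, 0)
}

#' One forward-Euler step of the shunting membrane equation
#'
#' Every rate-coded population obeys
#' \deqn{\tau \dot x = -Ax + (B - x)E - (x + C)I}
#' where `E`/`I` are the excitatory and inhibitory drives, `A` the passive
#' decay rate, `B` the maximum activity and `-C` the minimum. The
#' multiplicative (shunting) form keeps `x` in `[-C, B]` for any
#' nonnegative drives, and gives the equilibrium
#' `x* = (BE - CI) / (A + E + I)` under frozen drives.
#'
#' @param x Current activity (scalar or vector).
#' @param E,I Excitatory and inhibitory input (same shape as `x` or scalar).
#' @param A Passive decay rate (1/s).
#' @param B,C Upper bound and negated lower bound on activity.
#' @param tau Integration time constant (s).
#' @param h Euler step size (s).
#' @return Updated activity.
#' @examples
#' shunting_step(0, E = 1, I = 0, A = 1, B = 10, C = 10, tau = 0.05, h = 1e-4)
#' @export
shunting_step <- function(x, E, I, A, B, C, tau, h) {
  stopifnot(tau > 0, h > 0)
  x + (h / tau) * (-A * x + (B - x) * E - (x + C) * I)
}

#' Equilibrium of the shunting equation under frozen drives
#'
#' @inheritParams shunting_step
#' @return `(B * E - C * I) / (A + E + I)`.
#' @export
shunting_fixed_point <- function(E, I, A, B, C) {
  (B * E - C * I) / (A + E + I)
}
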