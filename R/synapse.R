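## Synaptic current schemes: continuous-release fast GABA, event-triggered
## nicotinic ACh, and the slow G-protein-coupled inhibitory current.

#' GABA transmitter concentration factor
#'
#' Fast GABA release is a continuous, sigmoidal function of the presynaptic
#' LN membrane potential (LNs fire graded calcium potentials, not all-or-none
#' spikes): \eqn{[T] = 1/(1 + \exp(-(V - V_0)/\sigma))} with
#' \eqn{V_0 = -20} mV and \eqn{\sigma = 1.5}.
#'
#' @param V_pre presynaptic membrane potential (mV).
#' @param params model parameters.
#' @return Transmitter factor in (0, 1); 0.5 at \eqn{V_0}.
#' @export
gaba_transmitter <- function(V_pre, params = al_params()) {
  g <- params$syn$gaba
  1 / (1 + exp(-(V_pre - g$V0) / g$sigma))
}

#' Nicotinic ACh transmitter pulse
#'
#' A presynaptic PN action potential (upward 0 mV crossing) triggers a
#' rectangular transmitter pulse of amplitude 0.5 lasting
#' \eqn{t_{max} = 0.3} ms.
#'
#' @param t current time (ms).
#' @param t0 time of the most recent presynaptic activation (ms); `-Inf` if
#'   none has occurred.
#' @param params model parameters.
#' @return 0.5 inside \eqn{[t_0, t_0 + t_{max}]}, else 0.
#' @export
nach_transmitter <- function(t, t0, params = al_params()) {
  n <- params$syn$nach
  ifelse(t >= t0 & t <= t0 + n$t_max, n$T_amp, 0)
}

#' One Euler step of a ligand-gated channel population
#'
#' \eqn{d[O]/dt = \alpha (1-[O])[T] - \beta [O]} for the fraction of open
#' channels of one afferent synapse (GABA: \eqn{\alpha = 10,
#' \beta = 0.16} ms\eqn{^{-1}}; nACh: \eqn{\alpha = 10, \beta = 0.2}).
#'
#' @param O open-channel fraction in \[0, 1\].
#' @param T_fac transmitter concentration factor.
#' @param alpha,beta binding/unbinding rates (1/ms).
#' @param dt Euler step (ms), must be positive.
#' @return Updated open fraction.
#' @export
channel_step <- function(O, T_fac, alpha, beta, dt) {
  if (dt <= 0) stop("dt must be positive")
  O + dt * (alpha * (1 - O) * T_fac - beta * O)
}

#' One Euler step of the slow-inhibition receptor/G-protein cascade
#'
#' The slow current is G-protein coupled: transmitter pulses (0.3 ms,
#' triggered by presynaptic LN 0 mV crossings) drive the activated receptor
#' fraction \eqn{d[R]/dt = r_1(1-[R])[T] - r_2[R]}, which in turn drives the
#' G-protein concentration \eqn{d[G]/dt = r_3[R] - r_4[G]}.
#'
#' @param R activated receptor fraction in \[0, 1\].
#' @param G G-protein concentration (uM-scaled, >= 0).
#' @param T_fac transmitter factor (0.5 during a pulse, else 0).
#' @param dt Euler step (ms).
#' @param params model parameters.
#' @return A list with updated `R` and `G`.
#' @export
slow_step <- function(R, G, T_fac, dt, params = al_params()) {
  if (dt <= 0) stop("dt must be positive")
  s <- params$syn$slow
  list(R = R + dt * (s$r1 * (1 - R) * T_fac - s$r2 * R),
       G = G + dt * (s$r3 * R - s$r4 * G))
}

#' Slow inhibitory current
#'
#' \eqn{I_{slow} = g_{slow}\,[G]^4/([G]^4 + K)\,(V - E_K)} with
#' \eqn{K = 100} and \eqn{E_K = -95} mV, where \eqn{[G]} is the summed
#' G-protein concentration over the afferent LNs. The quartic Hill term makes
#' activation require sustained presynaptic firing: roughly three LN calcium
#' spikes from a PN's afferent LN pool before the conductance is
#' half-activated.
#'
#' @param G_total summed G-protein concentration over afferents.
#' @param V postsynaptic membrane potential (mV).
#' @param g_max maximal conductance (mS/cm2).
#' @param params model parameters.
#' @return Current density (uA/cm2); outward (positive) for \eqn{V > E_K}.
#' @export
slow_current <- function(G_total, V, g_max = al_params()$syn$g_slow_lnpn,
                         params = al_params()) {
  s <- params$syn$slow
  g4 <- G_total^4
  g_max * g4 / (g4 + s$K) * (V - s$E)
}

#' Hill activation factor of the slow conductance
#'
#' @inheritParams slow_current
#' @return \eqn{[G]^4/([G]^4+K)}, in \[0, 1).
#' @export
slow_activation <- function(G_total, params = al_params()) {
  g4 <- G_total^4
  g4 / (g4 + params$syn$slow$K)
}
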