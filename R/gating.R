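## Intrinsic-current gating kinetics.
##
## PN spiking currents (I_Na, I_K) use Traub-Miles rate functions referenced
## to a threshold potential V_T = -63 mV, slowed by a temperature-like factor
## phi = 0.5 so that the sodium action potential is ~3 ms wide; with the
## model's weak delayed rectifier (g_K = 3.6 mS/cm2) these kinetics leave the
## resting state stable at E_L, which the unshifted squid-axon rates do not.
## The LN delayed rectifier uses the squid-axon n-gate referenced 40.25 mV
## above its classical frame, placing its activation range over the calcium
## spike rather than over the LN resting potential.
## The calcium-current inactivation time constant is converted from the
## seconds in which its source tabulates it to ms; at the calcium-spike
## plateau it is ~30 ms and is what terminates the ~25 ms spike.

.pn_VT <- -63
.pn_phi <- 0.5
.ln_Kshift <- 40.25
.A_tau_h_break <- -63

## vectorised x/(1 - exp(-x/s)) with the removable singularity at x = 0
.xexpm <- function(x, s) {
  out <- x / (1 - exp(-x / s))
  out[abs(x) < 1e-7] <- s
  out
}

## Traub-Miles rates for PN I_Na / I_K (per-ms, before phi scaling)
.pn_rates <- function(V) {
  v <- V - .pn_VT
  list(
    am = 0.32 * .xexpm(v - 13, 4),
    bm = 0.28 * .xexpm(40 - v, 5),
    ah = 0.128 * exp((17 - v) / 18),
    bh = 4 / (1 + exp((40 - v) / 5)),
    an = 0.032 * .xexpm(v - 15, 5),
    bn = 0.5 * exp((10 - v) / 40)
  )
}

## squid-axon n rates evaluated in the LN frame
.ln_K_rates <- function(V) {
  v <- V - .ln_Kshift
  list(an = 0.01 * .xexpm(v + 55, 10),
       bn = 0.125 * exp(-(v + 65) / 80))
}

.gate_tables <- function(current, gate, V, Ca, cell) {
  key <- paste(current, gate, sep = ".")
  r <- switch(key,
    "Na.m" = { x <- .pn_rates(V); list(a = x$am, b = x$bm) },
    "Na.h" = { x <- .pn_rates(V); list(a = x$ah, b = x$bh) },
    "K.m" = {
      if (cell == "PN") { x <- .pn_rates(V); list(a = x$an, b = x$bn) }
      else { x <- .ln_K_rates(V); list(a = x$an, b = x$bn) }
    },
    "A.m" = list(
      inf = 1 / (1 + exp(-(V + 60) / 8.5)),
      tau = 0.27 / (exp((V + 35.8) / 19.7) + exp(-(V + 79.7) / 12.7)) + 0.1),
    "A.h" = list(
      inf = 1 / (1 + exp((V + 78) / 6)),
      tau = ifelse(V < .A_tau_h_break,
                   0.27 / (exp((V + 46) / 5) + exp(-(V + 238) / 37.5)),
                   5.1)),
    "Ca.m" = list(inf = 1 / (1 + exp(-(V + 20) / 6.5)),
                  tau = pmax(1 + (V + 30) * 0.014, 0.1)),
    "Ca.h" = list(inf = 1 / (1 + exp((V + 25) / 12)),
                  tau = 1000 * (0.3 * exp((V - 40) / 13) +
                                0.002 * exp(-(V - 60) / 29))),
    "CaK.m" = list(inf = Ca / (Ca + 2), tau = 100 / (Ca + 2)),
    stop("unknown current/gate combination: ", current, "/", gate)
  )
  if (!is.null(r$a)) {
    phi <- if (current %in% c("Na", "K") && cell == "PN") .pn_phi else 1
    list(inf = r$a / (r$a + r$b), tau = 1 / (phi * (r$a + r$b)))
  } else r
}

.cell_for <- function(current, cell) {
  if (!is.null(cell)) return(match.arg(cell, c("PN", "LN")))
  switch(current, Na = , A = "PN", Ca = , CaK = "LN",
         K = stop("current 'K' exists in both cell types; give cell = \"PN\" or \"LN\""))
}

#' Steady-state activation/inactivation of an intrinsic current gate
#'
#' @param current one of `"Na"`, `"K"`, `"A"` (PN currents), `"Ca"`, `"CaK"`,
#'   `"K"` (LN currents).
#' @param gate `"m"` (activation) or `"h"` (inactivation). The single gate of
#'   the delayed rectifier and of the calcium-dependent K current is addressed
#'   as `"m"`.
#' @param V membrane potential (mV).
#' @param Ca intracellular calcium (mM); required for `"CaK"`.
#' @param cell `"PN"` or `"LN"`; needed only to disambiguate `"K"`.
#' @return Steady-state gate value in \[0, 1\].
#' @examples
#' gate_steady_state("Ca", "m", V = -20)    # 0.5 at the activation midpoint
#' gate_steady_state("CaK", "m", Ca = 2)    # half-activated at 2 mM
#' @export
gate_steady_state <- function(current, gate, V = NULL, Ca = NULL, cell = NULL) {
  cell <- .cell_for(current, cell)
  if (current == "CaK") {
    if (is.null(Ca) || any(Ca <= 0)) stop("'CaK' requires Ca > 0")
  } else if (is.null(V) || any(!is.finite(V))) stop("finite V required")
  .gate_tables(current, gate, V, Ca, cell)$inf
}

#' Time constant of an intrinsic current gate
#'
#' @inheritParams gate_steady_state
#' @return Time constant in ms (strictly positive).
#' @examples
#' gate_time_constant("A", "h", V = -60)    # 5.1 ms above the breakpoint
#' gate_time_constant("CaK", "m", Ca = 2)   # 100/(Ca+2) = 25 ms
#' @export
gate_time_constant <- function(current, gate, V = NULL, Ca = NULL, cell = NULL) {
  cell <- .cell_for(current, cell)
  if (current == "CaK") {
    if (is.null(Ca) || any(Ca <= 0)) stop("'CaK' requires Ca > 0")
  } else if (is.null(V) || any(!is.finite(V))) stop("finite V required")
  .gate_tables(current, gate, V, Ca, cell)$tau
}

#' Initial neuron state
#'
#' Membrane potential at the leak reversal, every gate at its steady state
#' for that potential and (for LNs) calcium at its equilibrium concentration.
#' The 1 s pre-stimulus period of each trial serves as settling time.
#'
#' @param cell `"PN"` or `"LN"`.
#' @param params model parameters, see [al_params()].
#' @return A named list with `V`, the gate variables of the cell's current
#'   set, and `Ca` for LNs.
#' @export
neuron_state <- function(cell = c("PN", "LN"), params = al_params()) {
  cell <- match.arg(cell)
  if (cell == "PN") {
    V <- params$pn$E_L
    list(V = V,
         m_Na = gate_steady_state("Na", "m", V),
         h_Na = gate_steady_state("Na", "h", V),
         m_K = gate_steady_state("K", "m", V, cell = "PN"),
         m_A = gate_steady_state("A", "m", V),
         h_A = gate_steady_state("A", "h", V))
  } else {
    V <- params$ln$E_L
    Ca <- params$ca$Ca_inf
    list(V = V,
         m_Ca = gate_steady_state("Ca", "m", V),
         h_Ca = gate_steady_state("Ca", "h", V),
         m_CaK = gate_steady_state("CaK", "m", Ca = Ca),
         m_K = gate_steady_state("K", "m", V, cell = "LN"),
         Ca = Ca)
  }
}

#' Right-hand side of the single-cell membrane equations
#'
#' Evaluates dV/dt, the gate derivatives and (for LNs) the calcium
#' derivative at a given state. `I_syn` and `I_stim` follow the sign
#' convention of the membrane equation: positive `I_stim` depolarises.
#'
#' @param state a state list as returned by [neuron_state()].
#' @param cell `"PN"` or `"LN"`.
#' @param I_syn synaptic current (uA/cm2, outward positive).
#' @param I_stim input current (uA/cm2, depolarising positive).
#' @param params model parameters.
#' @return A named list of time derivatives matching the state fields.
#' @export
membrane_rhs <- function(state, cell = c("PN", "LN"), I_syn = 0, I_stim = 0,
                         params = al_params()) {
  cell <- match.arg(cell)
  if (!all(vapply(state, is.finite, logical(1))) ||
      !is.finite(I_syn) || !is.finite(I_stim)) {
    stop("non-finite state or input in membrane_rhs")
  }
  V <- state$V
  gd <- function(current, gate, x, Ca = NULL) {
    tb <- .gate_tables(current, gate, V, Ca, cell)
    (tb$inf - x) / tb$tau
  }
  if (cell == "PN") {
    p <- params$pn
    I_int <- p$g_Na * state$m_Na^3 * state$h_Na * (V - p$E_Na) +
      p$g_K * state$m_K^4 * (V - p$E_K) +
      p$g_A * state$m_A^4 * state$h_A * (V - p$E_K)
    list(V = (-p$g_L * (V - p$E_L) - I_int - I_syn + I_stim) / p$C_m,
         m_Na = gd("Na", "m", state$m_Na),
         h_Na = gd("Na", "h", state$h_Na),
         m_K = gd("K", "m", state$m_K),
         m_A = gd("A", "m", state$m_A),
         h_A = gd("A", "h", state$h_A))
  } else {
    p <- params$ln
    ca <- params$ca
    I_Ca <- p$g_Ca * state$m_Ca^2 * state$h_Ca * (V - p$E_Ca)
    I_int <- I_Ca +
      p$g_CaK * state$m_CaK * (V - p$E_K) +
      p$g_K * state$m_K^4 * (V - p$E_K)
    list(V = (-p$g_L * (V - p$E_L) - I_int - I_syn + I_stim) / p$C_m,
         m_Ca = gd("Ca", "m", state$m_Ca),
         h_Ca = gd("Ca", "h", state$h_Ca),
         m_CaK = gd("CaK", "m", state$m_CaK, Ca = state$Ca),
         m_K = gd("K", "m", state$m_K),
         Ca = -ca$A * I_Ca - (state$Ca - ca$Ca_inf) / ca$tau)
  }
}

#' Naive reference integrator for a single cell
#'
#' Plain forward-Euler integration written in R, step for step the same
#' scheme as the compiled engine. Used as an equivalence oracle in the test
#' suite and for small desk calculations; for anything longer than a few
#' hundred ms use [simulate_neuron()].
#'
#' @param cell `"PN"` or `"LN"`.
#' @param duration total simulated time (ms).
#' @param dt Euler step (ms).
#' @param I_stim either a constant current (uA/cm2) or a function of time
#'   returning one.
#' @param params model parameters.
#' @return A data.frame with columns `t`, `V` (and `Ca` for LNs).
#' @export
simulate_neuron_r <- function(cell = c("PN", "LN"), duration = 100, dt = 0.01,
                              I_stim = 0, params = al_params()) {
  cell <- match.arg(cell)
  stim <- if (is.function(I_stim)) I_stim else function(t) I_stim
  s <- neuron_state(cell, params)
  n <- round(duration / dt)
  V <- numeric(n)
  Ca <- if (cell == "LN") numeric(n) else NULL
  for (i in seq_len(n)) {
    d <- membrane_rhs(s, cell, I_syn = 0, I_stim = stim((i - 1) * dt),
                      params = params)
    for (nm in names(s)) s[[nm]] <- s[[nm]] + dt * d[[nm]]
    V[i] <- s$V
    if (cell == "LN") Ca[i] <- s$Ca
  }
  out <- data.frame(t = seq_len(n) * dt, V = V)
  if (cell == "LN") out$Ca <- Ca
  out
}

#' Resting potential by root finding
#'
#' Solves for the membrane potential at which the full right-hand side
#' vanishes with all gates at steady state, independently of the
#' time-stepping scheme.
#'
#' @inheritParams neuron_state
#' @param interval search bracket (mV).
#' @return Resting potential in mV.
#' @export
resting_potential <- function(cell = c("PN", "LN"), params = al_params(),
                              interval = NULL) {
  cell <- match.arg(cell)
  # the upper bracket stays below the spike-initiation region
  if (is.null(interval)) interval <- if (cell == "PN") c(-90, -58) else c(-90, -45)
  f <- function(V) {
    s <- if (cell == "PN") {
      list(V = V,
           m_Na = gate_steady_state("Na", "m", V),
           h_Na = gate_steady_state("Na", "h", V),
           m_K = gate_steady_state("K", "m", V, cell = "PN"),
           m_A = gate_steady_state("A", "m", V),
           h_A = gate_steady_state("A", "h", V))
    } else {
      list(V = V,
           m_Ca = gate_steady_state("Ca", "m", V),
           h_Ca = gate_steady_state("Ca", "h", V),
           m_CaK = gate_steady_state("CaK", "m", Ca = params$ca$Ca_inf),
           m_K = gate_steady_state("K", "m", V, cell = "LN"),
           Ca = params$ca$Ca_inf)
    }
    membrane_rhs(s, cell, params = params)$V
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Spike width at a fixed voltage threshold
#'
#' Width of the first action potential in a voltage trace, measured between
#' the upward and the subsequent downward crossing of `threshold`.
#'
#' @param t,V time (ms) and voltage (mV) vectors of equal length.
#' @param threshold crossing level (mV); −40 mV is used for PN sodium
#'   spikes and −30 mV for LN calcium spikes.
#' @param which index of the spike to measure (1 = first).
#' @return Width in ms, or `NA` if no complete spike is found.
#' @export
spike_width <- function(t, V, threshold, which = 1) {
  n <- length(V)
  up <- which(V[-1] >= threshold & V[-n] < threshold)
  dn <- which(V[-1] < threshold & V[-n] >= threshold)
  if (length(up) < which) return(NA_real_)
  u <- up[which]
  d <- dn[dn > u]
  if (!length(d)) return(NA_real_)
  t[d[1]] - t[u]
}
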