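#' Model parameters for the antennal-lobe network
#'
#' Returns the full parameter set of the model: passive membrane properties,
#' maximal conductances and reversal potentials of the intrinsic currents,
#' synaptic kinetics, intracellular calcium dynamics, connection
#' probabilities, stimulus constants and integration settings. Individual
#' entries can be overridden by name, which is how the network variants and
#' sensitivity checks are realised.
#'
#' Units follow the usual conductance-based convention: membrane capacitance
#' in uF/cm2, conductances in mS/cm2, potentials in mV, time in ms, currents
#' as densities in uA/cm2 (input spike strengths quoted in uA assume unit
#' membrane area), calcium in mM.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of parameters.
#' @examples
#' p <- al_params()
#' p$pn$g_Na
#' @export
al_params <- function(...) {
  p <- list(
    ## passive membrane
    pn = list(
      C_m = 1.0, g_L = 0.3, E_L = -64,
      g_Na = 120, E_Na = 40,
      g_K = 3.6, E_K = -87,
      g_A = 1.43
    ),
    ln = list(
      C_m = 1.0, g_L = 0.3, E_L = -50,
      g_Ca = 5.0, E_Ca = 140,
      g_CaK = 0.045,
      g_K = 36, E_K = -95
    ),
    ## intracellular calcium (LN)
    ca = list(A = 2e-4, Ca_inf = 2.4e-4, tau = 150),
    ## synaptic kinetics
    syn = list(
      ## fast GABA-A: continuous release, sigmoidal transmitter
      gaba = list(alpha = 10, beta = 0.16, E = -70, V0 = -20, sigma = 1.5),
      ## nicotinic ACh: 0.3 ms transmitter pulse on presynaptic spike
      nach = list(alpha = 10, beta = 0.2, E = 0, t_max = 0.3, T_amp = 0.5),
      ## slow G-protein-coupled inhibition (GABA-B-like)
      slow = list(r1 = 0.5, r2 = 0.0013, r3 = 0.1, r4 = 0.033,
                  K = 100, E = -95, t_max = 0.3, T_amp = 0.5),
      ## maximal conductances by projection
      g_gaba_lnln = 0.3, g_gaba_lnpn = 0.36, g_slow_lnpn = 0.36,
      g_nach_pnln = 0.045, g_nach_pnpn = 0.009,
      ## re-arm time for presynaptic 0 mV crossing detection
      event_refractory = 2.0
    ),
    ## wiring
    net = list(
      n_pn = 90, n_ln = 30,
      p_pnpn = 0.1, p_pnln = 0.1, p_lnln = 0.25, p_lnpn = 0.15
    ),
    ## stimulus / input
    stim = list(
      bg_rate = 3500,          # spikes/s, PNs only
      bg_strength = 0.0654,    # uA per input spike
      n_stim_pn = 36, n_stim_ln = 12,
      n_trains = 200, train_rate = 35,    # odor drive: 200 x 35 spikes/s
      odor_strength_pn = 0.01743, odor_strength_ln = 0.01667,
      t_on = 1000, t_off = 3500,          # ms
      rise = 400, c1 = 1e5, c2 = sqrt(1000),
      ## input kernel: rectangular current pulse per input spike.
      ## tau_in/gain are the frozen calibration that realises the
      ## 2-4 spikes/s background band; gain_ln additionally scales the
      ## ORN drive to stimulated LNs so that they fire calcium spikes at
      ## roughly the network oscillation rate (see the methods vignette).
      tau_in = 1.0, gain = 4.7, gain_ln = 7.0
    ),
    ## integration / trial protocol
    sim = list(dt = 0.01, duration = 10000, n_trials = 80,
               spike_refractory = 2.0, v_decim = 10)
  )
  ov <- list(...)
  if (length(ov)) {
    for (nm in names(ov)) {
      if (!nm %in% names(p)) stop("unknown parameter group: ", nm)
      if (is.list(ov[[nm]])) p[[nm]][names(ov[[nm]])] <- ov[[nm]]
      else p[[nm]] <- ov[[nm]]
    }
  }
  p
}

## Network variants: scale factors applied to the GABA and slow conductances
## on top of one fixed wiring diagram.
.al_variants <- data.frame(
  label = c("I", "NG", "2X", "3X", "NS", "NS-2X", "NS-3X"),
  gaba_scale = c(1, 0, 2, 3, 1, 2, 3),
  slow_scale = c(1, 1, 1, 1, 0, 0, 0),
  stringsAsFactors = FALSE
)

#' Network variants
#'
#' The seven dynamical regimes studied with the model, all sharing one wiring
#' diagram: the intact network (\code{"I"}), no fast GABA (\code{"NG"}),
#' doubled/tripled GABA (\code{"2X"}, \code{"3X"}), no slow inhibition
#' (\code{"NS"}) and no slow inhibition with doubled/tripled GABA
#' (\code{"NS-2X"}, \code{"NS-3X"}).
#'
#' @param label one of \code{"I"}, \code{"NG"}, \code{"2X"}, \code{"3X"},
#'   \code{"NS"}, \code{"NS-2X"}, \code{"NS-3X"}.
#' @return A list with elements \code{label}, \code{gaba_scale},
#'   \code{slow_scale}.
#' @examples
#' al_variant("NS")
#' @export
al_variant <- function(label) {
  i <- match(label, .al_variants$label)
  if (is.na(i)) {
    stop("unknown network variant: '", label, "'; valid labels are ",
         paste(.al_variants$label, collapse = ", "))
  }
  list(label = .al_variants$label[i],
       gaba_scale = .al_variants$gaba_scale[i],
       slow_scale = .al_variants$slow_scale[i])
}
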