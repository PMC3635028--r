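## Network simulation orchestration: configuration, trials, experiments,
## and the LFP proxy.

#' Simulation configuration
#'
#' Bundles everything a reproducible run needs: the network variant, the
#' wiring seed, the odor (or none, for background-only runs), trial count
#' and duration, the integration step and the master seed. Trial seeds are
#' derived from the master seed and the trial index, and the wiring seed is
#' separate, so different variants can share one wiring diagram while
#' trials vary.
#'
#' @param variant variant label (see [al_variant()]).
#' @param wiring an [al_wiring()] object or an integer wiring seed.
#' @param odor an [al_odor()] object, or `NULL` for background drive only.
#' @param n_trials number of trials.
#' @param duration trial duration (ms); must cover the analysis epoch.
#' @param dt Euler step (ms).
#' @param seed master seed for the trial input streams.
#' @param record_v record membrane voltages (decimated) for LFP analysis.
#' @param params model parameters, see [al_params()].
#' @param scale_lnln_gaba also scale LN→LN GABA in 2X/3X variants.
#' @return An object of class `al_config`.
#' @export
al_config <- function(variant = "I", wiring = 1L, odor = NULL,
                      n_trials = 80, duration = NULL, dt = NULL,
                      seed = 1L, record_v = FALSE, params = al_params(),
                      scale_lnln_gaba = TRUE) {
  if (!inherits(wiring, "al_wiring")) wiring <- al_wiring(wiring, params)
  variant <- if (is.character(variant)) al_variant(variant) else variant
  if (is.null(duration)) duration <- params$sim$duration
  if (is.null(dt)) dt <- params$sim$dt
  if (dt <= 0) stop("dt must be positive")
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (!is.null(odor) && duration < odor$t_on) {
    stop("duration must extend past odor onset")
  }
  structure(list(variant = variant, wiring = wiring, odor = odor,
                 n_trials = as.integer(n_trials), duration = duration,
                 dt = dt, seed = as.integer(seed), record_v = record_v,
                 params = params, scale_lnln_gaba = scale_lnln_gaba),
            class = "al_config")
}

#' @export
print.al_config <- function(x, ...) {
  cat(sprintf(
    "al_config: variant %s, wiring seed %d, %s, %d trial(s) x %g ms, dt %g ms, seed %d\n",
    x$variant$label, x$wiring$seed,
    if (is.null(x$odor)) "background only" else
      sprintf("odor (seed %d)", x$odor$seed),
    x$n_trials, x$duration, x$dt, x$seed))
  invisible(x)
}

.trial_seed <- function(master, trial) {
  as.integer((as.numeric(master) * 48271 + trial * 16807) %% 2147483647)
}

.run_engine <- function(config, trial_seed, step_i_pn = NULL,
                        step_i_ln = NULL, step_t0 = 0, step_t1 = 0,
                        n_pn = NULL, n_ln = NULL, background = TRUE) {
  p <- config$params
  w <- config$wiring
  n_pn <- if (is.null(n_pn)) w$n_pn else n_pn
  n_ln <- if (is.null(n_ln)) w$n_ln else n_ln
  g <- apply_variant(config$variant, p, config$scale_lnln_gaba)
  st <- p$stim
  odor <- config$odor
  stim <- list(
    bg_rate = if (background) st$bg_rate else 0,
    bg_amp = st$bg_strength * st$gain,
    odor_rate_max = if (is.null(odor)) 0 else st$n_trains * st$train_rate,
    odor_amp_pn = st$odor_strength_pn * st$gain,
    odor_amp_ln = st$odor_strength_ln * st$gain * st$gain_ln,
    t_on = if (is.null(odor)) 0 else odor$t_on,
    t_off = if (is.null(odor)) 0 else odor$t_off,
    rise = st$rise, c1 = st$c1, c2 = st$c2, tau_in = st$tau_in,
    stim_pn = if (is.null(odor)) integer(0) else odor$pn - 1L,
    stim_ln = if (is.null(odor)) integer(0) else odor$ln - 1L,
    step_i_pn = if (is.null(step_i_pn)) numeric(0) else step_i_pn,
    step_i_ln = if (is.null(step_i_ln)) numeric(0) else step_i_ln,
    step_t0 = step_t0, step_t1 = step_t1
  )
  edges <- function(e) list(pre = as.integer(e[, "pre"] - 1L),
                            post = as.integer(e[, "post"] - 1L))
  pp <- edges(config$wiring$pn_pn); pl <- edges(config$wiring$pn_ln)
  ll <- edges(config$wiring$ln_ln); lp <- edges(config$wiring$ln_pn)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(trial_seed)
  phys <- p[c("pn", "ln", "ca", "syn")]
  .engine_run(n_pn, n_ln, pp$pre, pp$post, pl$pre, pl$post,
              ll$pre, ll$post, lp$pre, lp$post, g, stim, phys,
              config$dt, config$duration, config$record_v,
              config$params$sim$v_decim)
}

#' Run one trial
#'
#' Integrates the full network for one trial with the explicit Euler method.
#' Deterministic given (master seed, wiring seed, trial index). Spikes are
#' detected as upward 0 mV crossings with a 2 ms re-arm, the same criterion
#' that triggers the event-driven synapses.
#'
#' @param config an [al_config()].
#' @param trial trial index (1-based).
#' @return An `al_spikes` object holding this single trial (see
#'   [run_experiment()]); if `config$record_v` is set, decimated PN and LN
#'   voltage matrices are attached as `v_pn` / `v_ln` elements.
#' @export
run_trial <- function(config, trial = 1L) {
  res <- .run_engine(config, .trial_seed(config$seed, trial))
  tr <- list(pn = res$spikes_pn, ln = res$spikes_ln)
  out <- .al_spikes(list(tr), config, trials = trial)
  if (config$record_v) {
    out$v_pn <- list(res$v_pn)
    out$v_ln <- list(res$v_ln)
    out$v_dt <- res$v_dt
  }
  out
}

.al_spikes <- function(trials_list, config, trials = seq_along(trials_list)) {
  structure(list(
    trials = trials_list,
    n_pn = config$wiring$n_pn, n_ln = config$wiring$n_ln,
    trial_index = as.integer(trials),
    t_on = if (is.null(config$odor)) NA_real_ else config$odor$t_on,
    t_off = if (is.null(config$odor)) NA_real_ else config$odor$t_off,
    duration = config$duration, dt = config$dt,
    variant = config$variant$label,
    wiring_seed = config$wiring$seed, seed = config$seed,
    odor_seed = if (is.null(config$odor)) NA_integer_ else config$odor$seed
  ), class = "al_spikes")
}

#' Run a multi-trial experiment
#'
#' Runs `config$n_trials` independent trials (distinct derived seeds, same
#' wiring) and collects all spike trains.
#'
#' @param config an [al_config()].
#' @param progress print a dot per trial.
#' @return An object of class `al_spikes`: per trial, per neuron spike-time
#'   vectors (`$trials[[k]]$pn[[i]]`, `$trials[[k]]$ln[[j]]`, times in ms),
#'   with trial metadata (onset, offset, dt, variant, seeds). With
#'   `config$record_v`, decimated voltage matrices per trial in `$v_pn`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  trials <- vector("list", config$n_trials)
  vs_pn <- if (config$record_v) vector("list", config$n_trials) else NULL
  vs_ln <- if (config$record_v) vector("list", config$n_trials) else NULL
  v_dt <- NULL
  for (k in seq_len(config$n_trials)) {
    res <- .run_engine(config, .trial_seed(config$seed, k))
    trials[[k]] <- list(pn = res$spikes_pn, ln = res$spikes_ln)
    if (config$record_v) {
      vs_pn[[k]] <- res$v_pn; vs_ln[[k]] <- res$v_ln; v_dt <- res$v_dt
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- .al_spikes(trials, config)
  if (config$record_v) {
    out$v_pn <- vs_pn; out$v_ln <- vs_ln; out$v_dt <- v_dt
  }
  out
}

#' @export
print.al_spikes <- function(x, ...) {
  npn <- sum(vapply(x$trials, function(tr) sum(lengths(tr$pn)), numeric(1)))
  nln <- sum(vapply(x$trials, function(tr) sum(lengths(tr$ln)), numeric(1)))
  cat(sprintf(
    "al_spikes: %d trial(s) x %g ms, variant %s, %d PN / %d LN spikes\n",
    length(x$trials), x$duration, x$variant, npn, nln))
  invisible(x)
}

#' Trial-averaged firing rates
#'
#' @param spikes an `al_spikes` object.
#' @param epoch `c(t0, t1)` window in ms (default: the whole trial).
#' @param cells `"pn"` or `"ln"`.
#' @return Numeric vector of per-neuron rates (spikes/s), averaged over
#'   trials.
#' @export
firing_rates <- function(spikes, epoch = NULL, cells = c("pn", "ln")) {
  cells <- match.arg(cells)
  if (is.null(epoch)) epoch <- c(0, spikes$duration)
  n <- if (cells == "pn") spikes$n_pn else spikes$n_ln
  counts <- numeric(n)
  for (tr in spikes$trials) {
    counts <- counts + vapply(tr[[cells]], function(s)
      sum(s >= epoch[1] & s <= epoch[2]), numeric(1))
  }
  counts / length(spikes$trials) / ((epoch[2] - epoch[1]) / 1000)
}

#' Local field potential proxy and power spectrum
#'
#' The LFP is approximated by the mean subthreshold PN membrane potential:
#' voltages are clipped at `clip` (default −40 mV) so that the large,
#' cell-specific spike transients do not dominate the population signal,
#' averaged over PNs, and mean-subtracted over the analysis window. The
#' spectrum is the lightly smoothed (modified Daniell, span 3) periodogram
#' of the windowed LFP, averaged over trials; the peak frequency is
#' reported within a stated band (default 5-40 Hz).
#'
#' @param spikes an `al_spikes` object recorded with `record_v = TRUE`.
#' @param window `c(t0, t1)` analysis window in ms.
#' @param band frequency band (Hz) searched for the peak.
#' @param clip spike-clipping level (mV); `Inf` disables clipping.
#' @return A list with `freq` (Hz), `power` (trial-averaged periodogram),
#'   `peak_freq` (Hz within `band`), and the per-trial LFP matrix `lfp`
#'   (rows = time samples at `v_dt` spacing).
#' @export
compute_lfp <- function(spikes, window, band = c(5, 40), clip = -40) {
  if (is.null(spikes$v_pn)) stop("spikes were recorded without voltages; ",
                                 "set record_v = TRUE in al_config()")
  v_dt <- spikes$v_dt
  if (window[2] > spikes$duration || window[1] < 0) {
    stop("window outside the trial")
  }
  i0 <- max(1L, ceiling(window[1] / v_dt))
  i1 <- floor(window[2] / v_dt)
  pow <- NULL
  lfps <- NULL
  for (v in spikes$v_pn) {
    lfp <- rowMeans(pmin(v[i0:i1, , drop = FALSE], clip))
    lfp <- lfp - mean(lfp)
    sp <- stats::spec.pgram(stats::ts(lfp, deltat = v_dt / 1000),
                            taper = 0, detrend = TRUE, spans = 3,
                            plot = FALSE)
    pow <- if (is.null(pow)) sp$spec else pow + sp$spec
    lfps <- cbind(lfps, lfp)
  }
  pow <- pow / length(spikes$v_pn)
  freq <- sp$freq
  inb <- freq >= band[1] & freq <= band[2]
  peak <- freq[inb][which.max(pow[inb])]
  list(freq = freq, power = pow, peak_freq = peak, lfp = lfps, v_dt = v_dt)
}

#' Single-neuron simulation with the production engine
#'
#' Runs one isolated PN or LN (no synapses) with optional constant step
#' current and/or the background Poisson drive, using exactly the same
#' compiled integrator as the network.
#'
#' @param cell `"PN"` or `"LN"`.
#' @param duration total time (ms).
#' @param I_step constant current (uA/cm2) applied during `step_window`.
#' @param step_window `c(t0, t1)` in ms (default: the whole run).
#' @param background apply the 3500 spikes/s background drive (PNs).
#' @param dt Euler step (ms).
#' @param seed seed for the input stream.
#' @param record_v record the voltage trace (at full dt resolution when
#'   `v_decim = 1`).
#' @param v_decim voltage decimation factor.
#' @param params model parameters.
#' @return A list with `spikes` (times in ms) and, if recorded, `t` and `V`.
#' @export
simulate_neuron <- function(cell = c("PN", "LN"), duration = 1000,
                            I_step = 0, step_window = NULL,
                            background = FALSE, dt = NULL, seed = 1,
                            record_v = TRUE, v_decim = 1,
                            params = al_params()) {
  cell <- match.arg(cell)
  if (is.null(dt)) dt <- params$sim$dt
  if (is.null(step_window)) step_window <- c(0, duration)
  n_pn <- if (cell == "PN") 1L else 0L
  n_ln <- 1L - n_pn
  wiring <- structure(list(
    n_pn = n_pn, n_ln = n_ln,
    pn_pn = cbind(pre = integer(0), post = integer(0)),
    pn_ln = cbind(pre = integer(0), post = integer(0)),
    ln_ln = cbind(pre = integer(0), post = integer(0)),
    ln_pn = cbind(pre = integer(0), post = integer(0)),
    seed = 0L, p = c(pn_pn = 0, pn_ln = 0, ln_ln = 0, ln_pn = 0)),
    class = "al_wiring")
  config <- al_config(variant = "I", wiring = wiring, odor = NULL,
                      n_trials = 1, duration = duration, dt = dt,
                      seed = seed, record_v = record_v, params = params)
  config$params$sim$v_decim <- v_decim
  res <- .run_engine(config, .trial_seed(seed, 1),
                     step_i_pn = if (cell == "PN") I_step else NULL,
                     step_i_ln = if (cell == "LN") I_step else NULL,
                     step_t0 = step_window[1], step_t1 = step_window[2],
                     background = background && cell == "PN")
  out <- list(spikes = if (cell == "PN") res$spikes_pn[[1]] else res$spikes_ln[[1]])
  if (record_v) {
    v <- if (cell == "PN") res$v_pn else res$v_ln
    out$V <- as.numeric(v[, 1])
    out$t <- seq_len(length(out$V)) * res$v_dt
  }
  out
}
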