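## Plain-text persistence for spike data and the reproduction dispatcher.

#' Write / read spike data as plain text
#'
#' Three-column format (`trial neuron_id time_ms`; neuron ids 1..n_pn for
#' PNs, n_pn+1..n_pn+n_ln for LNs) with header comments carrying the trial
#' metadata, so a stored run can be reloaded with identical spike-time
#' arrays.
#'
#' @param spikes an `al_spikes` object.
#' @param path file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns
#'   an `al_spikes` object.
#' @export
write_spikes <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf(
    "# al_spikes n_pn=%d n_ln=%d n_trials=%d duration=%.10g dt=%.10g t_on=%.10g t_off=%.10g variant=%s wiring_seed=%d seed=%d odor_seed=%d",
    spikes$n_pn, spikes$n_ln, length(spikes$trials), spikes$duration,
    spikes$dt, spikes$t_on, spikes$t_off, spikes$variant,
    spikes$wiring_seed, spikes$seed, spikes$odor_seed)
  writeLines(meta, con)
  for (k in seq_along(spikes$trials)) {
    tr <- spikes$trials[[k]]
    for (i in seq_along(tr$pn)) {
      s <- tr$pn[[i]]
      if (length(s)) writeLines(sprintf("%d %d %.17g", k, i, s), con)
    }
    for (j in seq_along(tr$ln)) {
      s <- tr$ln[[j]]
      if (length(s)) writeLines(sprintf("%d %d %.17g", k, spikes$n_pn + j, s), con)
    }
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  body <- lines[-1]
  getv <- function(key, as = as.numeric) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    suppressWarnings(as(sub(paste0(key, "="), "", m)))
  }
  n_pn <- getv("n_pn", as.integer); n_ln <- getv("n_ln", as.integer)
  n_trials <- getv("n_trials", as.integer)
  trials <- replicate(n_trials, list(
    pn = replicate(n_pn, numeric(0), simplify = FALSE),
    ln = replicate(n_ln, numeric(0), simplify = FALSE)), simplify = FALSE)
  if (length(body)) {
    parts <- matrix(as.numeric(unlist(strsplit(body, " ", fixed = TRUE))),
                    ncol = 3, byrow = TRUE)
    for (k in unique(parts[, 1])) {
      sub_k <- parts[parts[, 1] == k, , drop = FALSE]
      for (id in unique(sub_k[, 2])) {
        s <- sub_k[sub_k[, 2] == id, 3]
        if (id <= n_pn) trials[[k]]$pn[[id]] <- s
        else trials[[k]]$ln[[id - n_pn]] <- s
      }
    }
  }
  structure(list(
    trials = trials, n_pn = n_pn, n_ln = n_ln,
    trial_index = seq_len(n_trials),
    t_on = getv("t_on"), t_off = getv("t_off"),
    duration = getv("duration"), dt = getv("dt"),
    variant = getv("variant", as.character),
    wiring_seed = getv("wiring_seed", as.integer),
    seed = getv("seed", as.integer),
    odor_seed = getv("odor_seed", as.integer)), class = "al_spikes")
}

#' Recompute a headline quantity of the model
#'
#' Dispatcher reproducing the model's reference quantities at a reduced,
#' stated scale: single-cell spike widths, input-calibration rates, the
#' slow-synapse activation count, the LFP peak frequency, the
#' disinhibited-PN fraction and the temporally-bound-PN firing rate.
#' `scripts/acceptance.R` is a thin wrapper around this function.
#'
#' @param what one of `"pn_spike_width"`, `"ln_spike_width"`,
#'   `"background_rate"`, `"stimulated_rate_min"`, `"lfp_peak"`,
#'   `"disinhibited_fraction"`, `"bound_pn_rate"`, `"slow_half_activation_spikes"`,
#'   or `"all"`.
#' @param seed master seed used for every stochastic component.
#' @param n_trials trial count for the network-level quantities.
#' @param wiring_seed wiring seed.
#' @param progress print progress dots during network runs.
#' @return A named list with `value` and `n` (problem size) per quantity.
#' @export
reproduce <- function(what = "all", seed = 1, n_trials = 20,
                      wiring_seed = 1, progress = FALSE) {
  all_ids <- c("pn_spike_width", "ln_spike_width", "background_rate",
               "stimulated_rate_min", "lfp_peak", "disinhibited_fraction",
               "bound_pn_rate", "slow_half_activation_spikes")
  if (identical(what, "all")) what <- all_ids
  bad <- setdiff(what, all_ids)
  if (length(bad)) stop("unknown quantity id(s): ", paste(bad, collapse = ", "))
  env <- new.env()
  out <- lapply(what, function(id) .reproduce_one(id, seed, n_trials,
                                                  wiring_seed, env, progress))
  stats::setNames(out, what)
}

## shared simulation cache lives in `env` so e.g. the NS run feeds both the
## disinhibited fraction and the bound-PN rate
.reproduce_one <- function(id, seed, n_trials, wiring_seed, env, progress) {
  get_run <- function(variant, n, record_v = FALSE, duration = 2100) {
    key <- paste(variant, n, record_v, duration)
    if (is.null(env[[key]])) {
      cfg <- al_config(variant, al_wiring(wiring_seed), al_odor(1),
                       n_trials = n, duration = duration,
                       seed = seed, record_v = record_v)
      env[[key]] <- run_experiment(cfg, progress = progress)
    }
    env[[key]]
  }
  switch(id,
    pn_spike_width = {
      r <- simulate_neuron("PN", duration = 1500, I_step = 2,
                           step_window = c(500, 1500), seed = seed)
      list(value = spike_width(r$t, r$V, -40), n = 1)
    },
    ln_spike_width = {
      r <- simulate_neuron("LN", duration = 2500, I_step = 3.3,
                           step_window = c(500, 2500), seed = seed)
      list(value = spike_width(r$t, r$V, -30), n = 1)
    },
    background_rate = {
      ncell <- 10; nsec <- 30
      rates <- vapply(seq_len(ncell), function(i) {
        r <- simulate_neuron("PN", duration = nsec * 1000, background = TRUE,
                             seed = seed + i, record_v = FALSE)
        length(r$spikes) / nsec
      }, numeric(1))
      list(value = mean(rates), n = ncell)
    },
    stimulated_rate_min = {
      sp <- get_run("I", 5)
      stim_pn <- al_odor(1)$pn
      r <- firing_rates(sp, c(sp$t_on, sp$t_on + 1000))[stim_pn]
      act <- r[r > 4]   # above the 2-4 spikes/s background band
      list(value = min(act), n = length(act))
    },
    lfp_peak = {
      sp <- get_run("I", 8, record_v = TRUE, duration = 1600)
      lfp <- compute_lfp(sp, c(sp$t_on, sp$t_on + 500))
      list(value = lfp$peak_freq, n = length(sp$trials))
    },
    disinhibited_fraction = {
      spi <- get_run("I", n_trials)
      spn <- get_run("NS", n_trials)
      ep <- c(spi$t_on, spi$t_on + 1000)
      dis <- classify_disinhibited(firing_rates(spi, ep),
                                   firing_rates(spn, ep))
      list(value = length(dis) / spi$n_pn, n = n_trials)
    },
    bound_pn_rate = {
      spn <- get_run("NS", n_trials)
      ep <- c(spn$t_on, spn$t_on + 1000)
      rec <- extract_subsets(spn, "BI3", threshold = 0.65, w = 20, epoch = ep)
      ids <- pooled_subset(rec)
      list(value = mean(firing_rates(spn, ep)[ids]), n = length(ids))
    },
    slow_half_activation_spikes = {
      list(value = slow_half_activation_spikes(), n = 1)
    })
}

#' Presynaptic calcium spikes needed to half-activate the slow conductance
#'
#' Drives the slow-synapse cascade of a PN's expected afferent LN pool
#' (4 to 5 LNs at the 0.15 connection probability) with synchronized 20 Hz
#' presynaptic calcium spikes from rest and counts the spikes per LN until
#' the quartic Hill activation factor of the summed G-protein concentration
#' first reaches 0.5.
#'
#' @param n_afferents number of afferent LNs (default 4.5, the
#'   expectation 30 x 0.15).
#' @param rate presynaptic firing rate (spikes/s).
#' @param dt Euler step (ms).
#' @param t_max maximal simulated time (ms).
#' @return Number of presynaptic spikes (per LN) fired strictly before
#'   half-activation; `Inf` if never reached.
#' @export
slow_half_activation_spikes <- function(n_afferents = 4.5, rate = 20,
                                        dt = 0.01, t_max = 2000) {
  p <- al_params()
  isi_steps <- round(1000 / rate / dt)
  pulse_steps <- round(p$syn$slow$t_max / dt)
  n <- round(t_max / dt)
  R <- 0; G <- 0   # one afferent; all afferents identical and synchronized
  for (s in seq_len(n)) {
    since_onset <- (s - 1) %% isi_steps
    T_fac <- if (since_onset <= pulse_steps) p$syn$slow$T_amp else 0
    st <- slow_step(R, G, T_fac, dt, p)
    R <- st$R; G <- st$G
    if (slow_activation(n_afferents * G, p) >= 0.5) {
      return((s - 1) %/% isi_steps + 1)   # pulse onsets so far
    }
  }
  Inf
}
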