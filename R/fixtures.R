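## Deterministic spike-train fixtures with known correlation structure, so
## every statistic is testable without the biophysical simulator.

#' Build a spike container from explicit spike times
#'
#' Wraps hand-written spike-time vectors in the same container the
#' simulator produces, for desk calculations and oracle tests.
#'
#' @param times a list of numeric vectors (one per neuron, times in ms) for
#'   a single trial, or a list of such lists (one per trial).
#' @param duration trial duration (ms).
#' @param t_on optional stimulus onset for epoch defaults.
#' @return An `al_spikes` object (PNs only).
#' @export
fixture_from_times <- function(times, duration, t_on = NA_real_) {
  if (length(times) && is.list(times[[1]])) trials <- times
  else trials <- list(times)
  n <- length(trials[[1]])
  structure(list(
    trials = lapply(trials, function(tt) list(pn = tt, ln = list())),
    n_pn = n, n_ln = 0L, trial_index = seq_along(trials),
    t_on = t_on, t_off = NA_real_, duration = duration, dt = NA_real_,
    variant = "fixture", wiring_seed = NA_integer_, seed = NA_integer_,
    odor_seed = NA_integer_), class = "al_spikes")
}

#' Generate a correlated/uncorrelated spike-train fixture
#'
#' Emulates the three raster regimes used to contrast the synchrony ratio
#' and the binding index:
#' \describe{
#'   \item{`independent`}{homogeneous Poisson per neuron at `rate`; low
#'     rate gives low SR and low BI, high rate gives low SR but high BI.}
#'   \item{`triplet-correlated`}{a master event train at `master_rate`; at
#'     each event, with probability `p` the whole group fires one jittered
#'     spike per member (a bound event); each member additionally has a
#'     private Poisson train at `private_rate`. Genuine n-point
#'     correlation: high SR and high BI.}
#'   \item{`pairwise-only`}{a master event train at `master_rate`; at each
#'     event every member fires independently with probability `p`.
#'     Conditioned on one member's spike the others fire independently, so
#'     pairwise conditionals are high (about `p`) while the SR stays near
#'     0 — co-firing driven by 2-point structure only.}
#' }
#' Jitter is truncated Gaussian within ±`w_detect`/4, so that any two
#' members of one event lie within `w_detect`/2 of each other and the event
#' is guaranteed detectable at the default 20 ms analysis window.
#'
#' @param mode one of `"independent"`, `"triplet-correlated"`,
#'   `"pairwise-only"`.
#' @param n_neurons group size (default 3).
#' @param rate per-neuron rate for `independent` (spikes/s).
#' @param master_rate master event rate (events/s) for the correlated
#'   modes.
#' @param p participation probability at a master event.
#' @param private_rate per-member independent rate (spikes/s) added in
#'   `triplet-correlated` mode.
#' @param jitter SD of the spike-time jitter around an event (ms).
#' @param w_detect detection window the jitter truncation respects (ms).
#' @param duration trial duration (ms).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return An `al_spikes` object with `n_neurons` PNs.
#' @export
fixture_spikes <- function(mode = c("independent", "triplet-correlated",
                                    "pairwise-only"),
                           n_neurons = 3, rate = 2, master_rate = 5,
                           p = 0.9, private_rate = master_rate * p / 2,
                           jitter = 3, w_detect = 20, duration = 1000,
                           n_trials = 20, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, master_rate >= 0, jitter >= 0, p >= 0, p <= 1)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  half <- w_detect / 4
  jit <- function(n) {
    x <- stats::rnorm(n, 0, max(jitter, 1e-9))
    pmax(pmin(x, half - 1e-6), -half + 1e-6)
  }
  pois <- function(r) {
    n <- stats::rpois(1, r * duration / 1000)
    sort(stats::runif(n, 0, duration))
  }
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    tt <- vector("list", n_neurons)
    if (mode == "independent") {
      for (i in seq_len(n_neurons)) tt[[i]] <- pois(rate)
    } else {
      ev <- pois(master_rate)
      for (i in seq_len(n_neurons)) tt[[i]] <- numeric(0)
      if (mode == "triplet-correlated") {
        bound <- ev[stats::runif(length(ev)) < p]
        for (i in seq_len(n_neurons)) {
          tt[[i]] <- c(bound + jit(length(bound)), pois(private_rate))
        }
      } else {
        for (i in seq_len(n_neurons)) {
          mine <- ev[stats::runif(length(ev)) < p]
          tt[[i]] <- mine + jit(length(mine))
        }
      }
      for (i in seq_len(n_neurons)) {
        s <- sort(tt[[i]])
        tt[[i]] <- s[s >= 0 & s <= duration]
      }
    }
    trials[[k]] <- tt
  }
  out <- fixture_from_times(trials, duration)
  out$variant <- paste0("fixture:", mode)
  out$seed <- as.integer(seed)
  out
}
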