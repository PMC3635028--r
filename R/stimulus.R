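## Odor stimulus construction and input drive.
##
## Each odor stimulates 36 of the 90 PNs and 12 of the 30 LNs. Receptor
## input is a stochastic point process: 200 independent 35 spikes/s trains
## per stimulated cell (simulated as one aggregated Poisson process of rate
## 7000 spikes/s by superposition), modulated by the rise/plateau/decay
## envelope. All PNs additionally receive an independent 3500 spikes/s
## background train. Each input event triggers a rectangular current pulse
## of the quoted per-spike strength lasting tau_in, scaled by a global gain
## that is calibrated once against the published firing-rate bands
## (background 2-4 spikes/s, active stimulated PNs 10-40 spikes/s) and then
## frozen in the default parameters.

#' Odor input envelope
#'
#' Rate multiplier of the receptor drive: Gaussian-shaped rise over the
#' 400 ms after onset, plateau at 1 until offset, root-exponential decay
#' afterwards (decay time about 1 s); 0 before onset.
#'
#' @param t time (ms), vectorised.
#' @param stim list with `t_on`, `t_off`, `rise`, `c1`, `c2` (defaults from
#'   [al_params()]).
#' @return Envelope value(s) in \[0, 1\].
#' @examples
#' p <- al_params()$stim
#' odor_envelope(p$t_on + 400, p)   # 1 at plateau onset
#' @export
odor_envelope <- function(t, stim = al_params()$stim) {
  r <- numeric(length(t))
  rising <- t >= stim$t_on & t < stim$t_on + stim$rise
  plateau <- t >= stim$t_on + stim$rise & t <= stim$t_off
  decay <- t > stim$t_off
  d <- t[rising] - (stim$t_on + stim$rise)
  r[rising] <- exp(-d^2 / stim$c1)
  r[plateau] <- 1
  r[decay] <- exp(-sqrt(t[decay] - stim$t_off) / stim$c2)
  r
}

#' Construct an odor
#'
#' @param seed integer seed selecting the stimulated subsets.
#' @param params model parameters.
#' @param pn,ln optional explicit index subsets (override the random draw).
#' @return An object of class `al_odor`: stimulated PN and LN index sets
#'   plus the envelope constants.
#' @export
al_odor <- function(seed = 1, params = al_params(), pn = NULL, ln = NULL) {
  st <- params$stim
  if (is.null(pn) || is.null(ln)) {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(seed + 211)
    if (is.null(pn)) pn <- sort(sample.int(params$net$n_pn, st$n_stim_pn))
    if (is.null(ln)) ln <- sort(sample.int(params$net$n_ln, st$n_stim_ln))
  }
  stopifnot(!anyDuplicated(pn), !anyDuplicated(ln))
  structure(list(pn = as.integer(pn), ln = as.integer(ln),
                 seed = as.integer(seed),
                 t_on = st$t_on, t_off = st$t_off, rise = st$rise,
                 c1 = st$c1, c2 = st$c2),
            class = "al_odor")
}

#' @export
print.al_odor <- function(x, ...) {
  cat(sprintf("Odor stimulus: %d PNs, %d LNs (seed %d), onset %g ms, offset %g ms\n",
              length(x$pn), length(x$ln), x$seed, x$t_on, x$t_off))
  invisible(x)
}

#' Construct a pair of odors with controlled overlap
#'
#' The two odors share exactly `round(36 * overlap_pn)` stimulated PNs and
#' `round(12 * overlap_ln)` stimulated LNs; the remaining members are drawn
#' disjointly. Used for the odor-specificity analyses (e.g. the similar-odor
#' pair with full LN overlap and half PN overlap).
#'
#' @param overlap_pn,overlap_ln overlap fractions in \[0, 1\].
#' @param seed integer seed.
#' @param params model parameters.
#' @return A list of two `al_odor` objects.
#' @examples
#' pr <- al_odor_pair(0.5, 1.0, seed = 1)
#' length(intersect(pr[[1]]$pn, pr[[2]]$pn))  # 18
#' @export
al_odor_pair <- function(overlap_pn, overlap_ln, seed = 1,
                         params = al_params()) {
  stopifnot(overlap_pn >= 0, overlap_pn <= 1, overlap_ln >= 0, overlap_ln <= 1)
  st <- params$stim
  n_pn <- params$net$n_pn; n_ln <- params$net$n_ln
  k_pn <- round(st$n_stim_pn * overlap_pn)
  k_ln <- round(st$n_stim_ln * overlap_ln)
  need_pn <- 2 * st$n_stim_pn - k_pn
  need_ln <- 2 * st$n_stim_ln - k_ln
  if (need_pn > n_pn || need_ln > n_ln) {
    stop("overlap not achievable: pair would need ", need_pn, " PNs and ",
         need_ln, " LNs")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed + 409)
  pool_pn <- sample.int(n_pn, need_pn)
  pool_ln <- sample.int(n_ln, need_ln)
  shared_pn <- pool_pn[seq_len(k_pn)]
  shared_ln <- pool_ln[seq_len(k_ln)]
  own1_pn <- pool_pn[k_pn + seq_len(st$n_stim_pn - k_pn)]
  own2_pn <- pool_pn[(st$n_stim_pn) + seq_len(st$n_stim_pn - k_pn)]
  own1_ln <- pool_ln[k_ln + seq_len(st$n_stim_ln - k_ln)]
  own2_ln <- pool_ln[(st$n_stim_ln) + seq_len(st$n_stim_ln - k_ln)]
  list(
    al_odor(seed, params, pn = sort(c(shared_pn, own1_pn)),
            ln = sort(c(shared_ln, own1_ln))),
    al_odor(seed + 1L, params, pn = sort(c(shared_pn, own2_pn)),
            ln = sort(c(shared_ln, own2_ln)))
  )
}

#' Sample an input event train
#'
#' Inhomogeneous Poisson event times with rate `rate_fn(t)` (spikes/s) over
#' `[0, duration]`, by thinning against `rate_max`. This is the R-level
#' counterpart of the event generator inside the compiled engine, exposed
#' for calibration and testing.
#'
#' @param rate_fn vectorised rate function of time in ms, returning
#'   spikes/s, or a single constant rate.
#' @param duration total time (ms).
#' @param rate_max upper bound on the rate (spikes/s); defaults to the
#'   constant rate if `rate_fn` is constant.
#' @param strength per-event current amplitude (uA).
#' @param seed optional seed.
#' @return A data.frame with columns `t` (ms) and `amp` (uA).
#' @export
sample_input_train <- function(rate_fn, duration, rate_max = NULL,
                               strength = 1, seed = NULL) {
  if (!is.function(rate_fn)) {
    rate <- rate_fn
    rate_fn <- function(t) rep(rate, length(t))
    if (is.null(rate_max)) rate_max <- rate
  }
  if (is.null(rate_max)) stop("rate_max required for a function rate")
  if (!is.null(seed)) {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(seed)
  }
  if (rate_max <= 0) return(data.frame(t = numeric(0), amp = numeric(0)))
  n <- stats::rpois(1, rate_max * duration / 1000)
  t <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(n) < rate_fn(t) / rate_max
  data.frame(t = t[keep], amp = rep(strength, sum(keep)))
}
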