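## Downstream coding analyses: symmetric difference ratio, disinhibited-PN
## classification, synchronous-event counting, pooled temporally bound
## subsets, the hypothetical Kenyon-cell coincidence detector, and the
## spike-scrambling control.

#' Symmetric difference ratio between two PN subsets
#'
#' Normalised overlap distance: with \eqn{n = |A| \ge k = |B|}, \eqn{r}
#' distinct ids overall and \eqn{s} shared ids,
#' \eqn{SDR = (r-s)/(n+k) - (n-k)/(n+k) = 2(k-s)/(n+k)}. 0 for identical
#' subsets, approaching 1 for disjoint subsets; the second term removes the
#' contribution of unequal cardinality. Symmetric in its arguments.
#'
#' @param A,B non-empty vectors of PN ids.
#' @return SDR value in \[0, 1\].
#' @examples
#' sdr(1:12, 13:24)          # disjoint equal size: 1
#' sdr(1:12, c(1:6, 13:18))  # half shared: 0.5
#' @export
sdr <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) stop("SDR undefined for empty subsets")
  if (length(B) > length(A)) { tmp <- A; A <- B; B <- tmp }
  n <- length(A); k <- length(B)
  s <- length(intersect(A, B))
  2 * (k - s) / (n + k)
}

#' Classify disinhibited PNs
#'
#' A PN is disinhibited if its odor-evoked firing rate (trial-averaged over
#' the 1 s epoch from onset) at least doubles when the slow inhibitory
#' synapses are removed: `rate_ns >= 2 * rate_i` with `rate_ns > 0`. A PN
#' silent in the intact network but active without slow inhibition counts
#' as disinhibited (any positive rate at least doubles zero).
#'
#' @param rates_i per-PN rates in the intact network (spikes/s).
#' @param rates_ns per-PN rates in the matching no-slow-inhibition network
#'   (same wiring, odor and epoch).
#' @return Integer vector of disinhibited PN ids.
#' @export
classify_disinhibited <- function(rates_i, rates_ns) {
  if (length(rates_i) != length(rates_ns)) {
    stop("rate vectors must describe the same neurons")
  }
  which(rates_ns >= 2 * rates_i & rates_ns > 0)
}

#' Fraction of triplet-member PNs classified as disinhibited, by threshold
#'
#' For each binding-index threshold, extracts the member PNs of all
#' triplets at or above the threshold and reports the fraction of them in
#' the disinhibited set. At threshold 0 every active PN belongs to some
#' triplet, so the fraction approaches the network-wide disinhibited
#' fraction.
#'
#' @param records a triplet data.frame from [extract_subsets()] with a
#'   `value` column (extract at threshold 0 to allow a full sweep).
#' @param disinhibited integer ids from [classify_disinhibited()].
#' @param thresholds numeric vector of thresholds to evaluate.
#' @return A data.frame with `threshold`, `n_members`, `fraction` (NA where
#'   no triplet survives).
#' @export
disinhibited_fraction_curve <- function(records, disinhibited,
                                        thresholds = seq(0, 0.9, by = 0.05)) {
  out <- data.frame(threshold = thresholds, n_members = NA_integer_,
                    fraction = NA_real_)
  for (r in seq_along(thresholds)) {
    keep <- records$value >= thresholds[r]
    ids <- unique(c(records$i[keep], records$j[keep], records$k[keep],
                    if ("m" %in% names(records)) records$m[keep]))
    out$n_members[r] <- length(ids)
    if (length(ids)) out$fraction[r] <- mean(ids %in% disinhibited)
  }
  out
}

#' Count synchronous firing events of a PN tuple
#'
#' Greedy non-overlapping counting: scanning the members' spikes in time
#' order, an event is scored whenever all members have (unconsumed) spikes
#' within a span of at most `w` ms, and the participating spikes are then
#' consumed, so one burst cannot be counted twice. Summed over trials.
#'
#' @param spikes an `al_spikes` object.
#' @param ids member PN indices (usually 3).
#' @param w maximal span of an event (ms), default 10.
#' @param epoch `c(t0, t1)` window; default first second after onset.
#' @return Total number of events (integer, summed over trials).
#' @export
count_triplet_events <- function(spikes, ids, w = 10, epoch = NULL) {
  if (w <= 0) stop("window width must be positive")
  epoch <- .default_epoch(spikes, epoch)
  total <- 0L
  for (tr in spikes$trials) {
    ts <- lapply(ids, function(i) {
      s <- tr$pn[[i]]
      s[s >= epoch[1] & s <= epoch[2]]
    })
    ptr <- rep(1L, length(ids))
    len <- lengths(ts)
    while (all(ptr <= len)) {
      cur <- vapply(seq_along(ids), function(a) ts[[a]][ptr[a]], numeric(1))
      if (max(cur) - min(cur) <= w) {
        total <- total + 1L
        ptr <- ptr + 1L
      } else {
        ptr[which.min(cur)] <- ptr[which.min(cur)] + 1L
      }
    }
  }
  total
}

#' Pool triplet records into a temporally bound subset
#'
#' Union of the member ids of a set of extracted records (deduplicated).
#'
#' @param records a data.frame from [extract_subsets()].
#' @return Sorted integer vector of PN ids.
#' @export
pooled_subset <- function(records) {
  cols <- intersect(c("i", "j", "k", "m"), names(records))
  sort(unique(as.integer(unlist(records[cols]))))
}

#' Temporally bound subset of a target size
#'
#' Adjusts the binding-index threshold by bisection (starting from
#' `start`) until the pooled subset of triplet members has the requested
#' size (e.g. the 13 PNs used for the Kenyon-cell experiment); the pooled
#' subset size is non-increasing in the threshold.
#'
#' @inheritParams conditional_joint_prob
#' @param size target number of pooled PNs.
#' @param start initial threshold.
#' @param max_iter bisection iterations.
#' @return A list with the subset `ids`, the `threshold` used and the
#'   triplet `records`; if the exact size is unreachable the closest
#'   achievable subset (preferring the smallest size >= `size`) is
#'   returned.
#' @export
bound_subset <- function(spikes, size = 13, start = 0.65, w = 20,
                         epoch = NULL, max_iter = 25) {
  epoch <- .default_epoch(spikes, epoch)
  all_rec <- extract_subsets(spikes, "BI3", threshold = 0, w = w, epoch = epoch)
  subset_at <- function(th) pooled_subset(all_rec[all_rec$value >= th, ])
  lo <- 0; hi <- 1; th <- start
  best <- NULL
  for (iter in seq_len(max_iter)) {
    ids <- subset_at(th)
    if (is.null(best) ||
        (abs(length(ids) - size) < abs(length(best$ids) - size)) ||
        (abs(length(ids) - size) == abs(length(best$ids) - size) &&
         length(ids) >= size && length(best$ids) < size)) {
      best <- list(ids = ids, threshold = th)
    }
    if (length(ids) == size) break
    if (length(ids) > size) lo <- th else hi <- th
    th <- (lo + hi) / 2
  }
  list(ids = best$ids, threshold = best$threshold,
       records = all_rec[all_rec$value >= best$threshold, ])
}

#' Kenyon-cell coincidence detector
#'
#' @param subset PN ids the detector reads from (the temporally bound
#'   subset of one odor; 13 in the reference experiment).
#' @param m required number of distinct members coincident in one window
#'   (9 in the reference experiment).
#' @param w window width (ms), default 10; also used as the dead time
#'   after each detector spike.
#' @return An object of class `kc_detector`.
#' @export
kc_detector <- function(subset, m = 9, w = 10) {
  stopifnot(m <= length(subset), w > 0)
  structure(list(subset = as.integer(subset), m = as.integer(m), w = w),
            class = "kc_detector")
}

#' Kenyon-cell response to network activity
#'
#' The detector fires at the first time a sliding window of width `w`
#' contains spikes of at least `m` distinct subset members; after each
#' detector spike a dead time of `w` is imposed.
#'
#' @param spikes an `al_spikes` object.
#' @param detector a [kc_detector()].
#' @param epoch analysis window, default first second after onset.
#' @return A list of numeric vectors, one per trial, with the KC spike
#'   times (ms).
#' @export
kc_response <- function(spikes, detector, epoch = NULL) {
  epoch <- .default_epoch(spikes, epoch)
  w <- detector$w
  lapply(spikes$trials, function(tr) {
    ev <- NULL
    for (a in seq_along(detector$subset)) {
      s <- tr$pn[[detector$subset[a]]]
      s <- s[s >= epoch[1] & s <= epoch[2]]
      if (length(s)) ev <- rbind(ev, cbind(s, a))
    }
    if (is.null(ev)) return(numeric(0))
    ev <- ev[order(ev[, 1]), , drop = FALSE]
    out <- numeric(0)
    dead_until <- -Inf
    for (r in seq_len(nrow(ev))) {
      t <- ev[r, 1]
      if (t <= dead_until) next
      inwin <- ev[, 1] > t - w & ev[, 1] <= t & ev[, 1] > dead_until
      if (length(unique(ev[inwin, 2])) >= detector$m) {
        out <- c(out, t)
        dead_until <- t + w
      }
    }
    out
  })
}

#' Fraction of trials with at least one KC response
#'
#' @inheritParams kc_response
#' @return Fraction in \[0, 1\].
#' @export
kc_response_fraction <- function(spikes, detector, epoch = NULL) {
  mean(lengths(kc_response(spikes, detector, epoch)) > 0)
}

#' Scramble spikes of a PN subset within an epoch
#'
#' Per trial and per subset member, the spikes inside the epoch (default:
#' first 500 ms after odor onset) are replaced by the same number of
#' sorted uniform draws over the epoch; spike counts, spikes outside the
#' epoch and all other neurons are untouched. The control that destroys
#' spike timing while preserving rates.
#'
#' @param spikes an `al_spikes` object.
#' @param subset PN ids to scramble.
#' @param epoch `c(t0, t1)`; default `t_on + c(0, 500)`.
#' @param seed integer seed for the redistribution.
#' @return A new `al_spikes` object.
#' @export
scramble_spikes <- function(spikes, subset, epoch = NULL, seed = 1) {
  if (is.null(epoch)) {
    if (is.na(spikes$t_on)) stop("no onset metadata; give an explicit epoch")
    epoch <- c(spikes$t_on, spikes$t_on + 500)
  }
  if (epoch[1] < 0 || epoch[2] > spikes$duration) stop("epoch outside trial")
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  out <- spikes
  for (k in seq_along(out$trials)) {
    for (i in subset) {
      s <- out$trials[[k]]$pn[[i]]
      inside <- s >= epoch[1] & s <= epoch[2]
      n <- sum(inside)
      if (n) {
        out$trials[[k]]$pn[[i]] <-
          sort(c(s[!inside], stats::runif(n, epoch[1], epoch[2])))
      }
    }
  }
  out
}
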