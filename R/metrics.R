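## Multi-neuron spike-correlation statistics: windowed conditional firing
## probabilities, the synchrony ratio (SR) on ordered PN triplets, and the
## binding index (BI) on unordered triplets/quadruplets.
##
## All probabilities are pooled over trials: for every spike of the
## conditioning neuron inside the analysis epoch, a window of width w
## centred on that spike is examined within the same trial, and a success
## is scored iff every target neuron fired at least once in the window.
## A single target spike may satisfy the windows of several conditioning
## spikes (no spike consumption), and windows are clipped at trial
## boundaries rather than discarded, so the denominator is always the
## total number of conditioning spikes in the epoch.

## Indicator matrices: for conditioning neuron i, a (#spikes-of-i x n_pn)
## logical matrix, rows = spikes of i in the epoch (pooled over trials),
## columns = "did PN j fire within the window around that spike".
.window_matrix <- function(spikes, i, w, epoch) {
  half <- w / 2
  rows <- NULL
  for (tr in spikes$trials) {
    ti <- tr$pn[[i]]
    ti <- ti[ti >= epoch[1] & ti <= epoch[2]]
    if (!length(ti)) next
    lo <- pmax(ti - half, 0)
    hi <- pmin(ti + half, spikes$duration)
    m <- matrix(FALSE, length(ti), spikes$n_pn)
    for (j in seq_len(spikes$n_pn)) {
      tj <- tr$pn[[j]]
      if (!length(tj)) next
      # spike counts of j below each window edge; >0 difference = hit
      m[, j] <- findInterval(hi, tj) > findInterval(lo - 1e-9, tj)
    }
    rows <- rbind(rows, m)
  }
  if (is.null(rows)) matrix(FALSE, 0, spikes$n_pn) else rows
}

#' Windowed conditional joint firing probability
#'
#' Probability that every neuron of a target set fires within a `w` ms
#' window centred at a spike of the conditioning neuron, estimated over all
#' conditioning spikes inside the epoch, pooled across trials.
#'
#' @param spikes an `al_spikes` object (or fixture with the same shape).
#' @param i conditioning PN index.
#' @param targets vector of target PN indices (may be empty: the vacuous
#'   conjunction has probability 1).
#' @param w window width (ms), centred.
#' @param epoch `c(t0, t1)` analysis epoch in ms; defaults to the first
#'   second after odor onset.
#' @return A list with `value` (NA if the conditioning neuron never fired
#'   in the epoch), `successes` and `n_cond` (the denominator).
#' @examples
#' # three hand-built spike trains, one trial
#' fx <- fixture_from_times(list(c(100, 200), c(105, 300), c(95, 205)), 400)
#' conditional_joint_prob(fx, 1, c(2, 3), w = 20, epoch = c(0, 400))$value
#' @export
conditional_joint_prob <- function(spikes, i, targets, w = 20, epoch = NULL) {
  epoch <- .default_epoch(spikes, epoch)
  if (i %in% targets) stop("conditioning neuron cannot be one of the targets")
  if (w <= 0) stop("window width must be positive")
  m <- .window_matrix(spikes, i, w, epoch)
  n <- nrow(m)
  if (n == 0) return(list(value = NA_real_, successes = 0L, n_cond = 0L))
  succ <- if (!length(targets)) n else sum(rowSums(m[, targets, drop = FALSE]) == length(targets))
  list(value = succ / n, successes = as.integer(succ), n_cond = as.integer(n))
}

.default_epoch <- function(spikes, epoch) {
  if (!is.null(epoch)) return(epoch)
  if (is.na(spikes$t_on)) c(0, spikes$duration) else c(spikes$t_on, spikes$t_on + 1000)
}

#' Synchrony ratio of an ordered PN triplet
#'
#' \eqn{SR_{j,k|i} = P_{j,k|i}/(P_{j|i} P_{k|i}) - 1}: the excess of the
#' conditional joint firing probability of `j` and `k` (in 20 ms windows
#' centred on spikes of `i`) over the product expected under conditional
#' independence. Ordered triplets with \eqn{P_{j|i} \le 0.5} or
#' \eqn{P_{k|i} \le 0.5} are filtered out (the measure targets temporally
#' bound subsets), as are triplets whose conditioning neuron is silent.
#' Values lie in (−1, 1): 0 under conditional independence, near 1 for
#' genuine 3-point correlation; the SR stays near 0 when neurons merely
#' co-fire due to high rates or pairwise correlation.
#'
#' @inheritParams conditional_joint_prob
#' @param j,k target PN indices.
#' @return A list with `sr` (NA when filtered out), the three conditional
#'   probabilities, and `filtered` (logical).
#' @export
synchrony_ratio <- function(spikes, i, j, k, w = 20, epoch = NULL) {
  epoch <- .default_epoch(spikes, epoch)
  stopifnot(length(unique(c(i, j, k))) == 3)
  m <- .window_matrix(spikes, i, w, epoch)
  if (nrow(m) == 0) {
    return(list(sr = NA_real_, p_jk = NA_real_, p_j = NA_real_,
                p_k = NA_real_, filtered = TRUE))
  }
  p_j <- mean(m[, j]); p_k <- mean(m[, k]); p_jk <- mean(m[, j] & m[, k])
  if (p_j <= 0.5 || p_k <= 0.5) {
    return(list(sr = NA_real_, p_jk = p_jk, p_j = p_j, p_k = p_k,
                filtered = TRUE))
  }
  list(sr = p_jk / (p_j * p_k) - 1, p_jk = p_jk, p_j = p_j, p_k = p_k,
       filtered = FALSE)
}

#' Binding index of a PN triplet or quadruplet
#'
#' \eqn{BI_{i,j,k} = \min(P_{j,k|i}, P_{i,j|k}, P_{i,k|j})} (and the
#' analogous minimum over four leave-one-out conditionals for a
#' quadruplet): whenever any one member fires, the remaining members fire
#' concurrently with at least this probability. A direct measure of
#' synchrony — high for temporally bound subsets but also for independent
#' neurons at high rate, which is exactly the contrast with the synchrony
#' ratio.
#'
#' @inheritParams conditional_joint_prob
#' @param ids 3 or 4 distinct PN indices.
#' @return The binding index in \[0, 1\]. If any member never fires in the
#'   epoch the index is 0 by convention (with attribute `undefined = TRUE`).
#' @export
binding_index <- function(spikes, ids, w = 20, epoch = NULL) {
  epoch <- .default_epoch(spikes, epoch)
  stopifnot(length(ids) %in% c(3, 4), !anyDuplicated(ids))
  vals <- numeric(length(ids))
  for (a in seq_along(ids)) {
    cp <- conditional_joint_prob(spikes, ids[a], ids[-a], w, epoch)
    if (is.na(cp$value)) {
      out <- 0
      attr(out, "undefined") <- TRUE
      return(out)
    }
    vals[a] <- cp$value
  }
  min(vals)
}

## all window matrices at once (one per conditioning neuron), plus spike
## counts -- the workhorse for exhaustive extraction
.all_window_stats <- function(spikes, w, epoch) {
  n <- spikes$n_pn
  pair <- vector("list", n)   # pair[[i]][j,k] = P_{j,k|i}; diag = P_{j|i}
  n_cond <- integer(n)
  for (i in seq_len(n)) {
    m <- .window_matrix(spikes, i, w, epoch)
    n_cond[i] <- nrow(m)
    if (nrow(m)) {
      mm <- matrix(as.numeric(m), nrow(m), n)
      pair[[i]] <- crossprod(mm) / nrow(m)
    }
  }
  list(pair = pair, n_cond = n_cond)
}

#' Exhaustive extraction of correlated / temporally bound PN subsets
#'
#' Enumerates all distinct PN combinations (ordered triplets for the
#' synchrony ratio; unordered triplets or quadruplets for the binding
#' index) and returns every record whose measure reaches the threshold.
#' Raising the threshold never adds records. An unordered triplet is
#' reported for the SR measure if any of its six orderings passes both the
#' \eqn{P > 0.5} filter and the threshold (set `all_orderings = TRUE` to
#' require all surviving orderings to pass).
#'
#' @inheritParams conditional_joint_prob
#' @param measure `"SR"`, `"BI3"` or `"BI4"`.
#' @param threshold minimum measure value.
#' @param all_orderings for `"SR"`: require every non-filtered ordering to
#'   pass instead of any.
#' @return A data.frame with the member ids (`i`, `j`, `k`\[, `m`\]) and the
#'   measure `value`; for `"SR"` the ids are sorted and `value` is the best
#'   passing ordering's SR. Attributes `measure`, `w`, `epoch`, `threshold`
#'   record the extraction settings.
#' @export
extract_subsets <- function(spikes, measure = c("SR", "BI3", "BI4"),
                            threshold, w = 20, epoch = NULL,
                            all_orderings = FALSE) {
  measure <- match.arg(measure)
  epoch <- .default_epoch(spikes, epoch)
  st <- .all_window_stats(spikes, w, epoch)
  n <- spikes$n_pn
  active <- which(st$n_cond > 0)
  out <- NULL
  if (measure == "SR") {
    recs <- list()
    cmb <- if (length(active) >= 3) utils::combn(active, 3) else
      matrix(integer(0), 3, 0)
    for (c_i in seq_len(ncol(cmb))) {
      trip <- cmb[, c_i]
      srs <- c()
      for (a in 1:3) {
        i <- trip[a]; jk <- trip[-a]
        P <- st$pair[[i]]
        p_j <- P[jk[1], jk[1]]; p_k <- P[jk[2], jk[2]]
        if (p_j > 0.5 && p_k > 0.5) {
          srs <- c(srs, P[jk[1], jk[2]] / (p_j * p_k) - 1)
        }
      }
      pass <- if (!length(srs)) FALSE
        else if (all_orderings) all(srs >= threshold) else any(srs >= threshold)
      if (pass) {
        recs[[length(recs) + 1]] <- c(trip, max(srs))
      }
    }
    out <- if (length(recs)) {
      m <- do.call(rbind, recs)
      data.frame(i = m[, 1], j = m[, 2], k = m[, 3], value = m[, 4])
    } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0))
  } else if (measure == "BI3") {
    recs <- list()
    cmb <- if (length(active) >= 3) utils::combn(active, 3) else
      matrix(integer(0), 3, 0)
    for (c_i in seq_len(ncol(cmb))) {
      trip <- cmb[, c_i]
      bi <- min(st$pair[[trip[1]]][trip[2], trip[3]],
                st$pair[[trip[2]]][trip[1], trip[3]],
                st$pair[[trip[3]]][trip[1], trip[2]])
      if (bi >= threshold) recs[[length(recs) + 1]] <- c(trip, bi)
    }
    out <- if (length(recs)) {
      m <- do.call(rbind, recs)
      data.frame(i = m[, 1], j = m[, 2], k = m[, 3], value = m[, 4])
    } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0))
  } else {
    ## quadruplets: prune via the triplet bound (BI4 <= BI3 of every
    ## contained triplet), then compute the exact triple-joint conditionals
    tri <- extract_subsets(spikes, "BI3", threshold, w, epoch)
    cand <- sort(unique(c(tri$i, tri$j, tri$k)))
    recs <- list()
    if (length(cand) >= 4) {
      wm <- lapply(seq_len(n), function(i)
        if (i %in% cand) .window_matrix(spikes, i, w, epoch) else NULL)
      cmb <- utils::combn(cand, 4)
      tri_key <- paste(tri$i, tri$j, tri$k)
      for (c_i in seq_len(ncol(cmb))) {
        quad <- cmb[, c_i]
        sub_ok <- all(apply(utils::combn(quad, 3), 2, function(tt)
          paste(tt[1], tt[2], tt[3]) %in% tri_key))
        if (!sub_ok) next
        vals <- vapply(1:4, function(a) {
          m <- wm[[quad[a]]]
          if (!nrow(m)) return(NA_real_)
          mean(rowSums(m[, quad[-a], drop = FALSE]) == 3)
        }, numeric(1))
        if (anyNA(vals)) next
        bi <- min(vals)
        if (bi >= threshold) recs[[length(recs) + 1]] <- c(quad, bi)
      }
    }
    out <- if (length(recs)) {
      mm <- do.call(rbind, recs)
      data.frame(i = mm[, 1], j = mm[, 2], k = mm[, 3], m = mm[, 4],
                 value = mm[, 5])
    } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                      m = integer(0), value = numeric(0))
  }
  attr(out, "measure") <- measure
  attr(out, "w") <- w
  attr(out, "epoch") <- epoch
  attr(out, "threshold") <- threshold
  out
}
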