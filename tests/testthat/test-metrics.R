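test_that("windowed conditional probabilities match manual enumeration", {
  fx <- fixture_from_times(list(c(100, 200), c(105, 300), c(95, 205)), 400)
  ep <- c(0, 400)
  ## at t=100: j@105 and k@95 in the 20 ms window; at t=200: no j spike
  expect_equal(conditional_joint_prob(fx, 1, c(2, 3), 20, ep)$value, 0.5)
  expect_equal(conditional_joint_prob(fx, 1, 2, 20, ep)$value, 0.5)
  expect_equal(conditional_joint_prob(fx, 1, 3, 20, ep)$value, 1.0)
  ## vacuous conjunction and silent targets
  expect_equal(conditional_joint_prob(fx, 1, integer(0), 20, ep)$value, 1.0)
  fx2 <- fixture_from_times(list(c(100, 200), numeric(0), c(95, 205)), 400)
  expect_equal(conditional_joint_prob(fx2, 1, 2, 20, ep)$value, 0)
  ## silent conditioning neuron -> undefined
  expect_true(is.na(conditional_joint_prob(fx2, 2, 1, 20, ep)$value))
  expect_error(conditional_joint_prob(fx, 1, 1, 20, ep), "targets")
})

test_that("production conditionals equal a brute-force recomputation", {
  set.seed(42)
  for (rep in 1:12) {
    nn <- 6
    tt <- lapply(1:nn, function(i) sort(runif(rpois(1, 20), 0, 1000)))
    fx <- fixture_from_times(tt, 1000)
    i <- sample(nn, 1)
    targ <- sample(setdiff(1:nn, i), sample(1:3, 1))
    a <- conditional_joint_prob(fx, i, targ, 20, c(0, 1000))$value
    b <- brute_cjp(fx, i, targ, 20, c(0, 1000))
    expect_equal(a, b, info = paste("rep", rep))
  }
})

test_that("synchrony ratio obeys its algebraic identities and filter", {
  ## perfect co-firing at moderate conditional: SR = p/(p^2) - 1
  ## construct: i fires at every event, j & k together at 60% of them
  ev <- seq(25, 1975, by = 50)   # 40 events
  on <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 8)
  fx <- fixture_from_times(list(ev, ev[on] + 1, ev[on] - 1), 2000)
  sr <- synchrony_ratio(fx, 1, 2, 3, 20, c(0, 2000))
  expect_false(sr$filtered)
  expect_equal(sr$p_j, 0.6)
  expect_equal(sr$sr, 0.6 / 0.36 - 1)
  ## conditional independence -> SR ~ 0 (exactly 0 in this construction)
  on_j <- rep(c(TRUE, FALSE), 20); on_k <- rep(c(TRUE, TRUE, FALSE),
                                               length.out = 40)
  ## j and k each co-fire with i but on unrelated schedules
  fx2 <- fixture_from_times(list(ev, ev[on_j] + 1, ev[on_k] - 1), 2000)
  sr2 <- synchrony_ratio(fx2, 1, 2, 3, 20, c(0, 2000))
  joint_expected <- mean(on_j & on_k)
  expect_equal(sr2$p_jk, joint_expected)
  ## a pairwise conditional at or below 0.5 filters the ordering out
  expect_true(sr2$filtered || sr2$p_j > 0.5)
  ## bounds: -1 < SR < 1 whenever defined
  expect_true(is.na(sr2$sr) || (sr2$sr > -1 && sr2$sr < 1))
})

test_that("SR concentrates near zero for independent Poisson triplets", {
  srs <- c()
  for (s in 1:60) {
    fx <- fixture_spikes("independent", rate = 40, n_trials = 8,
                         duration = 1000, seed = s)
    sr <- synchrony_ratio(fx, 1, 2, 3, 20, c(0, 1000))
    if (!sr$filtered) srs <- c(srs, sr$sr)
  }
  expect_gt(length(srs), 30)
  expect_lt(abs(mean(srs)), 0.05)
  expect_true(all(srs > -1 & srs < 1))
})

test_that("binding index is the minimum leave-one-out conditional", {
  ## always co-firing -> BI = 1
  ev <- seq(25, 975, by = 50)
  fx <- fixture_from_times(list(ev, ev + 2, ev - 2), 1000)
  expect_equal(binding_index(fx, 1:3, 20, c(0, 1000)), 1)
  ## never co-firing -> BI = 0
  fx0 <- fixture_from_times(list(c(100, 300), c(200, 400), c(150, 350)),
                            500)
  expect_equal(binding_index(fx0, 1:3, 4, c(0, 500)), 0)
  ## silent member -> 0 with the undefined flag
  fxs <- fixture_from_times(list(ev, ev + 2, numeric(0)), 1000)
  bi <- binding_index(fxs, 1:3, 20, c(0, 1000))
  expect_equal(as.numeric(bi), 0)
  expect_true(isTRUE(attr(bi, "undefined")))
  ## quadruplet form
  fx4 <- fixture_from_times(list(ev, ev + 2, ev - 2, ev + 4), 1000)
  expect_equal(binding_index(fx4, 1:4, 20, c(0, 1000)), 1)
  ## asymmetric case: BI = min over members
  on <- rep(c(TRUE, TRUE, FALSE), length.out = length(ev))
  fxa <- fixture_from_times(list(ev, ev[on] + 1, ev[on] - 1), 1000)
  expect_equal(binding_index(fxa, 1:3, 20, c(0, 1000)), mean(on))
})

test_that("the SR/BI contrast separates the three raster regimes", {
  ind_lo <- fixture_spikes("independent", rate = 2, n_trials = 30, seed = 5)
  ind_hi <- fixture_spikes("independent", rate = 100, n_trials = 30, seed = 5)
  corr <- fixture_spikes("triplet-correlated", master_rate = 5, p = 0.9,
                         jitter = 3, n_trials = 30, seed = 5)
  pair <- fixture_spikes("pairwise-only", master_rate = 30, p = 0.9,
                         n_trials = 30, seed = 5)
  ep <- c(0, 1000)
  bi <- function(fx) binding_index(fx, 1:3, 20, ep)
  sr <- function(fx) synchrony_ratio(fx, 1, 2, 3, 20, ep)
  ## low-rate independent: low SR (filtered or ~0) and low BI
  expect_lt(bi(ind_lo), 0.3)
  ## high-rate independent: low SR but high BI
  sr_hi <- sr(ind_hi)
  expect_false(sr_hi$filtered)
  expect_lt(abs(sr_hi$sr), 0.15)
  expect_gt(bi(ind_hi), 0.5)
  ## low-rate correlated: high SR and high BI
  sr_c <- sr(corr)
  expect_false(sr_c$filtered)
  expect_gt(sr_c$sr, sr_hi$sr + 0.15)
  expect_gt(bi(corr), 0.5)
  ## pairwise-only: conditionals above 0.5 yet SR near zero
  sr_p <- sr(pair)
  expect_false(sr_p$filtered)
  expect_gt(sr_p$p_j, 0.5)
  expect_gt(sr_p$p_k, 0.5)
  expect_lt(abs(sr_p$sr), 0.1)
  expect_lt(sr_p$sr, sr_c$sr)
})

test_that("subset extraction is exhaustive, thresholded and monotone", {
  set.seed(7)
  nn <- 8
  ev <- seq(25, 975, by = 50)
  tt <- lapply(1:nn, function(i) sort(runif(20, 0, 1000)))
  tt[[2]] <- ev + 1; tt[[4]] <- ev - 1; tt[[7]] <- ev + 3  # a bound triplet
  fx <- fixture_from_times(tt, 1000)
  ep <- c(0, 1000)
  rec <- extract_subsets(fx, "BI3", threshold = 0.8, w = 20, epoch = ep)
  expect_true(nrow(rec) >= 1)
  expect_true(any(rec$i == 2 & rec$j == 4 & rec$k == 7))
  ## every returned value equals the direct recomputation
  for (r in seq_len(nrow(rec))) {
    expect_equal(rec$value[r],
                 binding_index(fx, unlist(rec[r, c("i", "j", "k")]), 20, ep))
  }
  ## monotone in threshold
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 0.95),
                   function(th) nrow(extract_subsets(fx, "BI3", th, 20, ep)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  ## threshold above the max -> empty
  expect_identical(nrow(extract_subsets(fx, "BI3", 1.01, 20, ep)), 0L)
  ## SR records respect the ordering filter and recomputation
  rec_sr <- extract_subsets(fx, "SR", threshold = 0.2, w = 20, epoch = ep)
  for (r in seq_len(nrow(rec_sr))) {
    ids <- unlist(rec_sr[r, c("i", "j", "k")])
    best <- -Inf
    for (a in 1:3) {
      s <- synchrony_ratio(fx, ids[a], ids[-a][1], ids[-a][2], 20, ep)
      if (!s$filtered) best <- max(best, s$sr)
    }
    expect_equal(rec_sr$value[r], best)
  }
  ## quadruplet extraction finds the planted quadruplet and respects the
  ## triplet bound
  tt[[5]] <- ev + 5
  fx4 <- fixture_from_times(tt, 1000)
  rec4 <- extract_subsets(fx4, "BI4", threshold = 0.8, w = 20, epoch = ep)
  expect_true(any(apply(rec4[, c("i", "j", "k", "m")], 1, function(x)
    setequal(x, c(2, 4, 5, 7)))))
  for (r in seq_len(nrow(rec4))) {
    ids <- unlist(rec4[r, c("i", "j", "k", "m")])
    expect_equal(rec4$value[r], binding_index(fx4, ids, 20, ep))
  }
})
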