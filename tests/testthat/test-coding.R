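test_that("SDR matches its formula and symmetry", {
  expect_equal(sdr(1:12, 1:12), 0)
  expect_equal(sdr(1:12, 13:24), 1)
  expect_equal(sdr(1:12, c(1:6, 13:18)), 0.5)
  ## unequal cardinality: n=4, k=2, s=1 -> 2(2-1)/6
  expect_equal(sdr(1:4, c(4, 9)), 2 * (2 - 1) / 6)
  ## symmetry and range on random subsets
  set.seed(1)
  for (r in 1:25) {
    A <- sample(90, sample(3:20, 1)); B <- sample(90, sample(3:20, 1))
    expect_equal(sdr(A, B), sdr(B, A))
    v <- sdr(A, B)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(sdr(integer(0), 1:3), "undefined")
})

test_that("disinhibited classification uses the doubling rule", {
  ri <- c(2, 4, 0, 1, 5)
  rn <- c(5, 6, 1, 2, 0)
  d <- classify_disinhibited(ri, rn)
  expect_identical(d, c(1L, 3L, 4L))   # 2->5 yes, 4->6 no, 0->1 yes, 1->2 yes, 5->0 no
  expect_error(classify_disinhibited(1:3, 1:4), "same neurons")
})

test_that("disinhibited fraction curve has its boundary behaviors", {
  rec <- data.frame(i = c(1, 4), j = c(2, 5), k = c(3, 6),
                    value = c(0.3, 0.8))
  ## all members disinhibited -> curve 1 wherever defined
  cv <- disinhibited_fraction_curve(rec, 1:6, c(0, 0.5, 0.9))
  expect_equal(cv$fraction[1:2], c(1, 1))
  expect_true(is.na(cv$fraction[3]))
  ## empty disinhibited set -> 0
  cv0 <- disinhibited_fraction_curve(rec, integer(0), c(0, 0.5))
  expect_equal(cv0$fraction, c(0, 0))
  ## mixed: at threshold 0.5 only triplet {4,5,6} remains
  cv2 <- disinhibited_fraction_curve(rec, c(4, 5), c(0, 0.5))
  expect_equal(cv2$fraction, c(2 / 6, 2 / 3))
})

test_that("triplet event counting is greedy and non-overlapping", {
  fx <- fixture_from_times(list(c(10, 100), c(12, 103), c(15, 98)), 200)
  expect_equal(count_triplet_events(fx, 1:3, 10, c(0, 200)), 2L)
  ## single burst within w counts once
  fx1 <- fixture_from_times(list(10, 12, c(15)), 100)
  expect_equal(count_triplet_events(fx1, 1:3, 10, c(0, 100)), 1L)
  ## silent member -> 0
  fx0 <- fixture_from_times(list(c(10, 20), numeric(0), c(15)), 100)
  expect_equal(count_triplet_events(fx0, 1:3, 10, c(0, 100)), 0L)
  ## spread beyond w -> 0
  fx2 <- fixture_from_times(list(10, 30, 50), 100)
  expect_equal(count_triplet_events(fx2, 1:3, 10, c(0, 100)), 0L)
  ## consumption: a second event needs three fresh spikes
  fx3 <- fixture_from_times(list(c(10), c(12, 14), c(15, 16)), 100)
  expect_equal(count_triplet_events(fx3, 1:3, 10, c(0, 100)), 1L)
  ## manual enumeration on a hand-built raster with interleaved episodes
  fx4 <- fixture_from_times(list(c(10, 52, 300), c(14, 55, 305),
                                 c(18, 60, 990)), 1000)
  expect_equal(count_triplet_events(fx4, 1:3, 10, c(0, 1000)), 2L)
})

test_that("pooled subsets deduplicate member ids", {
  rec <- data.frame(i = c(1, 4), j = c(2, 5), k = c(3, 6), value = 1)
  expect_identical(pooled_subset(rec), 1:6)
  rec2 <- data.frame(i = c(1, 1), j = c(2, 2), k = c(3, 4), value = 1)
  expect_identical(pooled_subset(rec2), 1:4)
  expect_length(pooled_subset(rec2[0, ]), 0)
})

test_that("the KC coincidence detector requires m-of-n within the window", {
  ## 9 members firing within 5 ms once -> exactly one KC spike
  tt <- c(lapply(1:9, function(i) 500 + i * 0.5),
          lapply(10:13, function(i) numeric(0)))
  fx <- fixture_from_times(tt, 1000, t_on = 0)
  det <- kc_detector(1:13, m = 9, w = 10)
  resp <- kc_response(fx, det, c(0, 1000))
  expect_length(resp[[1]], 1)
  ## only 8 members -> no KC spike
  tt8 <- tt; tt8[[9]] <- numeric(0)
  fx8 <- fixture_from_times(tt8, 1000, t_on = 0)
  expect_length(kc_response(fx8, det, c(0, 1000))[[1]], 0)
  ## dead time: a sustained barrage yields spikes at least w apart
  ttb <- lapply(1:13, function(i) seq(100, 200, by = 2) + i * 0.1)
  fxb <- fixture_from_times(ttb, 1000, t_on = 0)
  rb <- kc_response(fxb, det, c(0, 1000))[[1]]
  expect_gt(length(rb), 1)
  expect_true(all(diff(rb) >= det$w))
  expect_error(kc_detector(1:5, m = 9), "m <= ")
})

test_that("scrambling preserves counts and only touches the epoch/subset", {
  fx <- fixture_spikes("triplet-correlated", n_neurons = 3, master_rate = 20,
                       n_trials = 5, duration = 1000, seed = 2)
  fx$t_on <- 0
  sc <- scramble_spikes(fx, subset = c(1, 3), epoch = c(0, 500), seed = 9)
  for (k in seq_along(fx$trials)) {
    for (i in 1:3) {
      a <- fx$trials[[k]]$pn[[i]]; b <- sc$trials[[k]]$pn[[i]]
      expect_length(b, length(a))
      if (i == 2) expect_identical(a, b)   # untouched neuron
      ## spikes outside the epoch untouched
      expect_identical(a[a > 500], b[b > 500])
      ## scrambled spikes stay inside the epoch
      expect_true(all(b[b <= 500] >= 0))
      expect_false(is.unsorted(b))
    }
  }
  ## member with zero spikes in the epoch is unchanged
  fx0 <- fixture_from_times(list(c(700, 800), c(100)), 1000, t_on = 0)
  sc0 <- scramble_spikes(fx0, 1, epoch = c(0, 500), seed = 1)
  expect_identical(sc0$trials[[1]]$pn[[1]], c(700, 800))
  expect_error(scramble_spikes(fx0, 1, epoch = c(-10, 500)), "epoch")
})

test_that("bound_subset bisects the threshold toward the target size", {
  ## plant a perfect triplet {1,2,3} and a weaker one {4,5,6} (member 6
  ## joins 60% of events), so different thresholds pool 3, 5 or 6 PNs
  set.seed(31)
  ev <- seq(25, 1975, by = 50)   # 40 events
  sub <- ev[1:30]
  tt <- list(ev + 1, ev - 1, ev + 3,
             sub + 1, sub - 1,
             sub[rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 6)] + 3)
  fx <- fixture_from_times(tt, 2000)
  bs <- bound_subset(fx, size = 3, start = 0.9, epoch = c(0, 2000))
  expect_length(bs$ids, 3)
  expect_setequal(bs$ids, 1:3)
  bs6 <- bound_subset(fx, size = 6, start = 0.9, epoch = c(0, 2000))
  expect_length(bs6$ids, 6)
})
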