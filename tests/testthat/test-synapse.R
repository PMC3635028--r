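test_that("GABA transmitter sigmoid has the printed midpoint and limits", {
  expect_equal(gaba_transmitter(-20), 0.5)
  expect_lt(gaba_transmitter(-80), 1e-10)
  expect_lt(1 - gaba_transmitter(10), 1e-8)
  V <- seq(-90, 30, by = 1)
  expect_true(all(diff(gaba_transmitter(V)) > 0))
})

test_that("nicotinic transmitter is a 0.3 ms rectangular pulse", {
  expect_equal(nach_transmitter(100.1, t0 = 100), 0.5)
  expect_equal(nach_transmitter(100.5, t0 = 100), 0)
  expect_equal(nach_transmitter(99.9, t0 = 100), 0)
  expect_equal(nach_transmitter(50, t0 = -Inf), 0)
})

test_that("channel kinetics follow the closed-form linear ODE", {
  p <- al_params()
  dt <- 0.01
  ## T = 0: pure exponential decay at rate beta
  O <- 0.8
  for (i in 1:5000) O <- channel_step(O, 0, 10, 0.16, dt)
  expect_equal(O, 0.8 * exp(-0.16 * 50), tolerance = 1e-3)
  ## T = 1 held: fixed point alpha/(alpha+beta)
  O <- 0
  for (i in 1:200000) O <- channel_step(O, 1, 10, 0.16, dt)
  expect_equal(O, 10 / 10.16, tolerance = 1e-6)
  ## one 0.3 ms nACh pulse from rest: analytic solution of the linear ODE
  ## (fine step so the Euler iterate is compared against the exact value)
  a <- p$syn$nach$alpha; b <- p$syn$nach$beta
  O <- 0
  dt_f <- 1e-4
  for (i in seq_len(round(0.3 / dt_f))) O <- channel_step(O, 0.5, a, b, dt_f)
  closed <- (a * 0.5) / (a * 0.5 + b) * (1 - exp(-(a * 0.5 + b) * 0.3))
  expect_lt(abs(O - closed), 1e-4)
  expect_error(channel_step(0, 0, 10, 0.2, dt = 0), "positive")
})

test_that("slow cascade kinetics match closed forms and accumulate", {
  p <- al_params()
  dt <- 0.01
  ## T = 0, R = 0: G decays at rate r4
  G <- 1
  for (i in 1:10000) G <- slow_step(0, G, 0, dt, p)$G
  expect_equal(G, exp(-p$syn$slow$r4 * 100), tolerance = 1e-3)
  ## sustained 20 Hz pulsing: G approaches a plateau, envelope saturating
  run_pulses <- function(n_ms) {
    R <- 0; G <- 0
    gmax <- 0
    traj <- numeric(0)
    for (s in seq_len(round(n_ms / dt))) {
      t <- s * dt
      T_fac <- if ((t %% 50) <= 0.3) 0.5 else 0
      st <- slow_step(R, G, T_fac, dt, p)
      R <- st$R; G <- st$G
      if (s %% 5000 == 0) traj <- c(traj, G)   # sample every 50 ms
    }
    traj
  }
  traj <- run_pulses(3000)
  expect_gt(traj[length(traj)], 0.5)
  ## saturating envelope: increments shrink; the sampled trajectory may
  ## overshoot its plateau by a fraction of a percent before settling
  inc <- diff(traj)
  expect_true(all(inc > -0.005 * max(traj)))
  expect_lt(inc[length(inc)], inc[1])
  ## single pulse peak < peak after three pulses
  peak_after <- function(n_pulses) {
    R <- 0; G <- 0; peak <- 0
    for (s in seq_len(round(200 / dt))) {
      t <- s * dt
      T_fac <- if (t < n_pulses * 50 && (t %% 50) <= 0.3) 0.5 else 0
      st <- slow_step(R, G, T_fac, dt, p)
      R <- st$R; G <- st$G
      peak <- max(peak, G)
    }
    peak
  }
  expect_lt(peak_after(1), peak_after(3))
})

test_that("slow current has the quartic Hill form", {
  expect_equal(slow_current(0, -60), 0)
  expect_equal(slow_activation(100^(1/4)), 0.5)
  expect_equal(slow_current(5, -95), 0)           # reversal
  expect_gt(slow_current(5, -60), 0)              # outward above E_K
  expect_true(all(slow_activation(c(0, 1, 5, 50)) >= 0))
  expect_true(all(slow_activation(c(0, 1, 5, 50)) < 1))
})

test_that("slow inhibition activates much more slowly than fast GABA", {
  p <- al_params()
  dt <- 0.01
  ## fast GABA under sustained 20 Hz presynaptic calcium spiking: time for
  ## O to reach 90% of its own plateau (per-afferent, 25 ms spikes => T
  ## high ~ half the cycle)
  O <- 0; O_traj <- numeric(0)
  R <- 0; G <- 0; t_half_slow <- NA; t_90_fast <- NA
  n_aff <- 4
  plateau <- 10 / (10 + p$syn$gaba$beta) # upper bound on O
  for (s in seq_len(round(3000 / dt))) {
    t <- s * dt
    spiking <- (t %% 50) <= 25   # calcium spike depolarised phase
    T_gaba <- if (spiking) 0.9 else 0
    T_slow <- if ((t %% 50) <= 0.3) 0.5 else 0
    O <- channel_step(O, T_gaba, p$syn$gaba$alpha, p$syn$gaba$beta, dt)
    st <- slow_step(R, G, T_slow, dt, p)
    R <- st$R; G <- st$G
    if (is.na(t_90_fast) && O >= 0.9 * plateau) t_90_fast <- t
    if (is.na(t_half_slow) && slow_activation(n_aff * G, p) >= 0.5) {
      t_half_slow <- t
    }
  }
  expect_false(is.na(t_90_fast))
  expect_false(is.na(t_half_slow))
  expect_gt(t_half_slow, t_90_fast)
})

test_that("slow conductance needs a few presynaptic calcium spikes", {
  n <- slow_half_activation_spikes()
  expect_gte(n, 2)
  expect_lte(n, 6)
})
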