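test_that("gate steady states match their defining formulas", {
  expect_equal(gate_steady_state("Ca", "m", V = -20), 0.5)
  expect_equal(gate_steady_state("CaK", "m", Ca = 2), 0.5)
  expect_equal(gate_steady_state("A", "h", V = -78), 0.5)
  ## voltage-gated activation gates are monotone in V
  V <- seq(-120, 60, by = 0.5)
  for (cur in c("Na", "Ca", "A")) {
    expect_true(all(diff(gate_steady_state(cur, "m", V)) > 0), info = cur)
  }
  expect_true(all(diff(gate_steady_state("K", "m", V, cell = "PN")) > 0))
  expect_true(all(diff(gate_steady_state("K", "m", V, cell = "LN")) > 0))
  ## all gate values stay in [0, 1] over the physiological range
  for (cur in c("Na", "A", "Ca")) {
    for (g in c("m", "h")) {
      x <- gate_steady_state(cur, g, V)
      expect_true(all(x >= 0 & x <= 1), info = paste(cur, g))
    }
  }
  expect_error(gate_steady_state("Nope", "m", V = -50), "unknown")
  expect_error(gate_steady_state("K", "m", V = -50), "both cell types")
})

test_that("gate time constants are positive and honor printed breakpoints", {
  expect_equal(gate_time_constant("A", "h", V = -60), 5.1)
  expect_equal(gate_time_constant("A", "h", V = -30), 5.1)
  expect_equal(gate_time_constant("CaK", "m", Ca = 2), 25)
  expect_equal(gate_time_constant("Ca", "m", V = -30), 1.0)
  V <- seq(-120, 60, by = 0.5)
  combos <- list(c("Na", "m"), c("Na", "h"), c("A", "m"), c("A", "h"),
                 c("Ca", "m"), c("Ca", "h"))
  for (cm in combos) {
    tau <- gate_time_constant(cm[1], cm[2], V)
    expect_true(all(tau > 0), info = paste(cm, collapse = "/"))
  }
  expect_true(all(gate_time_constant("K", "m", V, cell = "PN") > 0))
  expect_true(all(gate_time_constant("K", "m", V, cell = "LN") > 0))
})

test_that("membrane rhs has the stated equilibria", {
  p <- al_params()
  ## leak-only: with all conductances zero, dV/dt = 0 exactly at E_L
  p0 <- al_params(pn = list(g_Na = 0, g_K = 0, g_A = 0))
  d <- membrane_rhs(neuron_state("PN", p0), "PN", params = p0)
  expect_identical(d$V, 0)
  ## LN calcium equilibrium: Ca at rest concentration and I_Ca ~ 0
  pl <- al_params(ln = list(g_Ca = 0))
  dl <- membrane_rhs(neuron_state("LN", pl), "LN", params = pl)
  expect_equal(dl$Ca, 0)
  ## gates at steady state => gate derivatives vanish
  d_full <- membrane_rhs(neuron_state("PN", p), "PN", params = p)
  for (nm in setdiff(names(d_full), "V")) {
    expect_equal(d_full[[nm]], 0, tolerance = 1e-12, info = nm)
  }
  expect_error(membrane_rhs(list(V = NaN), "PN"), "non-finite")
})

test_that("time-stepped resting potential matches an independent root-finder", {
  for (cell in c("PN", "LN")) {
    v_root <- resting_potential(cell)
    tr <- simulate_neuron(cell, duration = 800, I_step = 0, record_v = TRUE,
                          v_decim = 10)
    expect_lt(abs(tr$V[length(tr$V)] - v_root), 0.1)
  }
})

test_that("production stepper matches the naive R reference stepper", {
  r <- simulate_neuron_r("PN", duration = 50, I_stim = 2)
  cpp <- simulate_neuron("PN", duration = 50, I_step = 2, v_decim = 1)
  expect_lt(max(abs(r$V - cpp$V)), 1e-9)
  r2 <- simulate_neuron_r("LN", duration = 50, I_stim = 3.3)
  cpp2 <- simulate_neuron("LN", duration = 50, I_step = 3.3, v_decim = 1)
  expect_lt(max(abs(r2$V - cpp2$V)), 1e-9)
})

test_that("PN fires brief repetitive sodium spikes under step current", {
  r <- simulate_neuron("PN", duration = 2000, I_step = 2,
                       step_window = c(500, 2000))
  expect_gt(length(r$spikes), 10)
  expect_true(all(diff(r$spikes) >= 2))   # refractory floor
  w <- spike_width(r$t, r$V, -40)
  expect_gt(w, 2); expect_lt(w, 4)
})

test_that("LN fires broad adapting calcium spikes under step current", {
  r <- simulate_neuron("LN", duration = 3000, I_step = 3.3,
                       step_window = c(500, 3000))
  expect_gt(length(r$spikes), 5)
  w <- spike_width(r$t, r$V, -30)
  expect_gt(w, 15); expect_lt(w, 35)
  isi <- diff(r$spikes)
  ## spike-rate adaptation: instantaneous frequency declines
  expect_gt(1 / isi[1], 1 / isi[5])
})

test_that("Euler trajectories keep every gate in [0, 1] over long runs", {
  ## 10 s single-cell runs at dt = 0.01 with strong drive; the engine
  ## integrates gates without clamping, so recover gate trajectories in R
  for (cell in c("PN", "LN")) {
    tr <- simulate_neuron_r(cell, duration = 300,
                            I_stim = if (cell == "PN") 3 else 4)
    expect_true(all(is.finite(tr$V)))
  }
  s <- neuron_state("PN")
  ok <- TRUE
  for (i in 1:30000) {   # 300 ms at dt 0.01
    d <- membrane_rhs(s, "PN", I_stim = 3)
    for (nm in names(s)) s[[nm]] <- s[[nm]] + 0.01 * d[[nm]]
    gs <- unlist(s[c("m_Na", "h_Na", "m_K", "m_A", "h_A")])
    if (any(gs < 0 | gs > 1)) { ok <- FALSE; break }
  }
  expect_true(ok)
  s <- neuron_state("LN")
  ok <- TRUE
  for (i in 1:30000) {
    d <- membrane_rhs(s, "LN", I_stim = 4)
    for (nm in names(s)) s[[nm]] <- s[[nm]] + 0.01 * d[[nm]]
    gs <- unlist(s[c("m_Ca", "h_Ca", "m_CaK", "m_K")])
    if (any(gs < 0 | gs > 1) || s$Ca <= 0) { ok <- FALSE; break }
  }
  expect_true(ok)
})
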