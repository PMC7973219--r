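# Single-neuron AdEx dynamics.

test_that("a neuron at rest with no drive stays near equilibrium", {
  p <- adex_params()
  s <- adex_state(V_m = p$E_L, w_adapt = 0)
  r <- adex_step(s, p, dt = 0.1)
  # the only residual drift is the (negligible) exponential term
  bound <- p$g_L * p$Delta_T * exp((p$E_L - p$V_th) / p$Delta_T) / p$C * 0.1
  expect_false(r$spiked)
  expect_lt(abs(r$state$V_m - p$E_L), bound + 1e-12)
})

test_that("a supra-cutoff state resets to V_reset and increments w_adapt by b", {
  p <- adex_params(V_reset = -46, b = 100)
  r <- adex_step(adex_state(V_m = 5, w_adapt = 50), p, dt = 0.1)
  expect_true(r$spiked)
  expect_identical(r$state$V_m, -46)
  expect_identical(r$state$w_adapt, 150)
})

test_that("sub-rheobase constant drive produces no spikes over one second", {
  # rheobase of the default parameter set located beforehand by bisection
  # with a fine-step integrator (dt = 0.05 ms, verified at dt = 0.01 ms)
  rheobase <- 59.2
  p <- adex_params()
  r <- adex_run(adex_state(V_m = p$E_L), p, dt = 0.1, duration = 1000,
                I_ext = 0.9 * rheobase)
  expect_length(r$spike_times, 0)
  r2 <- adex_run(adex_state(V_m = p$E_L), p, dt = 0.1, duration = 1000,
                 I_ext = 1.1 * rheobase)
  expect_gt(length(r2$spike_times), 0)
})

test_that("reset above threshold yields multi-spike bursts under drive", {
  p <- adex_params()  # V_reset (-46) > V_th (-51)
  expect_gt(p$V_reset, p$V_th)
  r <- adex_run(adex_state(V_m = p$E_L), p, dt = 0.1, duration = 2000,
                I_ext = 140)
  isi <- diff(r$spike_times)
  expect_gte(length(r$spike_times), 2)
  expect_true(any(isi < 20))
})

test_that("w_adapt gains exactly b per spike and decays per its ODE between spikes", {
  p <- adex_params()
  r <- adex_run(adex_state(V_m = p$E_L), p, dt = 0.1, duration = 1000,
                I_ext = 140)
  expect_gt(length(r$spike_times), 3)
  # between the last spike of a burst and the next burst there are no
  # resets: compare against a fine-step oracle of the adaptation ODE
  # started from the recorded state
  k0 <- round(r$spike_times[3] / 0.1) + 5  # a few steps after a spike
  span <- 200  # 20 ms inside the quiescent phase
  v_traj <- r$V_m[k0:(k0 + span)]
  w0 <- r$w_adapt[k0]
  w_oracle <- w0
  for (i in seq_len(span)) {
    # sub-steps with the recorded (coarse) voltage: the w equation is
    # linear, so refining dt in w alone isolates its own update rule
    w_oracle <- w_oracle + 0.1 / p$tau_w * (p$a * (v_traj[i] - p$E_L) - w_oracle)
  }
  expect_equal(r$w_adapt[k0 + span], w_oracle, tolerance = 1e-6)
  # spike increments: w_adapt rises by b across each reset
  ks <- round(r$spike_times / 0.1) + 1
  jumps <- r$w_adapt[ks] - r$w_adapt[pmax(ks - 1, 1)]
  expect_true(all(jumps[-1] > 0.9 * p$b))
})

test_that("voltage characteristic targets modify the effective dynamics", {
  p <- adex_params()
  # V_cm targeted at V_m is added after the integration step
  r0 <- adex_step(adex_state(V_m = -55), p, dt = 0.1)
  r1 <- adex_step(adex_state(V_m = -55), p, dt = 0.1,
                  V_cm_target = "V_m", V_cm = 2.5)
  expect_equal(r1$state$V_m - r0$state$V_m, 2.5, tolerance = 1e-12)
  # V_cm targeted at V_reset shifts the post-spike potential downward
  r2 <- adex_step(adex_state(V_m = 5), p, dt = 0.1,
                  V_cm_target = "V_reset", V_cm = 5)
  expect_identical(r2$state$V_m, p$V_reset - 5)
})

test_that("non-finite input is rejected as an integration blow-up", {
  p <- adex_params()
  expect_error(adex_step(adex_state(V_m = -58), p, dt = 0.1, I_ext = Inf),
               "blow-up")
})
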