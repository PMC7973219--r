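# Clock-driven network engine.

test_that("identical spec and seed give bit-identical spike trains", {
  spec <- build_experiment(1, 0, seed = 11)
  a <- simulate_network(spec, seed = 11)
  b <- simulate_network(spec, seed = 11)
  expect_identical(a$spikes$time, b$spikes$time)
  expect_identical(a$spikes$neuron, b$spikes$neuron)
  expect_identical(a$nsi_v, b$nsi_v)
  c <- simulate_network(spec, seed = 12)
  expect_false(identical(a$spikes$time, c$spikes$time))
})

test_that("spike trains respect their container invariants and round-trip to disk", {
  spec <- build_experiment(1, 0, seed = 3)
  sim <- simulate_network(spec, seed = 3)
  st <- sim$spikes
  expect_s3_class(st, "spike_train")
  expect_true(all(st$time >= 0 & st$time <= attr(st, "duration")))
  for (pop in unique(st$population)) {
    for (n in unique(st$neuron[st$population == pop])) {
      expect_false(is.unsorted(st$time[st$population == pop & st$neuron == n]))
    }
  }
  dir <- withr::local_tempdir()
  write_spike_train(st, dir, prefix = "run")
  back <- read_spike_train(file.path(dir, "run_mnp.txt"), population = "mnp")
  orig <- st[st$population == "mnp", ]
  expect_equal(back$time, orig$time)
  expect_equal(back$neuron, orig$neuron)
})

test_that("the network integrator reproduces the single-neuron stepper", {
  # a drive-only motor neuron with zero noise and zero synaptic weights
  # follows exactly the same trajectory as the R-level AdEx stepper
  p <- adex_params(C = 80, V_floor = -120)
  cfg <- network_config(n_per_pop = 1, adex = p, adex_mnp = p,
                        bias_e = 0, bias_i = 0, bias_m = 160,
                        w_ie = 0, w_ei = 0, w_em = 0, w_im = 0)
  spec <- build_experiment(7, 0, duration = 500, seed = 1)
  sim <- simulate_network(spec, config = cfg, noise = noise_config(0, 0),
                          seed = 1, record_traces = TRUE,
                          schedule = input_schedule("constant", I_max = 0))
  r <- adex_run(adex_state(V_m = cfg$init_v_m), p, dt = 0.1, duration = 500,
                I_ext = 160)
  got <- sim$traces[2:500, 3 * cfg$n_per_pop]  # motor neuron column
  expect_equal(got, r$V_m[seq(10, 4990, by = 10)], tolerance = 1e-10)
  # spike times agree on the recording grid
  mnp <- population_spikes(sim$spikes, "mnp")
  expect_equal(mnp, floor(r$spike_times))
})

test_that("the NSI trace relaxes toward the scheduled drive", {
  spec <- build_experiment(1, 0, duration = 1000, seed = 2)
  sim <- simulate_network(spec, noise = noise_config(0, 0), seed = 2,
                          schedule = input_schedule("constant", I_max = 148))
  expect_equal(sim$nsi_v[1], -60)
  expect_equal(sim$nsi_v[1000], -45, tolerance = 0.05)
  # the voltage characteristic offset follows the displacement / 3
  expect_equal(sim$vcm[1000], 5, tolerance = 0.02)
})

test_that("a too-low guard threshold trips the sub-threshold contract", {
  cfg <- network_config(nsi = nsi_params(guard_threshold = -55))
  spec <- build_experiment(1, 0, duration = 1000, seed = 1)
  expect_error(simulate_network(spec, config = cfg, seed = 1,
                                schedule = input_schedule("constant",
                                                          I_max = 148)),
               "contract")
})

test_that("the feedback loop regulates the conductance sign around the set point", {
  cfg <- feedback_config(desired_spike_number = 10)
  sim <- run_feedback_loop(cfg, seed = 4, duration = 3000)
  expect_false(is.null(sim$fb_weight))
  w <- sim$fb_weight[1000:3000]
  # both corrective directions occur
  expect_gt(sum(w > 0), 0)
  expect_gt(sum(w < 0), 0)
  # inhibitory corrections use the larger scaling factor
  expect_gt(max(abs(w[w < 0])), max(w[w > 0]))
})
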