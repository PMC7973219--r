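# NSI -> post-synaptic communication rules.

test_that("voltage characteristic offset follows |displacement|/3 with polarity sign", {
  expect_equal(voltage_characteristic_offset(-60, -45, "excitatory"), 5)
  expect_equal(voltage_characteristic_offset(-60, -60, "excitatory"), 0)
  expect_equal(voltage_characteristic_offset(-60, -60, "inhibitory"), 0)
  expect_equal(voltage_characteristic_offset(-60, -52.5, "inhibitory"), -2.5)
})

test_that("displacements beyond the biological range are clamped or rejected", {
  expect_warning(v <- voltage_characteristic_offset(-60, -40, "excitatory"),
                 "clamped")
  expect_equal(v, 5)
  expect_error(voltage_characteristic_offset(-60, -40, "excitatory",
                                             strict = TRUE), "range")
  # magnitude never exceeds 5 mV when the precondition holds
  for (vm in seq(-75, -45, by = 0.5)) {
    expect_lte(abs(voltage_characteristic_offset(-60, vm, "excitatory")), 5)
  }
})

test_that("injection current reproduces the full conductance table", {
  w <- c(2, 10, 20, 30, 40, 50, 60, 70)
  expected <- c(30, 150, 300, 450, 600, 750, 900, 1050)
  got <- vapply(w, injection_current, numeric(1),
                V_rest = -60, V_m = -45, polarity = "excitatory")
  expect_identical(got, expected)
  got_i <- vapply(w, injection_current, numeric(1),
                  V_rest = -60, V_m = -45, polarity = "inhibitory")
  expect_identical(got_i, -expected)
})

test_that("injection current is bilinear and zero at zero displacement", {
  expect_equal(injection_current(35, -60, -45, "excitatory"), 525)
  expect_equal(injection_current(70, -60, -52.5, "excitatory"), 525)
  expect_equal(injection_current(70, -60, -60, "excitatory"), 0)
  expect_equal(injection_current(70, -60, -60, "inhibitory"), 0)
  for (w in c(1, 7, 33)) for (d in c(1, 4, 12)) {
    expect_equal(injection_current(2 * w, -60, -60 - d, "excitatory"),
                 2 * injection_current(w, -60, -60 - d, "excitatory"))
    expect_equal(injection_current(w, -60, -60 - 2 * d, "excitatory"),
                 2 * injection_current(w, -60, -60 - d, "excitatory"))
  }
})

test_that("only the targeted voltage characteristic is offset", {
  m <- voltage_manipulation("V_th", "excitatory")
  expect_equal(m$V_th_initial, -56)
  expect_equal(m$V_reset_initial, -41)
  eff <- effective_voltage_characteristic(m, 5)
  expect_equal(eff$V_th_eff, -51)
  expect_equal(eff$V_reset_eff, -46)  # untargeted: default

  m2 <- voltage_manipulation("V_reset", "excitatory")
  eff2 <- effective_voltage_characteristic(m2, 0)
  expect_equal(eff2$V_reset_eff, -41)  # initial value unchanged
  expect_equal(eff2$V_th_eff, -51)

  m3 <- voltage_manipulation("V_th", "inhibitory")
  eff3 <- effective_voltage_characteristic(m3, -5)
  expect_equal(eff3$V_th_eff, -56)
})

test_that("full excitatory drive always converges to the default configuration", {
  # the targeted characteristic moves from its polarity-specific initial
  # value to -51/-46 (the 5 mV gap) at V_cm = +5
  for (target in c("V_th", "V_reset")) {
    m <- voltage_manipulation(target, "excitatory")
    eff <- effective_voltage_characteristic(m, 5)
    expect_equal(eff$V_th_eff, -51)
    expect_equal(eff$V_reset_eff, -46)
  }
})

test_that("feedback weight is proportional to the error with polarity by sign", {
  cfg <- feedback_config(desired_spike_number = 10)
  expect_equal(feedback_weight(cfg, 10)$w_syn, 0)
  r <- feedback_weight(feedback_config(scaling_factor_inhibitory = 50,
                                       desired_spike_number = 10), 60)
  expect_equal(r$w_syn, 2500)
  expect_equal(r$polarity, "inhibitory")
  r2 <- feedback_weight(feedback_config(scaling_factor_excitatory = 2,
                                        desired_spike_number = 50), 30)
  expect_equal(r2$w_syn, 40)
  expect_equal(r2$polarity, "excitatory")
})

test_that("feedback weight switches polarity exactly at the set point and is piecewise linear", {
  cfg <- feedback_config(desired_spike_number = 20)
  below <- feedback_weight(cfg, 19)
  above <- feedback_weight(cfg, 21)
  expect_equal(below$polarity, "excitatory")
  expect_equal(above$polarity, "inhibitory")
  # continuity at the switch: magnitude tends to zero from both sides
  expect_equal(below$w_syn, cfg$scaling_factor_excitatory)
  expect_equal(above$w_syn, cfg$scaling_factor_inhibitory)
  # linearity in the error on each side
  for (k in 1:5) {
    expect_equal(feedback_weight(cfg, 20 - k)$w_syn,
                 k * cfg$scaling_factor_excitatory)
    expect_equal(feedback_weight(cfg, 20 + k)$w_syn,
                 k * cfg$scaling_factor_inhibitory)
  }
  # optional cap clamps the magnitude
  capped <- feedback_config(desired_spike_number = 10, weight_cap = 70)
  expect_equal(feedback_weight(capped, 60)$w_syn, 70)
})

test_that("excitatory and inhibitory outputs are exact negations", {
  for (vm in c(-45, -50, -55)) {
    expect_equal(voltage_characteristic_offset(-60, vm, "excitatory"),
                 -voltage_characteristic_offset(-60, vm, "inhibitory"))
    expect_equal(injection_current(40, -60, vm, "excitatory"),
                 -injection_current(40, -60, vm, "inhibitory"))
  }
})
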