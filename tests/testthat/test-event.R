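# Event-driven NSI and the asynchronous reconstruction contract.

test_that("event updates decay then add the scaled input increment", {
  s <- event_nsi_state(V_m = -50, t_updated = 100)
  # zero elapsed time, zero input: unchanged
  s0 <- event_update(s, 100, 0)
  expect_equal(s0$V_m, -50)
  # long gap with no input: relaxation to rest
  far <- event_update(s, 1e5, 0)
  expect_equal(far$V_m, s$V_rest, tolerance = 1e-9)
  # increment scales with 1/C
  s1 <- event_update(s, 100, 200)
  expect_equal(s1$V_m, -50 + 200 / s$C)
  expect_error(event_update(s, 99), "out-of-order")
})

test_that("reconstruction is exact, pure, and a semigroup", {
  s <- event_nsi_state(V_m = -48, t_updated = 10)
  expect_equal(reconstruct_vm(s, 10), -48)
  rest <- event_nsi_state(V_m = -60, t_updated = 0)
  expect_equal(reconstruct_vm(rest, 321.5), -60)
  expect_error(reconstruct_vm(s, 9), "t_updated")
  # two-step reconstruction equals one-step (semigroup property)
  set.seed(42)
  for (rep in 1:20) {
    t1 <- 10 + runif(1, 0, 50)
    t2 <- t1 + runif(1, 0, 50)
    v1 <- reconstruct_vm(s, t1)
    mid <- event_nsi_state(V_m = v1, V_rest = s$V_rest, decay = s$decay,
                           C = s$C, t_updated = t1)
    expect_equal(reconstruct_vm(mid, t2), reconstruct_vm(s, t2),
                 tolerance = 1e-12)
  }
})

test_that("an event train matches the closed-form hybrid trajectory", {
  set.seed(8)
  ev <- sort(runif(30, 0, 150))
  I <- runif(30, 50, 200)
  s <- event_nsi_state()
  for (i in seq_along(ev)) s <- event_update(s, ev[i], I[i])
  tq <- 180
  expect_equal(reconstruct_vm(s, tq),
               naive_event_nsi(ev, I, tq),
               tolerance = 1e-6)
})

test_that("processing sorted events is invariant to their origin order", {
  set.seed(9)
  ev <- sort(runif(20, 0, 100))
  I <- runif(20, 0, 150)
  run <- function(ord) {
    s <- event_nsi_state()
    o <- order(ev[ord])
    for (i in o) s <- event_update(s, ev[ord][i], I[ord][i])
    s$V_m
  }
  base <- run(seq_along(ev))
  expect_equal(run(sample(seq_along(ev))), base, tolerance = 1e-12)
})

test_that("the V_th mapping is affine and clamped", {
  m <- vth_mapping(-60, -45, -56, -51)
  expect_equal(map_vm_to_vth(m, -60), -56)
  expect_equal(map_vm_to_vth(m, -52.5), -53.5)  # midpoint
  expect_equal(map_vm_to_vth(m, -45), -51)
  expect_equal(map_vm_to_vth(m, -20), -51)      # clamp high
  expect_equal(map_vm_to_vth(m, -80), -56)      # clamp low
})

test_that("the event-driven CPG demo shows V_th tracking and antiphase bursting", {
  sig <- make_step_signal(c(0.2, 1), 3000)
  enc <- bsa_encode(sig)
  demo <- run_event_demo(enc)
  # with no synapse noise both V_th traces are identical
  expect_identical(demo$vth_left, demo$vth_right)
  # V_th follows the NSI membrane potential through the mapping
  expect_equal(demo$vth_left,
               map_vm_to_vth(demo$mapping, demo$nsi_v))
  # the input step raises the NSI potential and the threshold
  expect_gt(mean(demo$nsi_v[5000:5999]), mean(demo$nsi_v[500:1500]) + 5)
  expect_gt(mean(demo$vth_left[5000:5999]), mean(demo$vth_left[500:1500]))
  # higher input rate -> higher burst frequency
  bursts_per_s <- function(sp, a, b) {
    st <- sp[sp >= a & sp < b]
    sum(diff(st) > 40) / ((b - a) / 1000)
  }
  expect_gt(bursts_per_s(demo$left, 4000, 6000),
            bursts_per_s(demo$left, 0, 2000))
  # antiphase bursting in the steady final segment
  bl <- demo$left[c(TRUE, diff(demo$left) > 40)]
  br <- demo$right[c(TRUE, diff(demo$right) > 40)]
  bl <- bl[bl >= 4000]
  br <- br[br >= 4000]
  per <- mean(diff(bl))
  off <- vapply(br, function(x) {
    d <- bl[which.min(abs(bl - x))] - x
    d - per * round(d / per)
  }, numeric(1))
  ang <- atan2(mean(sin(2 * pi * off / per)),
               mean(cos(2 * pi * off / per))) * 180 / pi
  expect_lt(abs(((ang + 360) %% 360) - 180), 30)
})

test_that("zero input leaves the threshold at its lower clamp", {
  empty <- spike_train(data.frame(time = numeric(0), neuron = integer(0)),
                       duration = 500)
  demo <- run_event_demo(empty, duration = 500)
  expect_true(all(demo$vth_left == demo$mapping$V_th_low))
})
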