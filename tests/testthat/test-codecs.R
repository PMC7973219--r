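# Rate coding, step signals, and Ben's Spiker Algorithm.

test_that("rate coding counts spikes in half-open sliding windows", {
  st <- spike_train(data.frame(time = c(1, 2, 3, 9), neuron = 1),
                    duration = 20)
  rs <- rate_code(st, window = 5, stride = 1)
  expect_equal(rs$values[1], 3)   # [0, 5) holds 1, 2, 3
  expect_equal(rs$values[6], 1)   # [5, 10) holds 9
  expect_equal(length(rs$values), floor((20 - 5) / 1) + 1)
  # empty population yields all zeros, not an error
  empty <- rate_code(numeric(0), duration = 20)
  expect_true(all(empty$values == 0))
})

test_that("rate coding agrees with brute-force interval counts", {
  set.seed(7)
  for (rep in 1:5) {
    times <- sort(runif(80, 0, 200))
    rs <- rate_code(times, window = 5, stride = 1, duration = 200)
    expect_equal(rs$values, naive_rate_code(times, 200))
  }
  # non-divisible window/stride falls back to the same counts
  times <- sort(runif(40, 0, 100))
  rs <- rate_code(times, window = 7, stride = 2, duration = 100)
  starts <- seq(0, 100 - 7, by = 2)
  expect_equal(rs$values,
               vapply(starts, naive_window_count, numeric(1),
                      times = times, window = 7))
})

test_that("each spike contributes to exactly window/stride windows", {
  rs <- rate_code(50, window = 5, stride = 1, duration = 100)
  expect_equal(sum(rs$values), 5)
  # additivity over disjoint spike sets
  a <- sort(runif(30, 0, 90))
  b <- sort(runif(20, 0, 90))
  ra <- rate_code(a, duration = 100)$values
  rb <- rate_code(b, duration = 100)$values
  rab <- rate_code(sort(c(a, b)), duration = 100)$values
  expect_equal(rab, ra + rb)
})

test_that("total spikes are conserved over non-overlapping windows", {
  set.seed(11)
  times <- sort(runif(60, 0, 99))
  rs <- rate_code(times, window = 5, stride = 5, duration = 100)
  expect_equal(sum(rs$values), sum(times < 100))
})

test_that("step signals are piecewise constant and conserve their integral", {
  s <- make_step_signal(7, 100)
  expect_true(all(s$value == 7))
  s2 <- make_step_signal(c(0, 148), 1000)
  expect_equal(unique(s2$value), c(0, 148))
  expect_equal(sum(s2$value), 0 * 1000 + 148 * 1000)
  expect_equal(nrow(s2), 2000)
})

test_that("BSA emits nothing for a silent signal and matches the naive reference", {
  z <- make_step_signal(0, 200)
  expect_equal(nrow(bsa_encode(z)), 0)
  set.seed(3)
  h <- bsa_filter(20)
  for (rep in 1:3) {
    v <- pmax(0, cumsum(rnorm(300, 0, 0.08)))
    sig <- analog_signal((seq_along(v) - 1), v)
    got <- bsa_encode(sig, h, threshold = 0.95)
    ref <- naive_bsa(v, h, 0.95)
    expect_equal(got$time, (ref - 1))
  }
})

test_that("BSA spike count rises monotonically with signal amplitude", {
  counts <- vapply(c(0.3, 0.6, 1.0), function(a) {
    nrow(bsa_encode(make_step_signal(a, 1000)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("filtering the spike train reconstructs a step input", {
  sig <- make_step_signal(c(0.2, 1), 1000)
  h <- bsa_filter(20)
  sp <- bsa_encode(sig, h)
  rec <- bsa_reconstruct(sp, h, sig$time)
  # skip the filter-length edges
  keep <- seq(30, nrow(sig) - 30)
  nrmse <- sqrt(mean((rec$value[keep] - sig$value[keep])^2)) /
    diff(range(sig$value))
  expect_lt(nrmse, 0.2)
})

test_that("a filter longer than the signal is rejected", {
  expect_error(bsa_encode(make_step_signal(1, 10), bsa_filter(20)), "longer")
})
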