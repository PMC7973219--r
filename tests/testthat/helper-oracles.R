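# Independent brute-force oracles used across the test files.

# Naive window count: number of spike times in [t0, t0 + window).
naive_window_count <- function(times, t0, window) {
  sum(times >= t0 & times < t0 + window)
}

# Naive rate coding by direct interval counting.
naive_rate_code <- function(times, duration, window = 5, stride = 1) {
  starts <- seq(0, duration - window, by = stride)
  vapply(starts, naive_window_count, numeric(1), times = times,
         window = window)
}

# Literal, loop-based Ben's Spiker Algorithm, kept deliberately naive.
naive_bsa <- function(values, h, threshold) {
  spikes <- integer(0)
  n <- length(values)
  L <- length(h)
  for (k in seq_len(n - L + 1)) {
    e1 <- 0
    e2 <- 0
    for (j in seq_len(L)) {
      e1 <- e1 + abs(values[k + j - 1] - h[j])
      e2 <- e2 + abs(values[k + j - 1])
    }
    if (e1 <= e2 - threshold) {
      for (j in seq_len(L)) values[k + j - 1] <- values[k + j - 1] - h[j]
      spikes <- c(spikes, k)
    }
  }
  spikes
}

# Build a rate_signal object directly from a value vector (1 ms grid).
synthetic_rate_signal <- function(values, window = 5, stride = 1) {
  structure(list(values = values, times = (seq_along(values) - 1) * stride,
                 window = window, stride = stride),
            class = "rate_signal")
}

# Fine-step Euler oracle for the event-driven NSI hybrid system: pure
# exponential decay toward rest between events, instantaneous increments
# I/C at event times.
naive_event_nsi <- function(event_times, I_events, t_query, V_rest = -60,
                            tau_m = 20, C = 200, dt = 0.001) {
  v <- V_rest
  t <- 0
  ev <- order(event_times)
  event_times <- event_times[ev]
  I_events <- I_events[ev]
  for (i in seq_along(event_times)) {
    n <- round((event_times[i] - t) / dt)
    v <- V_rest + (v - V_rest) * exp(-n * dt / tau_m)
    v <- v + I_events[i] / C
    t <- t + n * dt
  }
  V_rest + (v - V_rest) * exp(-(t_query - t) / tau_m)
}
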