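#' Analog signal container
#'
#' @param times sample times (ms), strictly increasing
#' @param values sample values (arbitrary units)
#' @return An object of class `analog_signal` (data frame `time`, `value`).
#' @export
analog_signal <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times),
            all(diff(times) > 0))
  structure(data.frame(time = times, value = values),
            class = c("analog_signal", "data.frame"))
}

#' Piecewise-constant step signal
#'
#' @param levels sequence of level values
#' @param level_duration duration of each level (ms), > 0
#' @param dt sample spacing (ms)
#' @return An [analog_signal()] sampled on a uniform grid.
#' @examples
#' make_step_signal(c(0, 148), 1000)
#' @export
make_step_signal <- function(levels, level_duration, dt = 1) {
  stopifnot(level_duration > 0, dt > 0)
  per <- round(level_duration / dt)
  values <- rep(levels, each = per)
  analog_signal(times = (seq_along(values) - 1) * dt, values = values)
}

#' Rate-coded decoding of a spike train
#'
#' Counts all spike events of a population inside a sliding time window --
#' the network's spikes-to-analog conversion, mimicking the low-pass
#' filtering performed by a muscle. Window `w` starting at time `t` counts
#' events with `t <= time < t + w` (half-open). The default 5 ms window
#' slides on the 1 ms recording grid.
#'
#' @param spikes a [spike_train()] or a numeric vector of spike times (ms)
#' @param window window length (ms), > 0
#' @param stride window step (ms), > 0; must divide `window`
#' @param duration signal duration (ms); defaults to the spike train's
#' @param population restrict to one population label
#' @return An object of class `rate_signal`: list with integer `values`,
#'   window start `times`, `window` and `stride`.
#' @examples
#' st <- spike_train(data.frame(time = c(1, 2, 3, 9), neuron = 1), duration = 20)
#' rate_code(st)$values[1:6]
#' @export
rate_code <- function(spikes, window = 5, stride = 1, duration = NULL,
                      population = NULL) {
  stopifnot(window > 0, stride > 0)
  if (inherits(spikes, "spike_train")) {
    if (is.null(duration)) duration <- attr(spikes, "duration")
    times <- population_spikes(spikes, population)
  } else {
    times <- sort(spikes)
    if (is.null(duration)) duration <- if (length(times)) max(times) else window
  }
  n_out <- floor((duration - window) / stride) + 1
  if (n_out < 1) stop("duration shorter than one window")
  k <- round(window / stride)
  if (abs(k * stride - window) > 1e-9) {
    # general (non-divisible) case: direct interval counts
    starts <- (seq_len(n_out) - 1) * stride
    values <- vapply(starts, function(t0)
      sum(times >= t0 & times < t0 + window), integer(1))
    return(structure(list(values = values, times = starts,
                          window = window, stride = stride),
                     class = "rate_signal"))
  }
  n_bins <- n_out + k - 1
  bins <- floor(times / stride) + 1
  bins <- bins[bins >= 1 & bins <= n_bins]
  counts <- tabulate(bins, nbins = n_bins)
  values <- as.integer(stats::filter(counts, rep(1, k), sides = 1)[k:n_bins])
  structure(list(values = values, times = (seq_len(n_out) - 1) * stride,
                 window = window, stride = stride),
            class = "rate_signal")
}

#' @export
print.rate_signal <- function(x, ...) {
  cat("<rate_signal> ", length(x$values), " samples, window ", x$window,
      " ms, stride ", x$stride, " ms, max ", max(x$values), "\n", sep = "")
  invisible(x)
}

#' Write a rate signal as CSV
#' @param signal a [rate_code()] result
#' @param path output file
#' @export
write_rate_signal <- function(signal, path) {
  utils::write.csv(data.frame(time_ms = signal$times, count = signal$values),
                   path, row.names = FALSE)
}

#' Normalized Gaussian FIR filter for Ben's Spiker Algorithm
#'
#' @param n number of taps
#' @param sd standard deviation in taps
#' @return Numeric filter coefficients summing to 1.
#' @export
bsa_filter <- function(n = 20, sd = n / 6) {
  h <- stats::dnorm(seq(-(n - 1) / 2, (n - 1) / 2, length.out = n), sd = sd)
  h / sum(h)
}

#' Encode an analog signal into spikes with Ben's Spiker Algorithm
#'
#' Standard BSA: walking forward over the uniformly sampled signal, a spike
#' is emitted at sample `k` -- and the FIR filter subtracted from the signal
#' starting there -- whenever the residual error of subtracting does not
#' exceed the error of not subtracting minus `threshold`. A spike train
#' filtered with the same FIR approximately reconstructs the signal.
#'
#' The filter and threshold are demonstration defaults (the encoding only
#' needs to be monotonically faithful); signals should be normalized to
#' about unit amplitude for the default threshold to be meaningful.
#'
#' @param signal an [analog_signal()] on a uniform grid
#' @param fir_filter non-negative FIR coefficients, shorter than the signal
#' @param threshold emission threshold (same units as the signal)
#' @return A [spike_train()] on the signal's grid (population `"input"`).
#' @examples
#' s <- make_step_signal(c(0, 1), 100)
#' bsa_encode(s)
#' @export
bsa_encode <- function(signal, fir_filter = bsa_filter(), threshold = 0.95) {
  stopifnot(inherits(signal, "analog_signal"), all(fir_filter >= 0))
  v <- signal$value
  L <- length(fir_filter)
  if (L > length(v)) stop("FIR filter (", L, " taps) longer than signal (",
                          length(v), " samples)")
  n <- length(v)
  spike_idx <- integer(0)
  for (k in seq_len(n - L + 1)) {
    seg <- v[k:(k + L - 1)]
    err_sub <- sum(abs(seg - fir_filter))
    err_keep <- sum(abs(seg))
    if (err_sub <= err_keep - threshold) {
      v[k:(k + L - 1)] <- seg - fir_filter
      spike_idx <- c(spike_idx, k)
    }
  }
  spike_train(data.frame(time = signal$time[spike_idx],
                         neuron = rep(1L, length(spike_idx)),
                         population = rep("input", length(spike_idx))),
              duration = max(signal$time))
}

#' Reconstruct an analog signal from a BSA spike train
#'
#' Convolves the spike indicator with the FIR filter -- the decoding side of
#' [bsa_encode()], used to measure round-trip fidelity.
#'
#' @param spikes a [spike_train()] from [bsa_encode()]
#' @param fir_filter the FIR filter used for encoding
#' @param times the signal's sample times (ms)
#' @return An [analog_signal()] of the reconstruction.
#' @export
bsa_reconstruct <- function(spikes, fir_filter, times) {
  dt <- times[2] - times[1]
  ind <- numeric(length(times))
  idx <- round((spikes$time - times[1]) / dt) + 1
  ind[idx[idx >= 1 & idx <= length(ind)]] <- 1
  rec <- numeric(length(times))
  L <- length(fir_filter)
  for (k in which(ind > 0)) {
    j <- k:min(k + L - 1, length(rec))
    rec[j] <- rec[j] + fir_filter[seq_along(j)]
  }
  analog_signal(times, rec)
}
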