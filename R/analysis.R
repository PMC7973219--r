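#' Detect burst peaks in a rate-coded signal
#'
#' Finds local maxima of the rate signal, then resolves clusters of maxima
#' closer than `min_separation`: within such a cluster only the largest
#' peak is kept, and the others are recorded as rejected double peaks (the
#' outliers removed before frequency estimation). For bursty signals that
#' return to zero between bursts the `min_prominence` height threshold
#' equals the peak's prominence.
#'
#' @param signal a [rate_code()] result
#' @param min_separation minimum time between accepted peaks (ms)
#' @param min_prominence minimum peak height (spike counts)
#' @return An object of class `peak_set`: list with data frames `peaks` and
#'   `rejected_double_peaks` (columns `time`, `value`).
#' @export
detect_peaks <- function(signal, min_separation = 50, min_prominence = 2) {
  stopifnot(inherits(signal, "rate_signal"), length(signal$values) > 0)
  v <- signal$values
  t <- signal$times
  # collapse plateaus to runs; a run is a local maximum when it exceeds
  # both neighbouring runs (boundaries count as -Inf); the plateau's
  # first sample carries the peak
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  left <- c(-Inf, r$values[-length(r$values)])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values >= min_prominence & r$values > left & r$values > right
  if (length(r$values) == 1) is_max <- FALSE  # constant signal: no peaks
  cand <- starts[is_max]
  if (!length(cand)) {
    empty <- data.frame(time = numeric(0), value = numeric(0))
    return(structure(list(peaks = empty, rejected_double_peaks = empty),
                     class = "peak_set"))
  }
  keep <- logical(length(cand))
  acc_t <- numeric(0)
  for (i in order(v[cand], t[cand] * 1e-9, decreasing = TRUE)) {
    if (!length(acc_t) || all(abs(t[cand[i]] - acc_t) >= min_separation)) {
      keep[i] <- TRUE
      acc_t <- c(acc_t, t[cand[i]])
    }
  }
  mk <- function(idx) {
    d <- data.frame(time = t[idx], value = v[idx])
    d[order(d$time), , drop = FALSE]
  }
  structure(list(peaks = mk(cand[keep]),
                 rejected_double_peaks = mk(cand[!keep])),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x$peaks), " peaks (",
      nrow(x$rejected_double_peaks), " rejected double peaks)\n", sep = "")
  invisible(x)
}

#' Average peak amplitude
#'
#' Arithmetic mean of the detected peak heights -- the "average maximum
#' number of spikes per time window" output measure. An empty peak set
#' yields `NA` (an undefined measure, deliberately distinct from zero:
#' suppressed-output trials legitimately have no peaks).
#'
#' @param peaks a [detect_peaks()] result
#' @return Mean peak height (spikes per window), or `NA_real_`.
#' @export
average_peak <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!nrow(peaks$peaks)) return(NA_real_)
  mean(peaks$peaks$value)
}

#' Burst frequency from inter-peak intervals
#'
#' One frequency value per successive peak pair, `1000 / gap_ms`, averaged
#' over the gaps inside `segment`. Residual double peaks -- secondary
#' maxima riding on the same burst that survive [detect_peaks()] -- produce
#' implausibly short inter-peak gaps and are removed as outliers: while any
#' gap is shorter than `outlier_frac` times the median gap, the smaller
#' peak of the offending pair is dropped and the gaps recomputed, so each
#' burst contributes one peak. Fewer than two peaks in the segment yield an
#' undefined measure (`NA`).
#'
#' @param peaks a [detect_peaks()] result
#' @param segment optional `c(t0, t1)` (ms) restricting the peaks used
#' @param outlier_frac gaps below this fraction of the median gap mark a
#'   double peak
#' @return An object of class `frequency_estimate`: list with
#'   `per_interval` (Hz), `mean` (Hz) and `gaps` (ms).
#' @examples
#' # peaks every 250 ms -> 4 Hz
#' @export
estimate_frequency <- function(peaks, segment = NULL, outlier_frac = 0.5) {
  stopifnot(inherits(peaks, "peak_set"))
  keep <- if (is.null(segment)) rep(TRUE, nrow(peaks$peaks)) else
    peaks$peaks$time >= segment[1] & peaks$peaks$time <= segment[2]
  t <- peaks$peaks$time[keep]
  v <- peaks$peaks$value[keep]
  if (length(t) < 2) {
    return(structure(list(per_interval = numeric(0), mean = NA_real_,
                          gaps = numeric(0)),
                     class = "frequency_estimate"))
  }
  thr <- outlier_frac * stats::median(diff(t))
  while (length(t) > 2 && any(diff(t) < thr)) {
    i <- which.min(diff(t))            # closest pair
    drop <- if (v[i] <= v[i + 1]) i else i + 1
    t <- t[-drop]
    v <- v[-drop]
  }
  gaps <- diff(t)
  f <- 1000 / gaps
  structure(list(per_interval = f, mean = mean(f), gaps = gaps),
            class = "frequency_estimate")
}

#' Phase shift between two peak sets
#'
#' Circular mean of the nearest-peak time offsets of `b` relative to `a`,
#' expressed in degrees of the supplied period. Identical peak sets give 0
#' degrees; shifting every peak by half a period gives 180 degrees.
#'
#' @param a,b [detect_peaks()] results
#' @param period oscillation period (ms)
#' @return Phase shift in degrees, in `[0, 360)`; `NA` if either set is
#'   empty.
#' @export
phase_shift <- function(a, b, period) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"), period > 0)
  ta <- a$peaks$time
  tb <- b$peaks$time
  if (!length(ta) || !length(tb)) return(NA_real_)
  off <- vapply(ta, function(x) {
    d <- tb[which.min(abs(tb - x))] - x
    d - period * round(d / period)  # wrap into (-period/2, period/2]
  }, numeric(1))
  ang <- 2 * pi * off / period
  deg <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  (deg + 360) %% 360
}

#' Does the rate-coded output return to zero between bursts?
#'
#' Checks, for every pair of successive accepted peaks, whether the signal
#' attains zero somewhere in the gap. Failure ("lifting") marks
#' over-excitation: some neurons never stop spiking between bursts.
#'
#' @param signal a [rate_code()] result
#' @param peaks a [detect_peaks()] result for the same signal
#' @return `TRUE` when every inter-peak gap touches zero; `NA` when there
#'   are fewer than two peaks.
#' @export
returns_to_zero <- function(signal, peaks) {
  stopifnot(inherits(signal, "rate_signal"), inherits(peaks, "peak_set"))
  pt <- peaks$peaks$time
  if (length(pt) < 2) return(NA)
  for (i in seq_len(length(pt) - 1)) {
    gap <- signal$values[signal$times > pt[i] & signal$times < pt[i + 1]]
    if (!length(gap) || min(gap) > 0) return(FALSE)
  }
  TRUE
}

#' Tidy per-run summary of the output measures
#'
#' @param sim an `nsi_sim` from [simulate_network()]
#' @param window,stride rate-coding parameters (ms)
#' @param ... passed to [detect_peaks()]
#' @return A data frame with one row per measure (`experiment`, `seed`,
#'   `measure`, `value`).
#' @export
summarize_run <- function(sim, window = 5, stride = 1, ...) {
  rs <- rate_code(sim$spikes, window = window, stride = stride,
                  population = "mnp")
  pk <- detect_peaks(rs, ...)
  fr <- estimate_frequency(pk)
  data.frame(
    experiment = sim$spec$label, seed = sim$seed,
    measure = c("average_peak", "mean_frequency_hz", "n_peaks",
                "returns_to_zero"),
    value = c(average_peak(pk), fr$mean, nrow(pk$peaks),
              as.numeric(returns_to_zero(rs, pk)))
  )
}
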