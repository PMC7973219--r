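#' Static-input amplitude run
#'
#' One 6 s simulation with constant maximum NSI input and current injection
#' to the MNP only -- the configuration of the conductance sweep used to
#' characterize amplitude control and to determine the maximum usable
#' conductance.
#'
#' @param w_syn NSI output conductance (nS)
#' @param polarity `"excitatory"` or `"inhibitory"`
#' @param seed RNG seed
#' @param config a [network_config()]
#' @param I_input constant NSI input current (pA)
#' @param noise a [noise_config()]
#' @return An `nsi_sim` object.
#' @export
static_amplitude_run <- function(w_syn, polarity = "excitatory", seed = 1,
                                 config = network_config(), I_input = 148,
                                 noise = noise_config()) {
  sub <- if (polarity == "excitatory") 0 else 3
  spec <- build_experiment(1, sub, seed = seed)
  simulate_network(spec, config = config, noise = noise, seed = seed,
                   w_syn = w_syn,
                   schedule = input_schedule("constant", I_max = I_input))
}

#' Conductance sweep of the rate-coded output amplitude
#'
#' Runs [static_amplitude_run()] over a grid of conductances and seeds and
#' summarizes the output measures; the layout mirrors the amplitude
#' characterization table (calculated injection current, conductance,
#' average peak per polarity).
#'
#' @param weights conductance grid (nS)
#' @param seeds seeds to average over
#' @param polarity `"excitatory"` or `"inhibitory"`
#' @param config a [network_config()]
#' @param transient initial time excluded from the measures (ms)
#' @param ... passed to [static_amplitude_run()]
#' @return Data frame with one row per (w, seed): `avg_peak`,
#'   `mean_freq_hz`, `returns_to_zero`, `I_injection`.
#' @export
conductance_sweep <- function(weights = c(2, 10, 20, 30, 40, 50, 60, 70),
                              seeds = 1:10, polarity = "excitatory",
                              config = network_config(), transient = 1000,
                              ...) {
  out <- expand.grid(w = weights, seed = seeds)
  res <- lapply(seq_len(nrow(out)), function(i) {
    sim <- static_amplitude_run(out$w[i], polarity, out$seed[i], config, ...)
    rs <- rate_code(sim$spikes, population = "mnp")
    keep <- rs$times >= transient
    rs$values <- rs$values[keep]
    rs$times <- rs$times[keep]
    pk <- detect_peaks(rs)
    fr <- estimate_frequency(pk)
    data.frame(avg_peak = average_peak(pk), mean_freq_hz = fr$mean,
               returns_to_zero = returns_to_zero(rs, pk))
  })
  cbind(out, do.call(rbind, res),
        I_injection = out$w * 15)  # nS x 15 mV displacement
}

#' Determine the maximum usable synaptic conductance
#'
#' Sweeps the excitatory conductance upward in fixed increments at maximum
#' static NSI input and reports the largest value for which the rate-coded
#' output still returns to zero between bursts in the majority of seeds
#' ("lifting" marks the end of the usable range). The sweep stops at the
#' first failing weight.
#'
#' @param weights increasing conductance grid (nS)
#' @param seeds seeds for the majority vote
#' @param config a [network_config()]
#' @param ... passed to [static_amplitude_run()]
#' @return List with `w_max` (nS), and `detail` (per-weight pass
#'   fractions).
#' @export
find_w_max <- function(weights = seq(10, 120, by = 10), seeds = 1:10,
                       config = network_config(), ...) {
  detail <- data.frame(w = weights, pass_fraction = NA_real_)
  w_max <- NA_real_
  for (i in seq_along(weights)) {
    ok <- vapply(seeds, function(s) {
      sim <- static_amplitude_run(weights[i], "excitatory", s, config, ...)
      rs <- rate_code(sim$spikes, population = "mnp")
      keep <- rs$times >= 1000
      rs$values <- rs$values[keep]; rs$times <- rs$times[keep]
      isTRUE(returns_to_zero(rs, detect_peaks(rs)))
    }, logical(1))
    detail$pass_fraction[i] <- mean(ok)
    if (mean(ok) > 0.5) w_max <- weights[i] else break
  }
  list(w_max = w_max, detail = detail[!is.na(detail$pass_fraction), ])
}

#' Frequency manipulation experiment
#'
#' Runs the voltage-characteristic manipulation test (stepping NSI input,
#' both sCPG populations targeted) and estimates the output frequency
#' during the first and last 1 s input levels.
#'
#' @param target `"V_th"` or `"V_reset"`
#' @param seeds seeds to run
#' @param config a [network_config()]
#' @param subcategory test subcategory (default 0: excitatory, both
#'   populations, input stepping 0 to 148 pA)
#' @param noise a [noise_config()]
#' @return Data frame with `seed`, `f_start` (Hz, during the initial zero
#'   drive level) and `f_end` (Hz, during the final maximum drive level).
#' @export
frequency_experiment <- function(target = c("V_th", "V_reset"), seeds = 1:10,
                                 config = network_config(), subcategory = 0,
                                 noise = noise_config()) {
  target <- match.arg(target)
  test_no <- if (target == "V_th") 7 else 9
  res <- lapply(seeds, function(s) {
    spec <- build_experiment(test_no, subcategory, seed = s)
    sim <- simulate_network(spec, config = config, noise = noise, seed = s)
    pk <- detect_peaks(rate_code(sim$spikes, population = "mnp"))
    data.frame(seed = s,
               f_start = estimate_frequency(pk, c(0, 1000))$mean,
               f_end = estimate_frequency(pk, c(5000, 6000))$mean)
  })
  do.call(rbind, res)
}

#' Toggled- vs constant-frequency phase experiment
#'
#' Two same-seed runs with V_th manipulation only (no MNP injection): one
#' holds the NSI input constant, the other toggles it every second between
#' the levels producing the low and high output frequencies. Because the
#' schedules agree during the first input level and the noise sequence is
#' seed-identical, the two outputs match exactly for the first 1000 ms and
#' diverge once the toggled input departs.
#'
#' @param seed common RNG seed
#' @param config a [network_config()]
#' @param high,low NSI input levels (pA)
#' @param start `"high"` or `"low"`: level of the first second (the
#'   constant run holds this level throughout)
#' @param noise a [noise_config()]
#' @return List with `toggled` and `constant` `nsi_sim` objects.
#' @export
toggling_phase_experiment <- function(seed = 1, config = network_config(),
                                      high = 148, low = 74, start = "high",
                                      noise = noise_config()) {
  a <- if (start == "high") high else low
  b <- if (start == "high") low else high
  spec <- build_experiment(7, 0, seed = seed)
  tog <- simulate_network(spec, config = config, noise = noise, seed = seed,
                          schedule = input_schedule("toggling",
                                                    levels = rep(c(a, b), 3)))
  con <- simulate_network(spec, config = config, noise = noise, seed = seed,
                          schedule = input_schedule("constant", I_max = a))
  list(toggled = tog, constant = con)
}
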