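#' Voltage characteristic manipulation offset
#'
#' Maps the NSI's displacement from rest to the offset applied to a voltage
#' characteristic (V_th, V_reset or V_m) of a post-synaptic spiking neuron:
#' the magnitude is `|V_rest - V_m| / divisor`. The divisor of 3 derives from
#' dividing the biologically plausible 15 mV NSI fluctuation range by the
#' 5 mV manipulation range known to keep the spiking CPG stable, so a fully
#' displaced NSI produces exactly a 5 mV offset.
#'
#' The offset is signed by the test polarity -- positive for excitatory,
#' negative for inhibitory -- mirroring the sign rule of the graded current
#' injection.
#'
#' @param V_rest NSI reference (starting) membrane potential (mV)
#' @param V_m current NSI membrane potential (mV)
#' @param polarity `"excitatory"` or `"inhibitory"`
#' @param divisor manipulation-range divisor (default 3)
#' @param range_max largest displacement considered biologically plausible
#'   (mV); larger displacements are handled per `strict`
#' @param strict if `TRUE`, displacement beyond `range_max` is an error;
#'   otherwise it is clamped with a warning
#' @return Signed offset V_cm in mV.
#' @examples
#' voltage_characteristic_offset(-60, -45, "excitatory")  # +5 mV
#' @export
voltage_characteristic_offset <- function(V_rest, V_m,
                                          polarity = c("excitatory", "inhibitory"),
                                          divisor = 3, range_max = 15,
                                          strict = FALSE) {
  polarity <- match.arg(polarity)
  disp <- abs(V_rest - V_m)
  if (disp > range_max) {
    if (strict) {
      stop("NSI displacement ", round(disp, 3), " mV outside the ",
           range_max, " mV biological fluctuation range")
    }
    warning("NSI displacement ", round(disp, 3),
            " mV clamped to the ", range_max, " mV range")
    disp <- range_max
  }
  sign <- if (polarity == "excitatory") 1 else -1
  sign * disp / divisor
}

#' Graded current injection from the NSI
#'
#' The current injected into a post-synaptic neuron is the synaptic
#' conductance weight times the NSI displacement from rest,
#' `I = w * |V_rest - V_m|` (nS x mV = pA), sent as a positive current for an
#' excitatory connection and negative for an inhibitory one. The result is
#' added to the post-synaptic neuron's bias current.
#'
#' @param w_syn synaptic conductance weight (nS), >= 0
#' @param V_rest NSI reference membrane potential (mV)
#' @param V_m current NSI membrane potential (mV)
#' @param polarity `"excitatory"` or `"inhibitory"`
#' @return Signed injection current in pA.
#' @examples
#' injection_current(70, -60, -45, "excitatory")  # +1050 pA
#' injection_current(10, -60, -45, "excitatory")  # +150 pA
#' @export
injection_current <- function(w_syn, V_rest, V_m,
                              polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  stopifnot(w_syn >= 0, is.finite(V_rest), is.finite(V_m))
  sign <- if (polarity == "excitatory") 1 else -1
  sign * w_syn * abs(V_rest - V_m)
}

#' Voltage manipulation configuration
#'
#' Bundles the target characteristic with the polarity-specific initial
#' values it is offset from. Excitatory tests start from V_th = -56 mV /
#' V_reset = -41 mV; inhibitory tests from V_th = -51 mV / V_reset = -46 mV.
#' In both cases the targeted characteristic sits 5 mV away from the default
#' (-51 / -46 mV) configuration and converges to it at full excitatory drive.
#'
#' @param target one of `"V_th"`, `"V_reset"`, `"V_m"`
#' @param polarity `"excitatory"` or `"inhibitory"`; selects the initial
#'   values unless both are supplied explicitly
#' @param V_th_initial,V_reset_initial override the polarity defaults (mV)
#' @return An object of class `voltage_manipulation`.
#' @export
voltage_manipulation <- function(target = c("V_th", "V_reset", "V_m"),
                                 polarity = c("excitatory", "inhibitory"),
                                 V_th_initial = NULL, V_reset_initial = NULL) {
  target <- match.arg(target)
  polarity <- match.arg(polarity)
  if (is.null(V_th_initial))
    V_th_initial <- if (polarity == "excitatory") -56 else -51
  if (is.null(V_reset_initial))
    V_reset_initial <- if (polarity == "excitatory") -41 else -46
  structure(list(target = target, polarity = polarity,
                 V_th_initial = V_th_initial,
                 V_reset_initial = V_reset_initial),
            class = "voltage_manipulation")
}

#' Effective voltage characteristics under a manipulation
#'
#' Applies a signed offset `V_cm` to the targeted characteristic only. The
#' offset is *added* to `V_th` and *subtracted* from `V_reset`: with the
#' polarity-specific initial values this makes a positive (excitatory)
#' offset always narrow the gap between threshold and reset -- the
#' high-frequency direction -- and a negative (inhibitory) offset widen it.
#' The untargeted characteristic keeps the default value used whenever a
#' characteristic is not under test (V_th = -51 mV, V_reset = -46 mV).
#'
#' @param manip a [voltage_manipulation()]
#' @param V_cm signed offset from [voltage_characteristic_offset()] (mV)
#' @param V_th_default,V_reset_default values used for the untargeted
#'   characteristic (mV)
#' @return A list with `V_th_eff` and `V_reset_eff` (mV).
#' @examples
#' m <- voltage_manipulation("V_th", "excitatory")
#' effective_voltage_characteristic(m, 5)  # V_th -51, V_reset -46
#' @export
effective_voltage_characteristic <- function(manip, V_cm,
                                             V_th_default = -51,
                                             V_reset_default = -46) {
  stopifnot(inherits(manip, "voltage_manipulation"), is.finite(V_cm))
  vth <- V_th_default
  vreset <- V_reset_default
  if (manip$target == "V_th") vth <- manip$V_th_initial + V_cm
  if (manip$target == "V_reset") vreset <- manip$V_reset_initial - V_cm
  list(V_th_eff = vth, V_reset_eff = vreset)
}

#' Feedback regulation configuration
#'
#' Settings for the internal feedback loop that regulates output amplitude:
#' the synaptic conductance from the NSI to the motor population is computed
#' each step as `scaling_factor * (desired - current)` spikes, with an
#' excitatory weight when the output undershoots the set point and an
#' inhibitory weight when it overshoots. The scaling factors found to give
#' maximal effect without over-excitation or over-inhibition are 2
#' (excitatory) and 50 (inhibitory).
#'
#' @param scaling_factor_excitatory dimensionless gain for positive error
#' @param scaling_factor_inhibitory dimensionless gain for negative error
#' @param desired_spike_number set point (spikes per rate window), >= 0
#' @param weight_cap optional clamp on the conductance magnitude (nS);
#'   `NULL` (default) disables the clamp
#' @return An object of class `feedback_config`.
#' @export
feedback_config <- function(scaling_factor_excitatory = 2,
                            scaling_factor_inhibitory = 50,
                            desired_spike_number = 10,
                            weight_cap = NULL) {
  stopifnot(scaling_factor_excitatory > 0, scaling_factor_inhibitory > 0,
            desired_spike_number >= 0)
  structure(list(scaling_factor_excitatory = scaling_factor_excitatory,
                 scaling_factor_inhibitory = scaling_factor_inhibitory,
                 desired_spike_number = desired_spike_number,
                 weight_cap = weight_cap),
            class = "feedback_config")
}

#' Feedback-regulated synaptic conductance
#'
#' @param cfg a [feedback_config()]
#' @param current_spike_number spikes observed in the latest rate window
#' @return A list with `w_syn` (nS, magnitude) and `polarity`
#'   (`"excitatory"` when the output is below the set point, `"inhibitory"`
#'   otherwise).
#' @examples
#' feedback_weight(feedback_config(desired_spike_number = 10), 60)
#' @export
feedback_weight <- function(cfg, current_spike_number) {
  stopifnot(inherits(cfg, "feedback_config"), current_spike_number >= 0)
  err <- cfg$desired_spike_number - current_spike_number
  polarity <- if (err > 0) "excitatory" else "inhibitory"
  sf <- if (err > 0) cfg$scaling_factor_excitatory else cfg$scaling_factor_inhibitory
  w <- abs(err) * sf
  if (!is.null(cfg$weight_cap)) w <- min(w, cfg$weight_cap)
  list(w_syn = w, polarity = polarity)
}
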