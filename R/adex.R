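#' Parameters of an adaptive exponential integrate-and-fire (AdEx) neuron
#'
#' The AdEx model couples a membrane-potential equation with an exponential
#' spike-initiation term to an adaptation current `w_adapt`:
#' \deqn{C \, dV_m/dt = -g_L (V_m - E_L) + g_L \Delta_T
#'       e^{(V_m - V_{th})/\Delta_T} - w_{adapt} + I_e}
#' \deqn{\tau_w \, dw_{adapt}/dt = a (V_m - E_L) - w_{adapt}}
#' A spike is registered whenever `V_m` exceeds 0 mV (the numerical cutoff),
#' upon which `V_m` is set to `V_reset` and `w_adapt` is incremented by `b`.
#' Because detection happens at 0 mV rather than at `V_th`, `V_reset` may lie
#' *above* `V_th`; with the regular-bursting parameter set used here that is
#' precisely what produces multi-spike bursts.
#'
#' Defaults follow the published regular-bursting AdEx set
#' (C = 200 pF, g_L = 10 nS, E_L = -58 mV, Delta_T = 2 mV, a = 2 nS,
#' b = 100 pA, tau_w = 120 ms) with V_th = -51 mV and V_reset = -46 mV.
#'
#' @param C membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L resting potential (mV)
#' @param Delta_T spike sharpness factor (mV)
#' @param V_th threshold potential of the exponential term (mV)
#' @param V_reset post-spike reset potential (mV); may exceed `V_th`
#' @param a sub-threshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_w adaptation time constant (ms)
#' @param I_e constant bias current (pA)
#' @param V_floor lower bound on the membrane potential (mV). Plays the
#'   role of the inhibitory/potassium reversal potential: strong
#'   hyperpolarizing currents saturate there instead of driving the linear
#'   model to arbitrarily negative voltages
#' @return An object of class `adex_params`.
#' @seealso [adex_step()], [nsi_params()]
#' @export
adex_params <- function(C = 200, g_L = 10, E_L = -58, Delta_T = 2,
                        V_th = -51, V_reset = -46,
                        a = 2, b = 100, tau_w = 120, I_e = 0,
                        V_floor = -90) {
  stopifnot(C > 0, g_L > 0, tau_w > 0, Delta_T > 0, V_floor < E_L)
  structure(list(C = C, g_L = g_L, E_L = E_L, Delta_T = Delta_T,
                 V_th = V_th, V_reset = V_reset, a = a, b = b,
                 tau_w = tau_w, I_e = I_e, spike_cutoff = 0,
                 V_floor = V_floor),
            class = "adex_params")
}

#' AdEx neuron state
#'
#' @param V_m membrane potential (mV)
#' @param w_adapt adaptation current (pA). The adaptation current is kept
#'   under its own name to avoid colliding with the synaptic conductance
#'   weight, which shares the symbol *w* in the coupling equations.
#' @return An object of class `adex_state`.
#' @export
adex_state <- function(V_m = -58, w_adapt = 0) {
  structure(list(V_m = V_m, w_adapt = w_adapt), class = "adex_state")
}

#' Advance an AdEx neuron by one explicit-Euler step
#'
#' Performs one `dt` update of the AdEx dynamics. The spike test (`V_m` > 0
#' mV) is applied both to the incoming state (so that an externally
#' perturbed supra-cutoff state resets immediately, without integrating a
#' divergent trajectory) and to the freshly integrated state. On a spike,
#' `V_m` is set to the *effective* reset potential and `w_adapt` increases
#' by `b`.
#'
#' Voltage characteristic manipulation: when `V_cm_target` is `"V_th"` or
#' `"V_reset"` the effective characteristic is the corresponding parameter
#' value plus/minus the offset (see [effective_voltage_characteristic()] for
#' the sign convention applied at the network level; here `V_cm` is added to
#' `V_th` and subtracted from `V_reset` so that a positive, excitatory offset
#' always narrows the `V_th`--`V_reset` gap). When the target is `"V_m"`,
#' `V_cm` is added to the membrane potential *after* the integration step.
#'
#' @param state an [adex_state()]
#' @param params an [adex_params()]
#' @param dt integration step (ms), > 0
#' @param I_ext external current in addition to `params$I_e` (pA)
#' @param V_cm_target one of `"none"`, `"V_th"`, `"V_reset"`, `"V_m"`
#' @param V_cm signed voltage characteristic offset (mV)
#' @return A list with elements `state` (the new [adex_state()]) and
#'   `spiked` (logical).
#' @examples
#' p <- adex_params()
#' s <- adex_state(V_m = 5, w_adapt = 50)  # supra-cutoff: resets immediately
#' adex_step(s, p, dt = 0.1)
#' @export
adex_step <- function(state, params, dt, I_ext = 0,
                      V_cm_target = c("none", "V_th", "V_reset", "V_m"),
                      V_cm = 0) {
  V_cm_target <- match.arg(V_cm_target)
  stopifnot(dt > 0, is.finite(V_cm))
  vth <- params$V_th + if (V_cm_target == "V_th") V_cm else 0
  vreset <- params$V_reset - if (V_cm_target == "V_reset") V_cm else 0
  v <- state$V_m
  w <- state$w_adapt
  I <- params$I_e + I_ext
  spiked <- FALSE
  if (v > params$spike_cutoff) {
    v <- vreset
    w <- w + params$b
    spiked <- TRUE
  } else {
    dv <- (-params$g_L * (v - params$E_L) +
             params$g_L * params$Delta_T * exp((v - vth) / params$Delta_T) -
             w + I) / params$C
    wn <- w + dt / params$tau_w * (params$a * (v - params$E_L) - w)
    v <- v + dt * dv
    w <- wn
    if (!is.finite(v) || !is.finite(w)) {
      stop("AdEx integration blow-up at dt = ", dt,
           " (V_m = ", state$V_m, ", I_ext = ", I_ext, ")")
    }
    if (v > params$spike_cutoff) {
      v <- vreset
      w <- w + params$b
      spiked <- TRUE
    }
    if (v < params$V_floor) v <- params$V_floor
  }
  if (V_cm_target == "V_m") v <- v + V_cm
  if (!is.finite(v) || !is.finite(w)) {
    stop("AdEx integration blow-up at dt = ", dt,
         " (V_m = ", state$V_m, ", I_ext = ", I_ext, ")")
  }
  list(state = adex_state(V_m = v, w_adapt = w), spiked = spiked)
}

#' Integrate a single AdEx neuron over a time span
#'
#' Convenience wrapper around [adex_step()] for constant (or per-step)
#' external current; used for rheobase searches and single-neuron checks.
#'
#' @inheritParams adex_step
#' @param duration total simulated time (ms)
#' @param I_ext either a scalar (pA) or a vector with one value per step
#' @return A list with `V_m` and `w_adapt` trajectories (one value per step,
#'   post-update) and `spike_times` (ms).
#' @export
adex_run <- function(state, params, dt, duration, I_ext = 0) {
  n <- round(duration / dt)
  I <- if (length(I_ext) == 1) rep(I_ext, n) else I_ext
  stopifnot(length(I) >= n)
  vs <- numeric(n)
  ws <- numeric(n)
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    r <- adex_step(state, params, dt, I[k])
    state <- r$state
    vs[k] <- state$V_m
    ws[k] <- state$w_adapt
    if (r$spiked) spikes <- c(spikes, (k - 1) * dt)
  }
  list(V_m = vs, w_adapt = ws, spike_times = spikes, state = state)
}
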