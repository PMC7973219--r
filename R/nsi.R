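#' Parameters of the non-spiking interneuron (NSI)
#'
#' The NSI is a leaky integrator operated strictly below threshold: it has no
#' reset condition, and its graded membrane-potential displacement from rest
#' is the signal passed on to post-synaptic spiking neurons. Dynamics, in
#' displacement coordinates `u = V_m - V_rest`:
#' \deqn{\tau_m \, du/dt = -u + R I_{input}}
#'
#' The default membrane resistance is chosen so that the maximum input
#' current of 148 pA displaces the membrane by exactly the biologically
#' plausible 15 mV (R = 101.35 MOhm: 101.35 MOhm x 148 pA = 15.0 mV).
#' `V_rest` defaults to -60 mV. `guard_threshold` is a numerical contract: a
#' valid sub-threshold run must never cross it.
#'
#' @param tau_m membrane time constant (ms)
#' @param R membrane resistance (MOhm)
#' @param V_rest rest potential (mV)
#' @param guard_threshold contract-violation voltage (mV)
#' @return An object of class `nsi_params`.
#' @export
nsi_params <- function(tau_m = 20, R = 101.35, V_rest = -60,
                       guard_threshold = -40) {
  stopifnot(tau_m > 0, R > 0)
  structure(list(tau_m = tau_m, R = R, V_rest = V_rest,
                 guard_threshold = guard_threshold),
            class = "nsi_params")
}

#' NSI state
#' @param V_m membrane potential (mV)
#' @return An object of class `nsi_state`.
#' @export
nsi_state <- function(V_m = -60) {
  structure(list(V_m = V_m), class = "nsi_state")
}

#' Advance the NSI by one explicit-Euler step
#'
#' One `dt` update of the RC dynamics. The returned membrane potential
#' relaxes exponentially toward `V_rest + R * I_input` (R in MOhm and I in pA
#' give microvolts; the product is divided by 1000 to yield mV).
#'
#' @param state an [nsi_state()]
#' @param params an [nsi_params()]
#' @param dt integration step (ms), > 0
#' @param I_input input current (pA)
#' @return The updated [nsi_state()].
#' @examples
#' s <- nsi_state()
#' p <- nsi_params()
#' nsi_step(s, p, dt = 0.1, I_input = 148)
#' @export
nsi_step <- function(state, params, dt, I_input = 0) {
  stopifnot(dt > 0)
  u <- state$V_m - params$V_rest
  u <- u + dt / params$tau_m * (-u + params$R * I_input / 1000)
  v <- params$V_rest + u
  if (v > params$guard_threshold) {
    stop("NSI sub-threshold contract violated: V_m = ", round(v, 3),
         " mV exceeds guard threshold ", params$guard_threshold, " mV")
  }
  nsi_state(V_m = v)
}
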