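#' Event-driven NSI state
#'
#' The event-driven counterpart of the clock-driven NSI: between input
#' events the membrane potential decays exponentially toward rest with a
#' per-ms `decay` factor; an input event at time `t` first applies the
#' elapsed decay and then increments the potential by `I_input / C`. The
#' state also records `t_updated`, the time of the most recent processed
#' event, which together with the other fields makes the membrane potential
#' at any later time recoverable without a global clock.
#'
#' The relation `decay = exp(-1 ms / tau_m)` ties the event engine to the
#' clock-driven [nsi_params()] time constant.
#'
#' @param V_m membrane potential (mV)
#' @param V_rest rest potential (mV)
#' @param decay per-ms decay factor, in (0, 1)
#' @param C membrane capacitance (pF)
#' @param t_updated time of the last processed event (ms)
#' @return An object of class `event_nsi_state`.
#' @export
event_nsi_state <- function(V_m = -60, V_rest = -60,
                            decay = exp(-1 / 20), C = 200, t_updated = 0) {
  stopifnot(decay > 0, decay < 1, C > 0)
  structure(list(V_m = V_m, V_rest = V_rest, decay = decay, C = C,
                 t_updated = t_updated),
            class = "event_nsi_state")
}

#' Process one input event of the event-driven NSI
#'
#' @param state an [event_nsi_state()]
#' @param event_time event timestamp (ms), >= `state$t_updated`
#' @param I_input input magnitude carried by the event (pA); the membrane
#'   increment is `I_input / C`
#' @return The updated [event_nsi_state()] with `t_updated = event_time`.
#' @export
event_update <- function(state, event_time, I_input = 0) {
  stopifnot(inherits(state, "event_nsi_state"))
  if (event_time < state$t_updated) {
    stop("out-of-order event: time ", event_time, " ms precedes t_updated ",
         state$t_updated, " ms")
  }
  v <- reconstruct_vm(state, event_time) + I_input / state$C
  event_nsi_state(V_m = v, V_rest = state$V_rest, decay = state$decay,
                  C = state$C, t_updated = event_time)
}

#' Asynchronously reconstruct the NSI membrane potential
#'
#' Pure function evaluated on the synapse side from a state snapshot:
#' `V_rest + (V_m - V_rest) * decay^(t - t_updated)`. Post-synaptic neurons
#' never read the NSI directly; they receive snapshots and reconstruct the
#' exact membrane potential as needed.
#'
#' @param snapshot an [event_nsi_state()] snapshot
#' @param t query time (ms), >= `snapshot$t_updated`
#' @return Membrane potential at `t` (mV).
#' @export
reconstruct_vm <- function(snapshot, t) {
  stopifnot(inherits(snapshot, "event_nsi_state"))
  if (any(t < snapshot$t_updated)) {
    stop("cannot reconstruct before t_updated = ", snapshot$t_updated, " ms")
  }
  snapshot$V_rest +
    (snapshot$V_m - snapshot$V_rest) * snapshot$decay^(t - snapshot$t_updated)
}

#' Affine mapping from NSI membrane potential to V_th
#'
#' Linear interpolation from the `[V_m_low, V_m_high]` range onto
#' `[V_th_low, V_th_high]`, clamped at both limits -- this is how the NSI
#' controls the threshold of the event-driven CPG neurons while keeping the
#' threshold within explicit bounds. The default limits tie the clamps to
#' the clock-driven manipulation endpoints (-56 to -51 mV over the 15 mV
#' displacement range).
#'
#' @param V_m_low,V_m_high NSI membrane potential range (mV)
#' @param V_th_low,V_th_high threshold range (mV)
#' @return An object of class `vth_mapping`.
#' @export
vth_mapping <- function(V_m_low = -60, V_m_high = -45,
                        V_th_low = -56, V_th_high = -51) {
  stopifnot(V_m_low < V_m_high)
  structure(list(V_m_low = V_m_low, V_m_high = V_m_high,
                 V_th_low = V_th_low, V_th_high = V_th_high),
            class = "vth_mapping")
}

#' @rdname vth_mapping
#' @param mapping a `vth_mapping`
#' @param V_m NSI membrane potential (mV); vectorized
#' @return `V_th` in mV, clamped to `[V_th_low, V_th_high]`.
#' @export
map_vm_to_vth <- function(mapping, V_m) {
  stopifnot(inherits(mapping, "vth_mapping"))
  frac <- (V_m - mapping$V_m_low) / (mapping$V_m_high - mapping$V_m_low)
  frac <- pmin(pmax(frac, 0), 1)
  mapping$V_th_low + frac * (mapping$V_th_high - mapping$V_th_low)
}

#' Event-driven CPG demonstration
#'
#' A two-neuron mutually inhibitory CPG whose V_th is controlled by an
#' event-driven NSI. Input spikes (e.g. a step function encoded with
#' [bsa_encode()]) drive the NSI; on every input event the NSI updates its
#' state and broadcasts a snapshot to the synapses of both AdEx neurons,
#' which asynchronously reconstruct the NSI membrane potential and map it
#' onto their threshold via [map_vm_to_vth()]. The AdEx neurons themselves
#' are integrated clock-driven between events (the membrane equation has no
#' closed form); the event contract covers the NSI-to-synapse path, where
#' neuron state is only ever read from snapshots. There is no noise in the
#' event engine.
#'
#' @param input a [spike_train()] of NSI input events
#' @param mapping a [vth_mapping()]
#' @param duration run length (ms); defaults to the input duration
#' @param input_current magnitude carried by each input event (pA)
#' @param adex [adex_params()] for the two CPG neurons (V_th is overridden
#'   by the mapping)
#' @param bias constant drive to both neurons (pA)
#' @param w_inh mutual-inhibition weight (pA per spike, < 0)
#' @param tau_syn,delay synapse decay constant and delay (ms)
#' @param nsi_decay per-ms NSI decay factor
#' @param dt integration step (ms)
#' @return An object of class `event_demo`: spike times `left`/`right`,
#'   per-ms traces `vth_left`, `vth_right`, `nsi_v`, and `times`.
#' @export
run_event_demo <- function(input, mapping = vth_mapping(),
                           duration = NULL, input_current = 150,
                           adex = adex_params(), bias = 200,
                           w_inh = -400, tau_syn = 5, delay = 1,
                           nsi_decay = exp(-1 / 20), dt = 0.1) {
  ev_t <- sort(input$time)
  if (is.null(duration)) duration <- attr(input, "duration")
  n_steps <- round(duration / dt)
  rec <- round(1 / dt)  # 1 ms trace grid
  n_rec <- round(duration)

  nsi <- event_nsi_state(decay = nsi_decay, C = adex$C)
  snapshot <- nsi  # what the synapses last received
  vth <- c(map_vm_to_vth(mapping, nsi$V_m), map_vm_to_vth(mapping, nsi$V_m))

  V <- c(adex$E_L + 1, adex$E_L - 1)  # symmetry breaking for antiphase
  W <- c(0, 0)
  syn <- c(0, 0)
  decay_syn <- exp(-dt / tau_syn)
  delay_steps <- max(1L, round(delay / dt))
  hist <- matrix(0L, nrow = n_steps, ncol = 2)
  sp <- list(numeric(0), numeric(0))
  vth_tr <- matrix(NA_real_, nrow = n_rec, ncol = 2)
  nsi_tr <- numeric(n_rec)

  ei <- 1L
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    while (ei <= length(ev_t) && ev_t[ei] <= t) {
      nsi <- event_update(nsi, ev_t[ei], input_current)
      snapshot <- nsi  # parameter-update message to the synapses
      ei <- ei + 1L
    }
    # synapse-side reconstruction; identical parameters for both synapses
    vm_nsi <- reconstruct_vm(snapshot, t)
    vth[] <- map_vm_to_vth(mapping, vm_nsi)

    del <- k - delay_steps
    arr_from <- if (del >= 1) hist[del, ] else c(0L, 0L)
    for (i in 1:2) {
      syn[i] <- syn[i] * decay_syn + w_inh * arr_from[3 - i]
      v <- V[i]; w <- W[i]
      spiked <- FALSE
      if (v > adex$spike_cutoff) {
        v <- adex$V_reset; w <- w + adex$b; spiked <- TRUE
      } else {
        dv <- (-adex$g_L * (v - adex$E_L) +
                 adex$g_L * adex$Delta_T * exp((v - vth[i]) / adex$Delta_T) -
                 w + bias + syn[i]) / adex$C
        wn <- w + dt / adex$tau_w * (adex$a * (v - adex$E_L) - w)
        v <- v + dt * dv; w <- wn
        if (v > adex$spike_cutoff) {
          v <- adex$V_reset; w <- w + adex$b; spiked <- TRUE
        }
      }
      V[i] <- v; W[i] <- w
      if (spiked) {
        hist[k, i] <- 1L
        sp[[i]] <- c(sp[[i]], t)
      }
    }
    if ((k - 1) %% rec == 0) {
      r <- (k - 1) %/% rec + 1
      vth_tr[r, ] <- vth
      nsi_tr[r] <- vm_nsi
    }
  }
  structure(list(left = sp[[1]], right = sp[[2]],
                 vth_left = vth_tr[, 1], vth_right = vth_tr[, 2],
                 nsi_v = nsi_tr, times = seq_len(n_rec) - 1,
                 mapping = mapping, duration = duration),
            class = "event_demo")
}
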