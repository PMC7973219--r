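#' Gaussian current-noise configuration
#'
#' Independent Gaussian noise currents are redrawn for every neuron at every
#' integration step (piecewise-constant over a step; the standard deviation
#' is not rescaled by dt). The NSI receives weaker noise than the spiking
#' neurons so that the noise stays comparable to the 29.6 pA input steps.
#'
#' @param nsi_std standard deviation of the NSI noise current (pA)
#' @param neuron_std standard deviation for all spiking neurons (pA)
#' @param mean common mean of the noise currents (pA)
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(nsi_std = 25, neuron_std = 50, mean = 0) {
  stopifnot(nsi_std >= 0, neuron_std >= 0)
  structure(list(nsi_std = nsi_std, neuron_std = neuron_std, mean = mean),
            class = "noise_config")
}

#' Network topology and calibrated parameters
#'
#' Describes the 16-neuron mixed network: three populations of `n_per_pop`
#' AdEx neurons (the mutually inhibitory excitatory/inhibitory halves of the
#' spiking CPG, plus the motor population driven by both) and a single NSI.
#' Connectivity between populations is all-to-all with uniform weights and a
#' common delay; there are no connections within a population. Synapses are
#' current-based with exponential decay: each presynaptic spike adds
#' `weight` pA to the target's synaptic current, which decays with
#' `tau_syn`.
#'
#' The synaptic weights and bias currents are calibration values, fixed once
#' by [calibrate_network()] against the baseline operating points of the
#' network (burst frequency 2.36-2.94 Hz at a 10 mV threshold-reset gap,
#' 8.0-8.9 Hz at the default 5 mV gap, and a baseline rate-coded peak of
#' 23-24.26 spikes per 5 ms window); the defaults below are the shipped
#' calibration.
#'
#' @param n_per_pop neurons per population
#' @param adex [adex_params()] for the CPG populations (the default
#'   V_th/V_reset of -51/-46 mV are the values used whenever a
#'   characteristic is not under manipulation)
#' @param adex_mnp [adex_params()] for the motor population; defaults to
#'   the CPG set except for the membrane capacitance, which is a
#'   calibration value (the motor readout gain)
#' @param nsi [nsi_params()] for the interneuron
#' @param bias_e,bias_i,bias_m bias currents (pA) for the excitatory sCPG,
#'   inhibitory sCPG and motor populations
#' @param w_ie weight of the E -> I projection (pA per spike; <= 0:
#'   the CPG halves are coupled by mutual inhibition)
#' @param w_ei weight of the I -> E projection (<= 0, inhibitory)
#' @param w_em weight of the E -> MNP projection (>= 0)
#' @param w_im weight of the I -> MNP projection (<= 0)
#' @param tau_syn synaptic current decay constant of the CPG
#'   cross-inhibition (ms)
#' @param tau_syn_m decay constant of the projections onto the motor
#'   population (ms); defaults to `tau_syn`
#' @param delay synaptic transmission delay (ms)
#' @param init_v_e,init_v_i,init_v_m initial membrane potentials (mV); the
#'   two CPG halves start slightly apart so the deterministic (noise-free)
#'   network still settles into antiphase bursting
#' @param dt integration step (ms)
#' @param record_dt recording grid (ms)
#' @param disp_max biologically plausible NSI displacement range (mV)
#' @param vcm_divisor divisor of the voltage-characteristic offset
#' @param vm_every_step apply a V_m-targeted offset at every integration
#'   step (`TRUE`, default) or once per recording step
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_per_pop = 5,
                           adex = adex_params(C = 80, V_floor = -120),
                           adex_mnp = adex_params(C = 80, V_floor = -120),
                           nsi = nsi_params(),
                           bias_e = 275, bias_i = 275, bias_m = -920,
                           w_ie = -40, w_ei = -40,
                           w_em = 420, w_im = -60,
                           tau_syn = 5, tau_syn_m = tau_syn, delay = 3,
                           init_v_e = -57, init_v_i = -59, init_v_m = -58,
                           dt = 0.1, record_dt = 1,
                           disp_max = 15, vcm_divisor = 3,
                           vm_every_step = TRUE) {
  stopifnot(n_per_pop >= 1, tau_syn > 0, delay >= dt, dt > 0,
            record_dt >= dt)
  structure(list(n_per_pop = n_per_pop, adex = adex, adex_mnp = adex_mnp,
                 nsi = nsi,
                 bias_e = bias_e, bias_i = bias_i, bias_m = bias_m,
                 w_ie = w_ie, w_ei = w_ei, w_em = w_em, w_im = w_im,
                 tau_syn = tau_syn, tau_syn_m = tau_syn_m, delay = delay,
                 init_v_e = init_v_e, init_v_i = init_v_i,
                 init_v_m = init_v_m,
                 dt = dt, record_dt = record_dt,
                 disp_max = disp_max, vcm_divisor = vcm_divisor,
                 vm_every_step = vm_every_step),
            class = "network_config")
}

.pop3 <- function(config, field) {
  c(config$adex[[field]], config$adex[[field]], config$adex_mnp[[field]])
}

.voltage_target_code <- function(target) {
  switch(target, none = 0L, V_th = 1L, V_reset = 2L, V_m = 3L,
         stop("unknown voltage target: ", target))
}

#' Simulate the mixed NSI + spiking-CPG network
#'
#' Runs the clock-driven simulation of one experiment: every neuron is
#' integrated by explicit Euler at `config$dt`, the NSI membrane potential
#' drives the graded current injections and voltage-characteristic offsets
#' at every integration step, and spikes are recorded with recording-grid
#' timestamps. Identical `(spec, seed)` pairs yield identical spike trains.
#'
#' @param spec an [build_experiment()] spec (or a list with the same fields)
#' @param config a [network_config()]
#' @param noise a [noise_config()]; use `noise_config(0, 0)` for a
#'   deterministic run
#' @param seed RNG seed; defaults to the seed stored in `spec`
#' @param w_syn NSI output synaptic conductance (nS) used for current
#'   injections
#' @param schedule override of the spec's [input_schedule()]
#' @param record_traces record per-neuron membrane potentials on the
#'   recording grid
#' @param feedback optional [feedback_config()]; when supplied, the MNP
#'   injection conductance is regulated by the rate-coded output instead of
#'   using the fixed `w_syn`
#' @param fb_window rate window used by the feedback loop (ms)
#' @return An object of class `nsi_sim`: a list with `spikes` (a
#'   [spike_train()]), `nsi_v`, `vcm` and `fb_weight` traces on the
#'   recording grid, `mnp_counts_ms`, and the resolved spec/config.
#' @examples
#' \donttest{
#' spec <- build_experiment(1, 0, seed = 42)
#' sim <- simulate_network(spec)
#' head(sim$spikes)
#' }
#' @export
simulate_network <- function(spec, config = network_config(),
                             noise = noise_config(), seed = spec$seed,
                             w_syn = 70, schedule = spec$input_schedule,
                             record_traces = FALSE, feedback = NULL,
                             fb_window = 5) {
  stopifnot(inherits(config, "network_config"))
  currents <- schedule_currents(schedule, spec$duration, config$record_dt) +
    noise$mean
  vt <- .voltage_target_code(spec$voltage_target)
  target_e <- spec$scpg_targets %in% c("both", "excitatory_pop")
  target_i <- spec$scpg_targets %in% c("both", "inhibitory_pop")
  manip <- if (vt %in% 1:2) {
    voltage_manipulation(spec$voltage_target, spec$polarity)
  } else {
    voltage_manipulation("V_th", spec$polarity)  # initials unused
  }
  fb <- !is.null(feedback)
  if (fb) stopifnot(inherits(feedback, "feedback_config"))

  set.seed(seed)
  raw <- sim_network_cpp(
    duration = spec$duration, dt = config$dt, record_dt = config$record_dt,
    C = .pop3(config, "C"), gL = .pop3(config, "g_L"),
    EL = .pop3(config, "E_L"), DeltaT = .pop3(config, "Delta_T"),
    a = .pop3(config, "a"), b = .pop3(config, "b"),
    tauw = .pop3(config, "tau_w"), vfloor = .pop3(config, "V_floor"),
    vth_default = config$adex$V_th, vreset_default = config$adex$V_reset,
    bias = c(config$bias_e, config$bias_i, config$bias_m) + noise$mean,
    init_v = c(config$init_v_e, config$init_v_i, config$init_v_m),
    n_per_pop = config$n_per_pop,
    w_ei = config$w_ei, w_ie = config$w_ie,
    w_em = config$w_em, w_im = config$w_im,
    tau_syn = config$tau_syn, tau_syn_m = config$tau_syn_m,
    delay = config$delay,
    nsi_tau = config$nsi$tau_m, nsi_R = config$nsi$R,
    nsi_vrest = config$nsi$V_rest, nsi_guard = config$nsi$guard_threshold,
    nsi_input = currents,
    noise_nsi = noise$nsi_std, noise_neuron = noise$neuron_std,
    polarity = if (spec$polarity == "excitatory") 1L else -1L,
    w_syn = w_syn,
    inj_mnp = !fb && spec$mnp_injection != "none",
    inj_e = spec$scpg_injection != "none" && target_e,
    inj_i = spec$scpg_injection != "none" && target_i,
    voltage_target = vt, vt_e = target_e, vt_i = target_i,
    vth_initial = manip$V_th_initial, vreset_initial = manip$V_reset_initial,
    disp_max = config$disp_max, vcm_divisor = config$vcm_divisor,
    vm_every_step = config$vm_every_step,
    feedback = fb,
    fb_sc_exc = if (fb) feedback$scaling_factor_excitatory else 0,
    fb_sc_inh = if (fb) feedback$scaling_factor_inhibitory else 0,
    fb_desired = if (fb) feedback$desired_spike_number else 0,
    fb_cap = if (fb && !is.null(feedback$weight_cap)) feedback$weight_cap else -1,
    fb_window = fb_window,
    record_traces = record_traces
  )

  grid <- function(t) floor(t / config$record_dt) * config$record_dt
  pop_df <- function(t, id, pop) {
    data.frame(time = grid(t), neuron = id,
               population = rep(pop, length(t)))
  }
  spikes <- rbind(
    pop_df(raw$spike_t_e, raw$spike_id_e, "scpg_excitatory"),
    pop_df(raw$spike_t_i, raw$spike_id_i, "scpg_inhibitory"),
    pop_df(raw$spike_t_m, raw$spike_id_m, "mnp")
  )
  structure(list(
    spikes = spike_train(spikes, duration = spec$duration),
    nsi_v = raw$nsi_v, vcm = raw$vcm,
    mnp_counts_ms = raw$mnp_counts_ms,
    fb_weight = if (fb) raw$fb_weight else NULL,
    traces = if (record_traces) raw$traces else NULL,
    spec = spec, config = config, noise = noise, seed = seed,
    w_syn = w_syn, schedule = schedule,
    feedback = feedback
  ), class = "nsi_sim")
}

#' Run the closed-loop amplitude-regulation experiment
#'
#' Reproduces the internal-feedback demonstration: the network frequency is
#' driven through an up-hold-down staircase of V_th manipulations (ten 1.2 s
#' divisions over 12 s) while the conductance of the NSI -> MNP injection is
#' regulated each recording step by [feedback_weight()] from the motor
#' output's latest rate-window spike count. The control condition applies
#' the fixed maximum conductance instead.
#'
#' @param cfg a [feedback_config()]; `NULL` runs the unregulated control
#' @param config a [network_config()]
#' @param seed RNG seed
#' @param duration trial length (ms)
#' @param noise a [noise_config()]
#' @param w_max conductance used by the unregulated control (nS)
#' @return An `nsi_sim` object (see [simulate_network()]); for regulated
#'   runs `fb_weight` holds the signed conductance trace.
#' @export
run_feedback_loop <- function(cfg, config = network_config(), seed = 1,
                              duration = 12000, noise = noise_config(),
                              w_max = 70) {
  spec <- build_experiment(4, 0, duration = duration, seed = seed)
  sched <- input_schedule(kind = "feedback", step_interval = 1200)
  simulate_network(spec, config = config, noise = noise, seed = seed,
                   w_syn = w_max, schedule = sched, feedback = cfg)
}
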