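#' Stepping (or constant) input-current schedule for the NSI
#'
#' The standard schedule steps the NSI input current through 6 levels held
#' 1 s each over a 6 s trial, from 0 pA up to the maximum of 148 pA in
#' increments of 148/5 = 29.6 pA. Excitatory tests step upward (0 to
#' 148 pA); inhibitory tests step downward, so that the system is "excited"
#' by the progressive removal of inhibition.
#'
#' @param kind `"stepping"`, `"constant"`, `"toggling"` or `"feedback"`.
#'   `"toggling"` alternates between two levels every `step_interval`;
#'   `"feedback"` is the up-hold-down staircase used by the amplitude
#'   regulation demonstration.
#' @param I_max maximum input current (pA)
#' @param step_interval level duration (ms)
#' @param direction `"up"` (excitatory) or `"down"` (inhibitory)
#' @param n_levels number of levels for a stepping schedule
#' @param levels explicit level sequence (pA), overriding the above
#' @return An object of class `input_schedule`.
#' @export
input_schedule <- function(kind = c("stepping", "constant", "toggling", "feedback"),
                           I_max = 148, step_interval = 1000,
                           direction = c("up", "down"), n_levels = 6,
                           levels = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (is.null(levels)) {
    levels <- switch(kind,
      constant = I_max,
      stepping = {
        lv <- seq(0, I_max, length.out = n_levels)
        if (direction == "down") rev(lv) else lv
      },
      toggling = rep(c(0, I_max), length.out = n_levels),
      feedback = I_max * c(0.24, 0.43, 0.62, 0.81, 1, 1, 0.81, 0.62, 0.43, 0.24)
    )
  }
  structure(list(kind = kind, I_max = I_max, step_interval = step_interval,
                 direction = direction, levels = levels),
            class = "input_schedule")
}

#' Expand an input schedule onto the recording grid
#'
#' @param schedule an [input_schedule()]
#' @param duration total time (ms)
#' @param record_dt recording grid (ms)
#' @return Numeric vector of input currents (pA), one per recording bin.
#' @export
schedule_currents <- function(schedule, duration, record_dt = 1) {
  n_rec <- round(duration / record_dt)
  bins_per_level <- round(schedule$step_interval / record_dt)
  idx <- pmin(floor(seq_len(n_rec) - 1) %/% bins_per_level + 1,
              length(schedule$levels))
  schedule$levels[idx]
}

# Table of the twelve communication tests: which pathway carries a stepping
# current injection and which voltage characteristic (if any) is manipulated.
.test_matrix <- data.frame(
  test_no = 1:12,
  mnp_injection = c("stepping", "none", "stepping", "stepping", "stepping",
                    "stepping", "none", "stepping", "none", "stepping",
                    "none", "stepping"),
  scpg_injection = c("none", "stepping", "stepping", "none", "none", "none",
                     "none", "stepping", "none", "stepping", "none",
                     "stepping"),
  voltage_target = c("none", "none", "none", "V_th", "V_reset", "V_m",
                     "V_th", "V_th", "V_reset", "V_reset", "V_m", "V_m"),
  stringsAsFactors = FALSE
)

#' Build one cell of the experiment test matrix
#'
#' The twelve main tests select which communication pathways are active:
#' stepping current injection to the motor population (MNP), stepping
#' current injection to the spiking-CPG populations, and/or manipulation of
#' one voltage characteristic (V_th, V_reset or V_m) of the sCPG
#' populations. The six subcategories select the polarity (0-2 excitatory,
#' 3-5 inhibitory) and which sCPG populations are targeted (0/3 both, 1/4
#' excitatory population only, 2/5 inhibitory population only).
#'
#' @param test_no main test number, 1-12
#' @param subcategory subcategory code, 0-5
#' @param duration trial duration (ms)
#' @param seed RNG seed stored with the spec
#' @param I_max maximum NSI input current (pA)
#' @return An object of class `experiment_spec`.
#' @examples
#' build_experiment(1, 0)  # MNP stepping injection, excitatory, no voltage target
#' build_experiment(7, 3)  # V_th manipulation only, inhibitory, both populations
#' @export
build_experiment <- function(test_no, subcategory, duration = 6000,
                             seed = 1L, I_max = 148) {
  if (!(length(test_no) == 1 && test_no %in% 1:12)) {
    stop("test_no must be a single integer in 1..12 (got ", test_no, ")")
  }
  if (!(length(subcategory) == 1 && subcategory %in% 0:5)) {
    stop("subcategory must be a single integer in 0..5 (got ", subcategory, ")")
  }
  row <- .test_matrix[test_no, ]
  polarity <- if (subcategory <= 2) "excitatory" else "inhibitory"
  scpg_targets <- switch(as.character(subcategory %% 3),
                         "0" = "both", "1" = "excitatory_pop", "2" = "inhibitory_pop")
  direction <- if (polarity == "excitatory") "up" else "down"
  has_stepping <- row$mnp_injection == "stepping" || row$scpg_injection == "stepping"
  sched <- input_schedule(kind = "stepping", I_max = I_max,
                          direction = direction)
  structure(list(
    test_no = test_no, subcategory = subcategory,
    label = paste0(test_no, "_", subcategory),
    mnp_injection = row$mnp_injection,
    scpg_injection = row$scpg_injection,
    voltage_target = row$voltage_target,
    polarity = polarity, scpg_targets = scpg_targets,
    duration = duration, input_schedule = sched, seed = seed,
    has_stepping = has_stepping
  ), class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("<experiment_spec ", x$label, "> ",
      "MNP injection: ", x$mnp_injection,
      ", sCPG injection: ", x$scpg_injection,
      ", voltage target: ", x$voltage_target,
      ", polarity: ", x$polarity,
      ", sCPG targets: ", x$scpg_targets, "\n", sep = "")
  invisible(x)
}
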