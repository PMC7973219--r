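#' Spike train container
#'
#' A spike train is a data frame of timestamped spike events with columns
#' `time` (ms), `neuron` (integer id within its population) and
#' `population` (label). It is the common currency between the simulation
#' engines and the analysis functions.
#'
#' @param events data frame with columns `time`, `neuron`, `population`
#'   (the latter is filled with `"pop"` if missing)
#' @param duration trial duration (ms); all times must lie in
#'   `[0, duration]`
#' @return The validated events data frame with class `spike_train` and a
#'   `duration` attribute.
#' @export
spike_train <- function(events, duration = NULL) {
  if (is.null(events$population)) events$population <- rep("pop", nrow(events))
  stopifnot(all(c("time", "neuron") %in% names(events)),
            all(events$time >= 0))
  if (is.null(duration)) duration <- if (nrow(events)) max(events$time) else 0
  stopifnot(all(events$time <= duration))
  o <- order(events$population, events$neuron, events$time)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("spike_train", "data.frame"),
            duration = duration)
}

#' Extract the spike times of one population
#'
#' @param spikes a [spike_train()]
#' @param population population label; `NULL` keeps all events
#' @return Sorted numeric vector of spike times (ms).
#' @export
population_spikes <- function(spikes, population = NULL) {
  t <- if (is.null(population)) spikes$time
       else spikes$time[spikes$population == population]
  sort(t)
}

#' Write / read spike trains as two-column text
#'
#' One file per population, tab-separated `time_ms<TAB>neuron_id`, plus the
#' population name in the file name.
#'
#' @param spikes a [spike_train()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @return Invisibly, the written file paths.
#' @export
write_spike_train <- function(spikes, dir, prefix = "spikes") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pop in unique(spikes$population)) {
    sub <- spikes[spikes$population == pop, c("time", "neuron")]
    path <- file.path(dir, paste0(prefix, "_", pop, ".txt"))
    utils::write.table(sub, path, sep = "\t", row.names = FALSE,
                       col.names = c("time_ms", "neuron_id"), quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_spike_train
#' @param path a file written by `write_spike_train`
#' @param population population label to attach
#' @export
read_spike_train <- function(path, population = "pop") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  spike_train(data.frame(time = d$time_ms, neuron = d$neuron_id,
                         population = population))
}
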