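#' Spike data container
#'
#' Event list of a continuous recording or simulation: spike times (ms) and
#' unit ids, plus unit metadata (population, cluster), total duration and a
#' free-form metadata list. This is the interchange object between the
#' simulator and the statistics functions.
#'
#' @param time spike times (ms).
#' @param unit integer unit ids (parallel to \code{time}).
#' @param units data frame of unit metadata with at least a \code{unit}
#'   column; typically also \code{population} and \code{cluster}.
#' @param duration total recorded duration (ms).
#' @param meta list of provenance metadata (seed, dt, topology, ...).
#' @param probes optional probe traces (see [simulate_network()]).
#' @return Object of class \code{spike_data}.
#' @export
spike_data <- function(time, unit, units, duration, meta = list(),
                       probes = NULL) {
  stopifnot(length(time) == length(unit), duration > 0)
  o <- order(time, unit)
  structure(list(spikes = data.frame(time = as.numeric(time)[o],
                                     unit = as.integer(unit)[o]),
                 units = units, duration = duration, meta = meta,
                 probes = probes),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("<spike_data>", nrow(x$spikes), "spikes,", nrow(x$units), "units,",
      x$duration, "ms\n")
  invisible(x)
}

#' Population firing rates
#'
#' Mean firing rate per population (spikes/s per neuron) over a time window.
#'
#' @param sd a [spike_data()] object.
#' @param from,to window bounds (ms); default the full recording.
#' @return Named numeric vector, one element per population.
#' @export
population_rates <- function(sd, from = 0, to = sd$duration) {
  sp <- sd$spikes[sd$spikes$time > from & sd$spikes$time <= to, ]
  pop <- sd$units$population[match(sp$unit, sd$units$unit)]
  n_by_pop <- table(sd$units$population)
  counts <- table(factor(pop, levels = names(n_by_pop)))
  out <- 1000 * as.numeric(counts) / as.numeric(n_by_pop) / (to - from)
  names(out) <- names(n_by_pop)
  out
}

#' Write / read spike data as CSV
#'
#' Spike events go to one CSV (\code{time_ms}, \code{unit_id}, and
#' \code{trial_id} for trial-aligned data); unit metadata to a second CSV.
#' The round trip is lossless for the event table.
#'
#' @param x a [spike_data()] or [trial_aligned()] object.
#' @param path events CSV path.
#' @param units_path optional unit-metadata CSV path.
#' @export
write_spikes_csv <- function(x, path, units_path = NULL) {
  if (inherits(x, "trial_aligned")) {
    write.csv(data.frame(time_ms = x$spikes$time, unit_id = x$spikes$unit,
                         trial_id = x$spikes$trial), path, row.names = FALSE)
  } else {
    write.csv(data.frame(time_ms = x$spikes$time, unit_id = x$spikes$unit),
              path, row.names = FALSE)
  }
  if (!is.null(units_path) && !is.null(x$units))
    write.csv(x$units, units_path, row.names = FALSE)
  invisible(path)
}

#' @param duration,window recording duration (continuous data) or trial
#'   window (aligned data) when reading; inferred from the data if omitted.
#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path, units_path = NULL, duration = NULL,
                            window = NULL) {
  ev <- read.csv(path)
  units <- if (!is.null(units_path)) read.csv(units_path)
           else data.frame(unit = sort(unique(ev$unit_id)))
  if ("trial_id" %in% names(ev)) {
    trial_aligned(time = ev$time_ms, unit = ev$unit_id, trial = ev$trial_id,
                  trials = data.frame(trial = sort(unique(ev$trial_id))),
                  window = window %||% c(0, max(ev$time_ms, 0)),
                  units = units)
  } else {
    spike_data(ev$time_ms, ev$unit_id, units,
               duration = duration %||% max(ev$time_ms, 1))
  }
}

#' Trial-aligned spike data
#'
#' Spike times per (unit, trial) aligned to a reference event (time 0), with
#' a trial table carrying condition labels.
#'
#' @param time spike times relative to the alignment event (ms).
#' @param unit,trial integer ids parallel to \code{time}.
#' @param trials data frame with one row per trial (column \code{trial};
#'   typically also \code{condition}, \code{cued}, \code{final}).
#' @param window numeric length-2, the time span covered by every trial
#'   (ms relative to the alignment event).
#' @param units optional unit metadata frame.
#' @param align name of the alignment event (metadata).
#' @return Object of class \code{trial_aligned}.
#' @export
trial_aligned <- function(time, unit, trial, trials, window, units = NULL,
                          align = "TS") {
  stopifnot(length(time) == length(unit), length(time) == length(trial),
            length(window) == 2, window[2] > window[1])
  keep <- time >= window[1] & time <= window[2]
  structure(list(spikes = data.frame(time = as.numeric(time)[keep],
                                     unit = as.integer(unit)[keep],
                                     trial = as.integer(trial)[keep]),
                 trials = trials, window = as.numeric(window),
                 units = units, align = align),
            class = "trial_aligned")
}

#' @export
print.trial_aligned <- function(x, ...) {
  cat("<trial_aligned>", nrow(x$spikes), "spikes,", nrow(x$trials),
      "trials, window [", x$window[1], ",", x$window[2], "] ms (align:",
      x$align, ")\n")
  invisible(x)
}

#' Cut trials from a continuous recording
#'
#' Aligns spikes of a continuous [spike_data()] recording to the trial-start
#' events of a trial table, keeping spikes within \code{window} ms of each
#' alignment event.
#'
#' @param sd a [spike_data()] object.
#' @param trials trial table with columns \code{trial} and the alignment-time
#'   column named by \code{align_col} (ms on the continuous timeline).
#' @param window numeric length-2 window around the alignment event (ms).
#' @param align_col name of the alignment-time column, default \code{"TS"}.
#' @return A [trial_aligned()] object.
#' @export
align_trials <- function(sd, trials, window = c(0, 2000), align_col = "TS") {
  stopifnot(align_col %in% names(trials))
  sp <- sd$spikes
  pieces <- lapply(seq_len(nrow(trials)), function(k) {
    t0 <- trials[[align_col]][k]
    sel <- sp$time >= t0 + window[1] & sp$time <= t0 + window[2]
    data.frame(time = sp$time[sel] - t0, unit = sp$unit[sel],
               trial = trials$trial[k])
  })
  all <- do.call(rbind, pieces)
  trial_aligned(all$time, all$unit, all$trial, trials = trials,
                window = window, units = sd$units, align = align_col)
}

#' Spike counts per (unit, trial) in a window
#'
#' @param aligned a [trial_aligned()] object.
#' @param from,to count window (ms, relative to the alignment event).
#' @param units optional subset of unit ids (default: all units in the
#'   metadata, or all units with spikes).
#' @return Integer matrix, units x trials, with dimnames.
#' @export
count_matrix <- function(aligned, from = aligned$window[1],
                         to = aligned$window[2], units = NULL) {
  if (is.null(units))
    units <- if (!is.null(aligned$units)) aligned$units$unit
             else sort(unique(aligned$spikes$unit))
  trials <- aligned$trials$trial
  sp <- aligned$spikes
  sel <- sp$time > from & sp$time <= to & sp$unit %in% units
  tab <- table(factor(sp$unit[sel], levels = units),
               factor(sp$trial[sel], levels = trials))
  m <- matrix(as.integer(tab), nrow = length(units),
              dimnames = list(unit = units, trial = trials))
  m
}
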