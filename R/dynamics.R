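#' Stimulation protocol
#'
#' An ordered set of constant-current stimulation epochs. During an epoch the
#' given amplitude (pA) is added to the external current of every targeted
#' unit; epochs may overlap (amplitudes add).
#'
#' @param t_start,t_end epoch boundaries (ms), vectors of equal length.
#' @param units list of integer vectors: unit ids targeted by each epoch.
#' @param amplitude stimulus amplitude per epoch (pA).
#' @return Object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(t_start = numeric(0), t_end = numeric(0),
                          units = list(), amplitude = numeric(0)) {
  stopifnot(length(t_start) == length(t_end),
            length(t_start) == length(units),
            length(t_start) == length(amplitude),
            all(t_end >= t_start), all(is.finite(amplitude)),
            all(t_start >= 0))
  structure(list(t_start = t_start, t_end = t_end, units = units,
                 amplitude = amplitude),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", length(x$t_start), "epochs\n")
  invisible(x)
}

#' Draw an initial network state
#'
#' Membrane potentials are drawn independently and uniformly on
#' \code{[V_R, V_th)} to avoid artificial start-up synchrony; synaptic
#' currents and refractory timers start at zero.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed, or \code{NULL} for an entropy-sourced draw.
#' @return List with elements \code{V} (mV, length N) and \code{seed}.
#' @export
initialize_state <- function(spec, seed = NULL) {
  V <- with_seed(seed, runif(spec$N, min = spec$V_R, max = spec$V_th))
  list(V = V, seed = seed)
}

#' Simulate a spiking network
#'
#' Time-steps the leaky integrate-and-fire network with exponential synaptic
#' currents using an exponential-Euler scheme (exact subthreshold solution
#' for piecewise-constant input). Spikes are detected as \code{V >= V_th}
#' after the subthreshold update, reset the potential to \code{V_R} for the
#' absolute refractory period, and are delivered to postsynaptic targets with
#' a one-step synaptic delay, incrementing the source-matched synaptic
#' current by the synaptic efficacy. Given a seed, the run is fully
#' deterministic: the only randomness is in the initial membrane potentials.
#'
#' @param conn a \code{connectivity} object (see [build_random_balanced()]).
#' @param duration simulated time (ms).
#' @param protocol optional [stim_protocol()].
#' @param seed integer seed for the initial state.
#' @param dt integration step (ms), default 0.1.
#' @param delay synaptic transmission delay (ms); rounded to a whole number
#'   of steps, minimum one step. Defaults to one step (\code{dt}).
#' @param probe_units optional integer vector of unit ids whose excitatory,
#'   inhibitory and total input currents and membrane potential are recorded
#'   at every step.
#' @param I_x optional per-unit external current (pA); defaults to
#'   [external_currents()] of the spec mapped by population.
#' @param V0 optional initial membrane potentials, overrides
#'   [initialize_state()].
#' @return A [spike_data()] object; if units were probed, its \code{probes}
#'   element holds matrices \code{I_E}, \code{I_I}, \code{I_tot}, \code{V}
#'   (one column per probed unit) and the sample times \code{time}.
#' @export
simulate_network <- function(conn, duration, protocol = NULL, seed = NULL,
                             dt = 0.1, probe_units = integer(0), I_x = NULL,
                             V0 = NULL, delay = dt) {
  stopifnot(dt > 0, duration > 0, delay > 0)
  spec <- conn$spec
  if (is.null(spec)) stop("connectivity object carries no network_spec")
  N <- spec$N
  stopifnot(nrow(conn$W) == N)
  if (is.null(I_x)) {
    ix <- external_currents(spec)
    I_x <- ifelse(conn$units$population == "E", ix[["E"]], ix[["I"]])
  }
  if (is.null(V0)) V0 <- initialize_state(spec, seed)$V
  n_steps <- as.integer(round(duration / dt))

  # stimulus epochs -> step-indexed amplitude switch events
  stim_step <- integer(0); stim_delta <- numeric(0); stim_targets <- list()
  if (!is.null(protocol) && length(protocol$t_start)) {
    on_step <- pmax(0L, as.integer(round(protocol$t_start / dt)))
    off_step <- pmax(0L, as.integer(round(protocol$t_end / dt)))
    keep_on <- on_step < n_steps
    keep_off <- off_step < n_steps
    stim_step <- c(on_step[keep_on], off_step[keep_off])
    stim_delta <- c(protocol$amplitude[keep_on], -protocol$amplitude[keep_off])
    stim_targets <- c(lapply(which(keep_on),
                             function(e) as.integer(protocol$units[[e]])),
                      lapply(which(keep_off),
                             function(e) as.integer(protocol$units[[e]])))
    o <- order(stim_step)
    stim_step <- stim_step[o]; stim_delta <- stim_delta[o]
    stim_targets <- stim_targets[o]
  }

  prm <- list(E_L = spec$E_L, V_th = spec$V_th, V_R = spec$V_R,
              C_m = spec$C_m,
              tau_m_E = spec$tau_m[["E"]], tau_m_I = spec$tau_m[["I"]],
              tau_syn_E = spec$tau_syn[["E"]], tau_syn_I = spec$tau_syn[["I"]],
              tau_r = spec$tau_r)
  res <- sim_lif_cpp(conn$W, conn$units$population == "E", prm,
                     as.numeric(I_x), as.numeric(V0),
                     stim_step, stim_targets, stim_delta,
                     as.integer(probe_units), n_steps, dt,
                     max(1L, as.integer(round(delay / dt))))

  probes <- NULL
  if (length(probe_units)) {
    probes <- list(time = seq_len(n_steps) * dt,
                   units = probe_units,
                   I_E = res$probe_I_E, I_I = res$probe_I_I,
                   I_tot = res$probe_I_tot, V = res$probe_V)
  }
  spike_data(time = res$time, unit = res$unit, units = conn$units,
             duration = duration,
             meta = list(seed = seed, dt = dt, delay = delay,
                         topology = conn$kind, build_seed = conn$seed),
             probes = probes)
}

#' Record synaptic input currents of selected units
#'
#' Convenience wrapper around [simulate_network()] with probes: returns the
#' time-resolved excitatory input, inhibitory input, net input (including the
#' constant external and any stimulus current) and membrane potential of the
#' probed units.
#'
#' @inheritParams simulate_network
#' @return The \code{probes} element of the simulation result (list with
#'   \code{time}, \code{units}, \code{I_E}, \code{I_I}, \code{I_tot},
#'   \code{V}); the full [spike_data()] is attached as attribute
#'   \code{"spikes"}.
#' @export
record_currents <- function(conn, duration, probe_units, protocol = NULL,
                            seed = NULL, dt = 0.1) {
  stopifnot(length(probe_units) >= 1,
            all(probe_units >= 1), all(probe_units <= conn$spec$N))
  sd <- simulate_network(conn, duration, protocol = protocol, seed = seed,
                         dt = dt, probe_units = probe_units)
  out <- sd$probes
  sd$probes <- NULL
  attr(out, "spikes") <- sd
  out
}
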