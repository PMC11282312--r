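#' Metastability scan over cluster strength and cluster number
#'
#' For each grid point, builds fresh network realizations, simulates
#' spontaneous activity, cuts it into consecutive trials and computes the
#' trial-averaged Fano factor of the excitatory units (mean across units,
#' then across realizations). A high FF (> 1) indicates metastable switching
#' of cluster states; FF below 1 indicates either the asynchronous-irregular
#' baseline or a frozen winner-takes-all state.
#'
#' @param spec a [network_spec()] (its \code{Q}/\code{J_Eplus} are overridden
#'   by the grids).
#' @param J_Eplus_grid excitatory cluster strengths to scan.
#' @param Q_grid cluster numbers to scan (default: the spec's Q).
#' @param topology one of \code{"EI"}, \code{"E"}, \code{"E+I"}.
#' @param n_realizations independent network realizations per grid point.
#' @param n_trials,trial_ms trials per realization and trial duration (ms).
#' @param transient_ms discarded start-up interval (ms); the default of 2 s
#'   lets the network settle into its stationary regime (in particular the
#'   frozen winner-takes-all states of strongly E-clustered networks) before
#'   trials are cut.
#' @param seed base seed; realization r at grid point k uses
#'   \code{seed + 1000 * k + r}.
#' @param dt integration step (ms).
#' @return Data frame with columns \code{J_Eplus}, \code{Q},
#'   \code{topology}, \code{FF} (grand mean), \code{FF_sd} (across
#'   realizations), \code{n_realizations}.
#' @export
scan_cluster_strength <- function(spec, J_Eplus_grid, Q_grid = spec$Q,
                                  topology = c("EI", "E", "E+I"),
                                  n_realizations = 5, n_trials = 20,
                                  trial_ms = 400, transient_ms = 2000,
                                  seed = 1, dt = 0.1) {
  topology <- match.arg(topology)
  grid <- expand.grid(J_Eplus = J_Eplus_grid, Q = Q_grid)
  duration <- transient_ms + n_trials * trial_ms
  trials <- data.frame(trial = seq_len(n_trials),
                       TS = transient_ms + (seq_len(n_trials) - 1) * trial_ms)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    sp_k <- spec
    sp_k$Q <- grid$Q[k]; sp_k$J_Eplus <- grid$J_Eplus[k]
    ffs <- vapply(seq_len(n_realizations), function(r) {
      s <- seed + 1000L * k + r
      conn <- switch(topology,
                     EI = build_ei_clustered(sp_k, seed = s),
                     E = build_e_clustered(sp_k, seed = s),
                     `E+I` = build_e_plus_i_variant(sp_k, seed = s))
      sd <- simulate_network(conn, duration, seed = s + 1L, dt = dt)
      eu <- conn$units$unit[conn$units$population == "E"]
      al <- align_trials(sd, trials, window = c(0, trial_ms))
      cm <- count_matrix(al, units = eu)
      ff <- apply(cm, 1, fano_factor)
      mean(ff, na.rm = TRUE)
    }, numeric(1))
    data.frame(J_Eplus = grid$J_Eplus[k], Q = grid$Q[k], topology = topology,
               FF = mean(ffs), FF_sd = stats::sd(ffs),
               n_realizations = n_realizations)
  })
  do.call(rbind, out)
}

#' Stimulus-response scan
#'
#' Stimulates a subset of clusters with a constant current over repeated
#' trials and computes the per-neuron change in firing rate and Fano factor
#' between matched spontaneous and evoked epochs ([delta_stats()]), as a
#' function of stimulus amplitude. The current is injected into every neuron
#' belonging to a stimulated cluster: in the E/I-clustered topology that is
#' the excitatory cluster and its paired inhibitory pool, while in the
#' E-clustered topology inhibitory neurons belong to no cluster and the
#' stimulus reaches only excitatory units.
#'
#' @param spec a [network_spec()] with the desired \code{Q} and
#'   \code{J_Eplus}.
#' @param amplitudes stimulus amplitudes to scan (pA).
#' @param topology \code{"EI"}, \code{"E"} or \code{"E+I"}.
#' @param stim_clusters cluster indices stimulated (default the first 5).
#' @param n_trials trials per amplitude.
#' @param spont_ms,evoked_ms epoch durations (ms), default 1000 each.
#' @param gap_ms relaxation gap between trials (ms).
#' @param seed,dt as in [scan_cluster_strength()].
#' @return Data frame: one row per (amplitude, group) with \code{d_rate},
#'   \code{d_rate_se}, \code{d_ff}, \code{d_ff_se}.
#' @export
scan_stimulus_response <- function(spec, amplitudes, topology = c("EI", "E"),
                                   stim_clusters = 0:4, n_trials = 20,
                                   spont_ms = 1000, evoked_ms = 1000,
                                   gap_ms = 500, seed = 1, dt = 0.1) {
  topology <- match.arg(topology)
  cycle <- spont_ms + evoked_ms + gap_ms
  duration <- n_trials * cycle + gap_ms
  out <- lapply(seq_along(amplitudes), function(a) {
    s <- seed + a
    conn <- switch(topology,
                   EI = build_ei_clustered(spec, seed = s),
                   E = build_e_clustered(spec, seed = s))
    targets <- conn$units$unit[!is.na(conn$units$cluster) &
                                 conn$units$cluster %in% stim_clusters]
    starts <- gap_ms + (seq_len(n_trials) - 1) * cycle
    prot <- if (amplitudes[a] > 0)
      stim_protocol(t_start = starts + spont_ms,
                    t_end = starts + spont_ms + evoked_ms,
                    units = rep(list(targets), n_trials),
                    amplitude = rep(amplitudes[a], n_trials))
    else NULL
    sd <- simulate_network(conn, duration, protocol = prot, seed = s + 1L,
                           dt = dt)
    trials <- data.frame(trial = seq_len(n_trials), TS = starts)
    spont <- align_trials(sd, trials, window = c(0, spont_ms))
    evoked <- align_trials(sd, trials, window = c(spont_ms,
                                                  spont_ms + evoked_ms))
    ds <- delta_stats(spont, evoked, conn$units, stim_clusters)
    cbind(amplitude = amplitudes[a], topology = topology, ds)
  })
  do.call(rbind, out)
}

#' Write a run manifest
#'
#' Records the parameters, seeds and package version of an experiment run
#' next to its outputs, for provenance.
#'
#' @param path output file (YAML).
#' @param ... named parameters to record.
#' @export
write_manifest <- function(path, ...) {
  yaml::write_yaml(list(package = "eiclust",
                        version = as.character(utils::packageVersion("eiclust")),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                        parameters = list(...)),
                   path)
  invisible(path)
}
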