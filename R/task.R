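#' Delayed center-out task protocol
#'
#' Generates the trial structure of the delayed center-out reach task with
#' graded prior target information. Each 2 s trial starts at TS; the
#' preparatory signal (PS) comes 500 ms later and cues one, two or three of
#' the six target directions (Conditions 1-3); after a fixed 1000 ms delay
#' the response signal (RS) indicates the final target (drawn uniformly from
#' the cued set) for 400 ms. Trials are concatenated on a continuous timeline
#' with an inter-trial interval drawn uniformly from 1.5-1.7 s; conditions
#' run in blocks. The cue sets are restricted so that every condition has six
#' equally frequent trial types: single targets 1-6 (Condition 1), the pairs
#' 1-2, 3-4, 5-6 (Condition 2) and the triples 6-1-2, 3-4-5 (Condition 3).
#'
#' During the PS epoch all excitatory units of every cued cluster receive the
#' stimulus amplitude; during the RS epoch only the final cluster does.
#'
#' @param conditions subset of 1:3.
#' @param trials_per_condition trials per condition block (150 in the full
#'   protocol).
#' @param interleave if \code{TRUE}, trials of the different conditions are
#'   randomly interleaved on the timeline instead of run in blocks. Blocks
#'   match the experimental sessions; interleaving removes the confound of
#'   slow network-state drift when comparing conditions at small trial
#'   counts.
#' @param amplitude stimulus amplitude (pA), >= 0.
#' @param seed integer seed for cue/target draws and inter-trial intervals.
#' @param Q number of direction clusters (6).
#' @param t_first_TS start of the first trial (ms).
#' @param iti_range inter-trial interval range (ms).
#' @return Object of class \code{task_protocol}: list with the trial table
#'   \code{trials} (columns \code{trial}, \code{condition}, \code{cued},
#'   \code{final}, \code{TS}, \code{PS}, \code{RS}, \code{RS_end}), the
#'   cluster-level stimulation table \code{epochs}, \code{amplitude} and
#'   \code{Q}. Directions are numbered 1..Q and direction d maps to cluster
#'   d - 1.
#' @export
make_task_protocol <- function(conditions = 1:3, trials_per_condition = 150,
                               amplitude = 0.1, seed = NULL, Q = 6,
                               t_first_TS = 500,
                               iti_range = c(1500, 1700),
                               interleave = FALSE) {
  stopifnot(all(conditions %in% 1:3), trials_per_condition >= 1,
            amplitude >= 0, Q == 6)
  cue_sets <- list(`1` = as.list(1:6),
                   `2` = list(c(1, 2), c(3, 4), c(5, 6)),
                   `3` = list(c(6, 1, 2), c(3, 4, 5)))
  with_seed(seed, {
    cond_seq <- rep(conditions, each = trials_per_condition)
    if (interleave) cond_seq <- sample(cond_seq)
    pick <- lapply(conditions, function(cond)
      sample(rep(seq_along(cue_sets[[as.character(cond)]]),
                 length.out = trials_per_condition)))
    names(pick) <- as.character(conditions)
    used <- stats::setNames(rep(0L, length(conditions)),
                            as.character(conditions))
    rows <- list()
    t_now <- t_first_TS
    for (k in seq_along(cond_seq)) {
      cond <- cond_seq[k]
      used[as.character(cond)] <- used[as.character(cond)] + 1L
      cued <- cue_sets[[as.character(cond)]][[
        pick[[as.character(cond)]][used[as.character(cond)]]]]
      final <- if (length(cued) == 1) cued else sample(cued, 1)
      TS <- t_now
      rows[[k]] <- data.frame(
        trial = k, condition = cond,
        cued = paste(cued, collapse = ","), final = final,
        TS = TS, PS = TS + 500, RS = TS + 1500, RS_end = TS + 1900)
      t_now <- TS + 2000 + runif(1, iti_range[1], iti_range[2])
    }
    trials <- do.call(rbind, rows)
  })
  ep <- rbind(
    data.frame(t_start = trials$PS, t_end = trials$RS,
               clusters = trials$cued, amplitude = amplitude),
    data.frame(t_start = trials$RS, t_end = trials$RS_end,
               clusters = as.character(trials$final), amplitude = amplitude))
  ep <- ep[order(ep$t_start), ]
  structure(list(trials = trials, epochs = ep, amplitude = amplitude, Q = Q,
                 seed = seed),
            class = "task_protocol")
}

#' @export
print.task_protocol <- function(x, ...) {
  cat("<task_protocol>", nrow(x$trials), "trials, conditions",
      paste(sort(unique(x$trials$condition)), collapse = "/"),
      ", amplitude", x$amplitude, "pA\n")
  invisible(x)
}

parse_cued <- function(s) lapply(strsplit(s, ","), as.integer)

#' Run the task simulation
#'
#' Builds the E/I-clustered task network and simulates the full continuous
#' task timeline of a [make_task_protocol()], mapping each cued direction d
#' to the excitatory units of cluster d - 1.
#'
#' @param spec a [network_spec()]; default [task_network_spec()].
#' @param protocol a \code{task_protocol}.
#' @param seed integer seed (network realization uses \code{seed}, initial
#'   state \code{seed + 1}).
#' @param dt integration step (ms).
#' @return List with elements \code{spikes} ([spike_data()]), \code{trials}
#'   (trial table) and \code{conn} (the network).
#' @export
run_task <- function(spec = task_network_spec(), protocol, seed = NULL,
                     dt = 0.1) {
  stopifnot(inherits(protocol, "task_protocol"), spec$Q == protocol$Q)
  conn <- build_ei_clustered(spec, seed = seed)
  e_units <- split(conn$units$unit[conn$units$population == "E"],
                   conn$units$cluster[conn$units$population == "E"])
  cl_sets <- parse_cued(protocol$epochs$clusters)
  units <- lapply(cl_sets, function(ds)
    unlist(e_units[as.character(ds - 1L)], use.names = FALSE))
  sp <- stim_protocol(t_start = protocol$epochs$t_start,
                      t_end = protocol$epochs$t_end,
                      units = units,
                      amplitude = protocol$epochs$amplitude)
  duration <- max(protocol$trials$TS) + 2000 + 500
  sd <- simulate_network(conn, duration, protocol = sp,
                         seed = if (is.null(seed)) NULL else seed + 1L,
                         dt = dt)
  list(spikes = sd, trials = protocol$trials, conn = conn)
}

#' Per-cluster spike counts in time bins
#'
#' @param sd a [spike_data()] with cluster metadata.
#' @param from,to counting interval (ms).
#' @param bin bin width (ms), default 1.
#' @param population population whose spikes are counted, default \code{"E"}.
#' @return Matrix (bins x clusters) of population spike counts; attribute
#'   \code{"time"} holds the bin end times.
#' @export
cluster_counts <- function(sd, from, to, bin = 1, population = "E") {
  u <- sd$units
  sel_units <- u$unit[u$population == population & !is.na(u$cluster)]
  clusters <- sort(unique(u$cluster[u$unit %in% sel_units]))
  breaks <- seq(from, to, by = bin)
  n_bins <- length(breaks) - 1
  sp <- sd$spikes[sd$spikes$unit %in% sel_units &
                    sd$spikes$time > from & sd$spikes$time <= breaks[n_bins + 1], ]
  cl <- u$cluster[match(sp$unit, u$unit)]
  b <- pmin(pmax(findInterval(sp$time, breaks, left.open = TRUE), 1), n_bins)
  m <- table(factor(b, levels = seq_len(n_bins)),
             factor(cl, levels = clusters))
  m <- matrix(as.numeric(m), nrow = n_bins,
              dimnames = list(NULL, cluster = clusters))
  attr(m, "time") <- breaks[-1]
  m
}

#' Leaky integration of cluster spike counts
#'
#' Discrete-time solution of \eqn{dI_d/dt = -I_d/\tau_I + C_d(t)} with
#' \eqn{I_d(0) = 0}, where \eqn{C_d} is the per-bin population spike count of
#' cluster d: each bin the integrator decays by \eqn{e^{-\Delta/\tau_I}} and
#' the bin's count is added. Values are non-negative by construction.
#'
#' @param counts matrix of per-bin spike counts (bins x directions), e.g.
#'   from [cluster_counts()].
#' @param tau_I integration time constant (ms), default 50.
#' @param bin bin width (ms), default 1.
#' @return Matrix of integrator values, same shape as \code{counts}.
#' @export
leaky_integrate <- function(counts, tau_I = 50, bin = 1) {
  stopifnot(tau_I > 0, bin > 0)
  decay <- exp(-bin / tau_I)
  I <- matrix(0, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  prev <- rep(0, ncol(counts))
  for (k in seq_len(nrow(counts))) {
    prev <- prev * decay + counts[k, ]
    I[k, ] <- prev
  }
  attr(I, "time") <- attr(counts, "time")
  I
}

#' Decision variables from integrator traces
#'
#' Normalizes the leaky-integrator values across directions,
#' \eqn{DV_d = I_d / \sum_j I_j}, interpreted as the probability that
#' direction d is the correct movement target. Rows with an all-zero
#' denominator are set to the uniform value 1/Q.
#'
#' @param I matrix of integrator values (bins x directions).
#' @return Matrix of decision variables, each row summing to 1.
#' @export
decision_variable <- function(I) {
  tot <- rowSums(I)
  DV <- I / ifelse(tot == 0, 1, tot)
  DV[tot == 0, ] <- 1 / ncol(I)
  attr(DV, "time") <- attr(I, "time")
  DV
}

#' Threshold decision from decision-variable traces
#'
#' A decision is reached at the first crossing of the common threshold
#' \code{theta} within the 400 ms interval following the RS. If a decision
#' variable is already at or above threshold at the RS the decision counts as
#' anticipatory with reaction time 0. Crossings after the window mean an
#' unsuccessful trial. Ties at the same bin are broken toward the lower
#' direction index.
#'
#' @param DV decision-variable matrix with attribute \code{"time"} (ms on the
#'   same timeline as \code{rs_time}).
#' @param theta decision threshold in (0, 1).
#' @param rs_time RS onset (ms).
#' @param window decision window after RS (ms), default 400.
#' @param final the correct direction (1-based column index), or \code{NA}.
#' @return List: \code{chosen} (direction or \code{NA}), \code{rt} (ms from
#'   RS; 0 for anticipatory; \code{NA} if no decision), \code{success}.
#' @export
detect_decision <- function(DV, theta, rs_time, window = 400, final = NA) {
  stopifnot(theta > 0, theta < 1)
  tm <- attr(DV, "time")
  at_rs <- which(tm >= rs_time)[1]
  if (is.na(at_rs)) stop("DV trace does not cover the RS")
  in_win <- which(tm >= rs_time & tm <= rs_time + window)
  chosen <- NA_integer_; rt <- NA_real_
  if (any(DV[at_rs, ] >= theta)) {
    chosen <- which(DV[at_rs, ] >= theta)[1]
    rt <- 0
  } else {
    for (k in in_win) {
      hit <- which(DV[k, ] >= theta)
      if (length(hit)) { chosen <- hit[1]; rt <- tm[k] - rs_time; break }
    }
  }
  list(chosen = chosen, rt = rt,
       success = !is.na(chosen) && !is.na(final) && chosen == final)
}

# DV traces for every trial of a task run: integration starts at PS onset so
# that anticipatory threshold crossings at RS are possible.
task_dv_traces <- function(task, tau_I = 50, bin = 1,
                           integrate_from = c("PS", "RS")) {
  integrate_from <- match.arg(integrate_from)
  lapply(seq_len(nrow(task$trials)), function(k) {
    tr <- task$trials[k, ]
    t0 <- if (integrate_from == "PS") tr$PS else tr$RS
    cc <- cluster_counts(task$spikes, from = t0, to = tr$RS_end, bin = bin)
    decision_variable(leaky_integrate(cc, tau_I = tau_I, bin = bin))
  })
}

#' Decision outcomes for all trials of a task run
#'
#' Applies the leaky-integrator decoder ([leaky_integrate()],
#' [decision_variable()], [detect_decision()]) to every trial. Integration
#' starts at PS onset; threshold crossings are evaluated from the RS.
#'
#' @param task result of [run_task()].
#' @param theta decision threshold.
#' @param tau_I integrator time constant (ms).
#' @param bin spike-count bin (ms).
#' @param window decision window after RS (ms).
#' @param dv optional precomputed DV traces (from repeated calls while
#'   tuning).
#' @return Data frame with one row per trial: \code{trial},
#'   \code{condition}, \code{final}, \code{chosen}, \code{rt},
#'   \code{success}.
#' @export
task_decisions <- function(task, theta, tau_I = 50, bin = 1, window = 400,
                           dv = NULL) {
  if (is.null(dv)) dv <- task_dv_traces(task, tau_I = tau_I, bin = bin)
  rows <- lapply(seq_len(nrow(task$trials)), function(k) {
    tr <- task$trials[k, ]
    d <- detect_decision(dv[[k]], theta, rs_time = tr$RS, window = window,
                         final = tr$final)
    data.frame(trial = tr$trial, condition = tr$condition, final = tr$final,
               chosen = if (is.na(d$chosen)) NA_integer_ else d$chosen,
               rt = d$rt, success = d$success)
  })
  do.call(rbind, rows)
}

#' Tune the decision threshold
#'
#' Scans a grid of thresholds and returns the one maximizing mean decision
#' accuracy (fraction of successful trials) pooled across all trials.
#'
#' @param task result of [run_task()].
#' @param theta_grid candidate thresholds, default 0.50-0.99 in steps of 0.01.
#' @inheritParams task_decisions
#' @return List with \code{theta} (the argmax; ties go to the lower value),
#'   \code{accuracy}, and \code{grid} (data frame theta x accuracy).
#' @export
tune_threshold <- function(task, theta_grid = seq(0.5, 0.99, by = 0.01),
                           tau_I = 50, bin = 1, window = 400) {
  if (!length(theta_grid)) stop("empty threshold grid")
  dv <- task_dv_traces(task, tau_I = tau_I, bin = bin)
  acc <- vapply(theta_grid, function(th)
    mean(task_decisions(task, th, window = window, dv = dv)$success),
    numeric(1))
  best <- which.max(acc)
  list(theta = theta_grid[best], accuracy = acc[best],
       grid = data.frame(theta = theta_grid, accuracy = acc))
}

#' Time-resolved decoding of movement direction
#'
#' Trains a multinomial (logistic) linear classifier on per-trial spike-count
#' vectors in a sliding window and reports the cross-validated decoding
#' accuracy: the fraction of correctly predicted movement directions,
#' averaged over the directions and over the folds. Accuracy is computed
#' separately per task condition.
#'
#' @param aligned a [trial_aligned()] whose trial table has \code{condition}
#'   and \code{final} columns.
#' @param window sliding window width (ms), default 400.
#' @param step window step (ms), default 100.
#' @param units optional subset of unit ids used as features (default: all
#'   excitatory units if metadata is present, else all units).
#' @param n_folds cross-validation folds, default 5; classes with fewer
#'   trials than folds reduce the fold count with a warning.
#' @param lambda ridge penalty of the classifier (fixed small default; the
#'   plateau levels of the accuracy are insensitive to it).
#' @param seed seed for the fold assignment.
#' @return Data frame with columns \code{condition}, \code{t_center},
#'   \code{accuracy}.
#' @export
decoding_accuracy <- function(aligned, window = 400, step = 100,
                              units = NULL, n_folds = 5, lambda = 0.05,
                              seed = 1) {
  tr <- aligned$trials
  stopifnot(all(c("condition", "final") %in% names(tr)))
  if (is.null(units)) {
    units <- if (!is.null(aligned$units) &&
                 "population" %in% names(aligned$units))
      aligned$units$unit[aligned$units$population == "E"]
    else if (!is.null(aligned$units)) aligned$units$unit
    else sort(unique(aligned$spikes$unit))
  }
  span <- aligned$window
  centers <- seq(span[1] + window / 2, span[2] - window / 2, by = step)
  out <- list()
  for (cond in sort(unique(tr$condition))) {
    t_sub <- tr[tr$condition == cond, ]
    y_all <- factor(t_sub$final)
    min_class <- min(table(y_all))
    if (min_class < 2) stop("need at least 2 trials per direction")
    k_folds <- min(n_folds, min_class)
    if (k_folds < n_folds)
      warning("condition ", cond, ": classes with < ", n_folds,
              " trials, using ", k_folds, " folds")
    folds <- with_seed(seed + cond, {
      f <- integer(nrow(t_sub))
      for (lv in levels(y_all)) {
        idx <- sample(which(y_all == lv))
        f[idx] <- rep_len(seq_len(k_folds), length(idx))
      }
      f
    })
    sub <- aligned
    sub$spikes <- sub$spikes[sub$spikes$trial %in% t_sub$trial, ]
    sub$trials <- t_sub
    for (tc in centers) {
      cm <- count_matrix(sub, from = tc - window / 2, to = tc + window / 2,
                         units = units)
      X <- t(cm)                      # trials x units
      acc_folds <- vapply(seq_len(k_folds), function(f) {
        tr_idx <- which(folds != f); te_idx <- which(folds == f)
        if (length(unique(y_all[tr_idx])) < 2) return(NA_real_)
        fit <- withCallingHandlers(
          glmnet::glmnet(X[tr_idx, , drop = FALSE], y_all[tr_idx],
                         family = "multinomial", alpha = 0,
                         lambda = lambda),
          # small-class advisory is expected at scaled trial counts
          warning = function(w) {
            if (grepl("fewer than 8", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        pred <- predict(fit, X[te_idx, , drop = FALSE], s = lambda,
                        type = "class")
        pred <- factor(as.vector(pred), levels = levels(y_all))
        truth <- y_all[te_idx]
        per_dir <- vapply(levels(y_all), function(lv) {
          sel <- truth == lv
          if (!any(sel)) return(NA_real_)
          mean(pred[sel] == lv)
        }, numeric(1))
        mean(per_dir, na.rm = TRUE)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(condition = cond, t_center = tc,
                                           accuracy = mean(acc_folds,
                                                           na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
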