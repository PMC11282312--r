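#' Fano factor of spike counts
#'
#' Dispersion of spike counts across repeated trials,
#' \eqn{FF = \sigma_c^2 / \mu_c}, using the unbiased (n-1) variance
#' estimator. Undefined (returns \code{NA}) when the mean count is zero.
#'
#' @param counts integer vector of per-trial spike counts (>= 2 trials).
#' @return The Fano factor, or \code{NA_real_} for all-zero counts.
#' @examples
#' fano_factor(c(2, 2, 2, 2))  # 0
#' fano_factor(c(0, 4))        # 4
#' @export
fano_factor <- function(counts) {
  if (length(counts) < 2) stop("Fano factor needs at least 2 trials")
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Coefficient of variation of inter-spike intervals
#'
#' \eqn{CV = \sigma_{ISI} / \mu_{ISI}} over the supplied intervals.
#'
#' @param isis inter-spike intervals (ms), at least 2.
#' @return The CV.
#' @export
cv_isi <- function(isis) {
  if (length(isis) < 2) stop("CV needs at least 2 intervals")
  stats::sd(isis) / mean(isis)
}

#' Local coefficient of variation (CV2)
#'
#' Computed over all pairs of consecutive inter-spike intervals:
#' \eqn{CV_2 = 2 \langle |\tau - \tau'| / (\tau + \tau') \rangle}. Being a
#' local measure it is largely insensitive to slow firing-rate modulations
#' and to right-censoring by finite observation windows.
#'
#' @param isis consecutive inter-spike intervals of one spike train (ms);
#'   at least 2 (i.e. at least 3 spikes).
#' @return The CV2, or \code{NA_real_} when fewer than 2 intervals are given.
#' @examples
#' cv2(rep(10, 5))       # 0
#' cv2(rep(c(1, 2), 5))  # 2/3
#' @export
cv2 <- function(isis) {
  n <- length(isis)
  if (n < 2) return(NA_real_)
  a <- isis[-n]; b <- isis[-1]
  2 * mean(abs(a - b) / (a + b))
}

# ISIs of one (unit, trial) spike train restricted to a window
isis_in_window <- function(times, from, to) {
  t <- sort(times[times >= from & times <= to])
  if (length(t) < 2) return(numeric(0))
  diff(t)
}

#' Time-resolved variability statistics
#'
#' Slides a centered window over trial-aligned spike data and computes, per
#' window, the across-trial Fano factor per unit averaged across units
#' (\code{"FF"}), the within-trial CV2 averaged over trials then units
#' (\code{"CV2"}), or the mean firing rate (\code{"rate"}, spikes/s per
#' unit). Units (and, for CV2, trials) that do not admit the statistic in a
#' window are excluded from the average, not zero-filled.
#'
#' @param aligned a [trial_aligned()] object.
#' @param statistic one of \code{"FF"}, \code{"CV2"}, \code{"rate"}.
#' @param window sliding window width (ms), default 400.
#' @param step window-center step (ms), default 25.
#' @param units optional subset of unit ids.
#' @param groups optional factor (one value per row of
#'   \code{aligned$trials}) grouping trials with an identical stimulus
#'   sequence; the across-trial FF is then computed per (unit, group) sample
#'   before averaging, as required when trials of different cued directions
#'   are pooled.
#' @return Data frame of class \code{variability_trace} with columns
#'   \code{t_center}, \code{statistic}, \code{value}, \code{n} (number of
#'   contributing samples); attribute \code{"window"} records the width.
#' @export
time_resolved <- function(aligned, statistic = c("FF", "CV2", "rate"),
                          window = 400, step = 25, units = NULL,
                          groups = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(groups))
    stopifnot(length(groups) == nrow(aligned$trials))
  span <- aligned$window
  stopifnot(window <= diff(span))
  if (is.null(units))
    units <- if (!is.null(aligned$units)) aligned$units$unit
             else sort(unique(aligned$spikes$unit))
  centers <- seq(span[1] + window / 2, span[2] - window / 2, by = step)
  trials <- aligned$trials$trial
  sp <- aligned$spikes[aligned$spikes$unit %in% units, ]
  by_ut <- split(sp$time, list(unit = sp$unit, trial = sp$trial), drop = FALSE)

  out <- lapply(centers, function(tc) {
    lo <- tc - window / 2; hi <- tc + window / 2
    if (statistic == "FF") {
      cm <- count_matrix(aligned, from = lo, to = hi, units = units)
      if (is.null(groups)) {
        ff <- apply(cm, 1, fano_factor)
      } else {
        ff <- unlist(lapply(split(seq_along(groups), groups), function(ix) {
          if (length(ix) < 2) return(NULL)
          apply(cm[, ix, drop = FALSE], 1, fano_factor)
        }))
      }
      ff <- ff[!is.na(ff)]
      data.frame(t_center = tc, statistic = "FF",
                 value = if (length(ff)) mean(ff) else NA_real_,
                 n = length(ff))
    } else if (statistic == "rate") {
      n_sp <- sum(sp$time > lo & sp$time <= hi)
      data.frame(t_center = tc, statistic = "rate",
                 value = 1000 * n_sp / window / length(trials) / length(units),
                 n = length(units) * length(trials))
    } else {
      per_unit <- vapply(as.character(units), function(u) {
        vals <- vapply(as.character(trials), function(tr) {
          key <- paste(u, tr, sep = ".")
          ts <- by_ut[[key]]
          if (is.null(ts)) return(NA_real_)
          cv2(isis_in_window(ts, lo, hi))
        }, numeric(1))
        vals <- vals[!is.na(vals)]
        if (length(vals)) mean(vals) else NA_real_
      }, numeric(1))
      per_unit <- per_unit[!is.na(per_unit)]
      data.frame(t_center = tc, statistic = "CV2",
                 value = if (length(per_unit)) mean(per_unit) else NA_real_,
                 n = length(per_unit))
    }
  })
  res <- do.call(rbind, out)
  attr(res, "window") <- window
  class(res) <- c("variability_trace", class(res))
  res
}

#' Spike-count synchrony
#'
#' Population synchrony measure
#' \eqn{\chi = \sqrt{\sigma^2_{pop} / \langle \sigma_i^2 \rangle}}, where
#' \eqn{\sigma^2_{pop}} is the variance of the population-averaged count
#' trace and \eqn{\langle \sigma_i^2 \rangle} the mean of the per-unit count
#' variances. Counts are measured in bins of \code{bin} ms. The measure is 1
#' for fully synchronized activity and of order \eqn{1/\sqrt{N}} for
#' asynchronous activity in a network of N units.
#'
#' @param sd a [spike_data()] object.
#' @param bin count bin width (ms), default 20.
#' @param units optional subset of unit ids (default all units).
#' @param from,to analysis window (ms).
#' @return The synchrony value, or \code{NA_real_} for all-silent input.
#' @export
synchrony_chi <- function(sd, bin = 20, units = NULL, from = 0,
                          to = sd$duration) {
  if (is.null(units)) units <- sd$units$unit
  stopifnot(length(units) >= 2)
  breaks <- seq(from, to, by = bin)
  if (length(breaks) < 3) stop("need at least 2 bins")
  sp <- sd$spikes[sd$spikes$unit %in% units & sd$spikes$time > from &
                    sd$spikes$time <= breaks[length(breaks)], ]
  if (nrow(sp) == 0) return(NA_real_)
  bin_idx <- findInterval(sp$time, breaks, left.open = TRUE,
                          rightmost.closed = TRUE)
  n_bins <- length(breaks) - 1
  cm <- table(factor(sp$unit, levels = units),
              factor(pmin(bin_idx, n_bins), levels = seq_len(n_bins)))
  cm <- matrix(as.numeric(cm), nrow = length(units))
  var_i <- apply(cm, 1, stats::var)
  denom <- mean(var_i)
  if (denom == 0) return(NA_real_)
  sqrt(stats::var(colMeans(cm)) / denom)
}

#' Triangular-kernel firing rate estimate
#'
#' Convolves a spike train with a unit-area symmetric triangular kernel of
#' the given total base width, yielding an instantaneous rate in spikes/s.
#'
#' @param times spike times (ms) of one spike train (or the pooled train of a
#'   population; divide by the number of units for the per-neuron rate).
#' @param width total base width of the triangular kernel (ms), default 50.
#' @param duration extent of the returned trace (ms).
#' @param dt sampling interval of the trace (ms), default 1.
#' @return Data frame with columns \code{time} (ms) and \code{rate}
#'   (spikes/s).
#' @export
rate_kernel <- function(times, width = 50, duration, dt = 1) {
  stopifnot(width > 0, duration > 0)
  grid <- seq(0, duration, by = dt)
  n <- length(grid)
  counts <- numeric(n)
  idx <- round(times / dt) + 1
  idx <- idx[idx >= 1 & idx <= n]
  for (i in idx) counts[i] <- counts[i] + 1
  half <- width / 2
  k_t <- seq(-half, half, by = dt)
  kern <- (1 - abs(k_t) / half)
  kern <- kern / (sum(kern) * dt)            # unit area in ms^-1
  rate <- stats::convolve(counts, rev(kern), type = "open") * 1000
  offset <- (length(kern) - 1) / 2
  data.frame(time = grid, rate = rate[seq_len(n) + offset])
}

#' Stimulus-evoked changes in rate and Fano factor
#'
#' Compares matched spontaneous and evoked epochs of the same units: the
#' difference (evoked minus spontaneous) in firing rate and in across-trial
#' Fano factor is computed per neuron before averaging within the stimulated
#' and non-stimulated cluster groups. The evoked rate of stimulated clusters
#' is restricted to active periods: time bins in which the trial-averaged
#' cluster rate exceeds the median rate of the non-stimulated clusters.
#'
#' @param spont,evoked [trial_aligned()] objects over matched units and equal
#'   numbers of trials (typically 1000 ms epochs).
#' @param units unit metadata frame with columns \code{unit},
#'   \code{population}, \code{cluster}.
#' @param stim_clusters integer vector of stimulated cluster indices.
#' @param mask_bin bin width (ms) of the active-period mask, default 20.
#' @return Data frame with one row per group (\code{stimulated},
#'   \code{non_stimulated}): mean and standard error of the per-neuron
#'   \code{d_rate} (spikes/s) and \code{d_ff}.
#' @export
delta_stats <- function(spont, evoked, units, stim_clusters, mask_bin = 20) {
  eu <- units[units$population == "E" & !is.na(units$cluster), ]
  if (!setequal(spont$trials$trial, evoked$trials$trial) &&
      nrow(spont$trials) != nrow(evoked$trials))
    stop("spontaneous and evoked epochs must have matching trials")
  span_s <- spont$window; span_e <- evoked$window
  dur_s <- diff(span_s); dur_e <- diff(span_e)

  cm_s <- count_matrix(spont, units = eu$unit)
  cm_e <- count_matrix(evoked, units = eu$unit)
  ff_s <- apply(cm_s, 1, fano_factor)
  ff_e <- apply(cm_e, 1, fano_factor)
  rate_s <- rowMeans(cm_s) / dur_s * 1000
  stim <- eu$cluster %in% stim_clusters

  # active-period mask from trial-averaged cluster rate traces (evoked epoch)
  breaks <- seq(span_e[1], span_e[2], by = mask_bin)
  n_bins <- length(breaks) - 1
  sp <- evoked$spikes[evoked$spikes$unit %in% eu$unit, ]
  cl_of <- eu$cluster[match(sp$unit, eu$unit)]
  b_idx <- pmin(pmax(findInterval(sp$time, breaks, left.open = TRUE), 1),
                n_bins)
  n_trials <- nrow(evoked$trials)
  cl_levels <- sort(unique(eu$cluster))
  cl_size <- as.numeric(table(factor(eu$cluster, levels = cl_levels)))
  rate_tr <- table(factor(cl_of, levels = cl_levels),
                   factor(b_idx, levels = seq_len(n_bins)))
  rate_tr <- matrix(as.numeric(rate_tr), nrow = length(cl_levels)) /
    (cl_size * n_trials * mask_bin) * 1000   # spikes/s per neuron
  rownames(rate_tr) <- cl_levels
  nonstim_lv <- as.character(setdiff(cl_levels, stim_clusters))
  med_nonstim <- if (length(nonstim_lv)) median(rate_tr[nonstim_lv, ])
                 else 0

  # per-neuron evoked rate within its cluster's active periods
  rate_e <- numeric(nrow(eu))
  for (ci in seq_along(cl_levels)) {
    cl <- cl_levels[ci]
    members <- which(eu$cluster == cl)
    if (cl %in% stim_clusters) {
      active <- which(rate_tr[ci, ] > med_nonstim)
      if (!length(active)) active <- seq_len(n_bins)   # fallback: full epoch
      dur_active <- length(active) * mask_bin
      sel <- cl_of == cl & b_idx %in% active
      cnt <- table(factor(sp$unit[sel], levels = eu$unit[members]))
      rate_e[members] <- as.numeric(cnt) / (n_trials * dur_active) * 1000
    } else {
      rate_e[members] <- rowMeans(cm_e[members, , drop = FALSE]) / dur_e * 1000
    }
  }

  d_rate <- rate_e - rate_s
  d_ff <- ff_e - ff_s
  grp <- ifelse(stim, "stimulated", "non_stimulated")
  agg <- function(v, g) {
    v <- split(v, g)
    data.frame(group = names(v),
               mean = vapply(v, function(z) mean(z, na.rm = TRUE), 1),
               se = vapply(v, function(z) {
                 z <- z[!is.na(z)]
                 stats::sd(z) / sqrt(length(z))
               }, 1))
  }
  r <- agg(d_rate, grp); f <- agg(d_ff, grp)
  data.frame(group = r$group, d_rate = r$mean, d_rate_se = r$se,
             d_ff = f$mean[match(r$group, f$group)],
             d_ff_se = f$se[match(r$group, f$group)],
             row.names = NULL)
}

#' Renewal-theory consistency of interval statistics
#'
#' For a stationary point process the limiting Fano factor obeys
#' \eqn{FF = CV^2 (1 + 2\xi)} with \eqn{\xi = \sum_i \xi_i} the sum of serial
#' interval correlation coefficients. This estimates \eqn{CV^2} and
#' \eqn{\xi} (truncated at \code{max_lag}) and returns the predicted limiting
#' Fano factor. For a renewal process \eqn{\xi \approx 0} and
#' \eqn{FF \approx CV^2}.
#'
#' @param isis stationary inter-spike interval sequence (ms).
#' @param max_lag truncation lag of the correlation sum, default 10.
#' @return Named vector \code{c(cv_sq = , xi = , ff_pred = )}.
#' @export
renewal_consistency <- function(isis, max_lag = 10) {
  n <- length(isis)
  if (n < max_lag + 10) warning("short interval sequence: estimates unstable")
  cv_sq <- cv_isi(isis)^2
  xi <- sum(vapply(seq_len(max_lag), function(l) {
    if (n - l < 3) return(0)
    stats::cor(isis[seq_len(n - l)], isis[seq_len(n - l) + l])
  }, numeric(1)))
  c(cv_sq = cv_sq, xi = xi, ff_pred = cv_sq * (1 + 2 * xi))
}

#' Unit-inclusion filter for cross-condition comparisons
#'
#' Retains only (unit, cued-direction) combinations that meet, in every
#' condition, both a minimum mean spike count per trial within the reference
#' interval and a minimum number of trials.
#'
#' @param aligned a [trial_aligned()] whose trial table has columns
#'   \code{condition} and \code{final} (cued/executed direction).
#' @param min_spikes minimum mean spike count per trial in \code{interval}
#'   (default 10).
#' @param min_trials minimum number of trials per (condition, direction)
#'   (default 10).
#' @param interval reference counting interval (ms), default \code{c(0, 2000)}.
#' @return A filtered [trial_aligned()] containing only passing units, with
#'   attribute \code{"kept"} listing the retained (unit, direction) pairs.
#' @export
unit_inclusion_filter <- function(aligned, min_spikes = 10, min_trials = 10,
                                  interval = c(0, 2000)) {
  tr <- aligned$trials
  stopifnot(all(c("condition", "final") %in% names(tr)))
  units <- if (!is.null(aligned$units)) aligned$units$unit
           else sort(unique(aligned$spikes$unit))
  conds <- unique(tr$condition)
  dirs <- unique(tr$final)
  cm <- count_matrix(aligned, from = interval[1], to = interval[2],
                     units = units)
  kept <- list()
  for (u in seq_along(units)) {
    for (d in dirs) {
      ok <- TRUE
      for (cn in conds) {
        sel <- tr$condition == cn & tr$final == d
        if (sum(sel) < min_trials ||
            mean(cm[u, sel, drop = TRUE]) < min_spikes) { ok <- FALSE; break }
      }
      if (ok) kept[[length(kept) + 1]] <- data.frame(unit = units[u],
                                                     direction = d)
    }
  }
  kept <- if (length(kept)) do.call(rbind, kept)
          else data.frame(unit = integer(0), direction = integer(0))
  keep_units <- unique(kept$unit)
  sp <- aligned$spikes[aligned$spikes$unit %in% keep_units, ]
  out <- trial_aligned(sp$time, sp$unit, sp$trial, trials = tr,
                       window = aligned$window,
                       units = if (!is.null(aligned$units))
                         aligned$units[aligned$units$unit %in% keep_units, ]
                       else NULL,
                       align = aligned$align)
  attr(out, "kept") <- kept
  out
}
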