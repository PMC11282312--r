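#' Synthetic spike-train generators
#'
#' Seeded generators of trial-structured spike trains for testing the
#' statistics pipeline independently of the network simulator:
#' \describe{
#'   \item{\code{gen_poisson}}{homogeneous Poisson process (reference with
#'     FF = CV2 = 1).}
#'   \item{\code{gen_gamma}}{equilibrium gamma-renewal process with shape
#'     \code{k} (CV^2 = 1/k; limiting FF = 1/k).}
#'   \item{\code{gen_switching}}{Poisson process modulated by a two-state
#'     Markov telegraph rate, emulating metastable cluster activity
#'     (FF > 1 across trials while CV2 stays near 1).}
#' }
#' Each (unit, trial) train is drawn independently.
#'
#' @param rate firing rate (spikes/s); for \code{gen_switching},
#'   \code{rate_low}/\code{rate_high} are the two state rates.
#' @param duration trial duration (ms).
#' @param n_trials,n_units numbers of trials and units.
#' @param seed integer seed (RNG state of the caller is preserved).
#' @param shape gamma shape parameter k (> 0).
#' @param switch_rate rate of leaving either state (1/s); a length-2 vector
#'   gives the low-to-high and high-to-low rates separately.
#' @return A [trial_aligned()] object with window \code{c(0, duration)}.
#' @examples
#' fx <- gen_gamma(rate = 20, shape = 4, duration = 2000, n_trials = 20,
#'                 seed = 1)
#' @export
gen_poisson <- function(rate, duration, n_trials = 1, n_units = 1,
                        seed = NULL) {
  stopifnot(rate > 0, duration > 0)
  with_seed(seed, {
    gen_trains(n_units, n_trials, duration, function() {
      mean_isi <- 1000 / rate
      t <- cumsum(rexp(ceiling(duration / mean_isi * 1.5) + 20,
                       rate = 1 / mean_isi))
      while (length(t) && t[length(t)] < duration)
        t <- c(t, t[length(t)] +
                 cumsum(rexp(20, rate = 1 / mean_isi)))
      t[t <= duration]
    })
  })
}

#' @rdname gen_poisson
#' @export
gen_gamma <- function(rate, shape, duration, n_trials = 1, n_units = 1,
                      seed = NULL) {
  stopifnot(rate > 0, shape > 0, duration > 0)
  mean_isi <- 1000 / rate
  scale <- mean_isi / shape
  burn <- 20 * mean_isi             # start in the far past -> equilibrium
  with_seed(seed, {
    gen_trains(n_units, n_trials, duration, function() {
      total <- burn + duration
      n_guess <- ceiling(total / mean_isi * 1.5) + 20
      t <- cumsum(rgamma(n_guess, shape = shape, scale = scale))
      while (length(t) && t[length(t)] < total)
        t <- c(t, t[length(t)] +
                 cumsum(rgamma(20, shape = shape, scale = scale)))
      t <- t - burn
      t[t > 0 & t <= duration]
    })
  })
}

#' @rdname gen_poisson
#' @export
gen_switching <- function(rate_low, rate_high, switch_rate, duration,
                          n_trials = 1, n_units = 1, seed = NULL) {
  stopifnot(rate_low > 0, rate_high > 0, all(switch_rate > 0), duration > 0)
  if (length(switch_rate) == 1) switch_rate <- rep(switch_rate, 2)
  r_max <- max(rate_low, rate_high)
  with_seed(seed, {
    gen_trains(n_units, n_trials, duration, function() {
      # telegraph state trajectory (state 1 = low, 2 = high), random start
      # from the stationary occupancy
      occ_high <- switch_rate[1] / sum(switch_rate)
      state <- if (runif(1) < occ_high) 2L else 1L
      t_sw <- 0
      sw_times <- numeric(0); sw_states <- integer(0)
      while (t_sw < duration) {
        sw_times <- c(sw_times, t_sw); sw_states <- c(sw_states, state)
        dwell <- rexp(1, rate = switch_rate[state] / 1000)  # ms
        t_sw <- t_sw + dwell
        state <- 3L - state
      }
      # thinned homogeneous Poisson at the envelope rate
      cand <- cumsum(rexp(ceiling(duration / 1000 * r_max * 1.5) + 20,
                          rate = r_max / 1000))
      while (length(cand) && cand[length(cand)] < duration)
        cand <- c(cand, cand[length(cand)] +
                    cumsum(rexp(20, rate = r_max / 1000)))
      cand <- cand[cand <= duration]
      st <- sw_states[findInterval(cand, sw_times)]
      r_at <- ifelse(st == 1L, rate_low, rate_high)
      cand[runif(length(cand)) < r_at / r_max]
    })
  })
}

# Shared assembly: draw one train per (unit, trial) with `draw()` and wrap
# as trial_aligned data.
gen_trains <- function(n_units, n_trials, duration, draw) {
  pieces <- vector("list", n_units * n_trials)
  k <- 0
  for (u in seq_len(n_units)) for (tr in seq_len(n_trials)) {
    t <- draw()
    k <- k + 1
    pieces[[k]] <- if (length(t))
      data.frame(time = t, unit = u, trial = tr) else NULL
  }
  all <- do.call(rbind, pieces)
  if (is.null(all)) all <- data.frame(time = numeric(0), unit = integer(0),
                                      trial = integer(0))
  trial_aligned(all$time, all$unit, all$trial,
                trials = data.frame(trial = seq_len(n_trials)),
                window = c(0, duration),
                units = data.frame(unit = seq_len(n_units)),
                align = "t0")
}
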