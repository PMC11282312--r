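# Variability statistics: FF, CV, CV2, sliding windows, synchrony, kernels,
# evoked deltas, renewal consistency, inclusion filter.

test_that("fano_factor handles the elementary cases", {
  expect_equal(fano_factor(c(2, 2, 2, 2)), 0)
  expect_equal(fano_factor(c(0, 4)), 4)     # unbiased (n-1) variance
  expect_true(is.na(fano_factor(c(0, 0, 0))))
  expect_error(fano_factor(3), "2 trials")

  # Poisson counts at large n: FF within 3 standard errors of 1
  n <- 4000
  counts <- local({ set.seed(42); stats::rpois(n, 12) })
  se <- sqrt(2 / n)   # SE of var/mean for Poisson, large n
  expect_lt(abs(fano_factor(counts) - 1), 3 * se)
})

test_that("cv_isi recovers the CV of known renewal processes", {
  expect_equal(cv_isi(rep(7, 10)), 0)
  set.seed(43)
  expect_equal(cv_isi(rexp(20000, 0.1)), 1, tolerance = 0.03)
  for (k in c(0.5, 2, 4)) {
    isis <- rgamma(20000, shape = k, scale = 10 / k)
    expect_equal(cv_isi(isis), 1 / sqrt(k), tolerance = 0.03)
  }
  expect_error(cv_isi(numeric(0)))
})

test_that("cv2 is exact on constructed interval sequences", {
  expect_equal(cv2(rep(4, 9)), 0)
  expect_equal(cv2(rep(c(1, 2), 10)), 2/3)   # |a-2a|/(3a) = 1/3, doubled
  expect_true(is.na(cv2(5)))
  set.seed(44)
  expect_equal(cv2(rexp(50000, 1)), 1, tolerance = 0.02)
})

test_that("time_resolved traces are flat at 1 for a Poisson ensemble", {
  fx <- gen_poisson(rate = 20, duration = 2000, n_trials = 40, n_units = 20,
                    seed = 45)
  ff <- time_resolved(fx, "FF", window = 400, step = 200)
  cv <- time_resolved(fx, "CV2", window = 400, step = 200)
  rt <- time_resolved(fx, "rate", window = 400, step = 200)
  expect_true(all(abs(ff$value - 1) < 0.15))
  expect_true(all(abs(cv$value - 1) < 0.1))
  expect_true(all(abs(rt$value - 20) < 2))
  expect_true(all(ff$n > 0))
})

test_that("a rate step is smeared over at most one window width", {
  # piecewise-constant rate: 5 Hz for 2 s, then 40 Hz for 2 s
  set.seed(46)
  lo <- gen_poisson(5, 2000, n_trials = 60, n_units = 10, seed = 47)
  hi <- gen_poisson(40, 2000, n_trials = 60, n_units = 10, seed = 48)
  sp_hi <- hi$spikes; sp_hi$time <- sp_hi$time + 2000
  all <- rbind(lo$spikes, sp_hi)
  fx <- trial_aligned(all$time, all$unit, all$trial, trials = lo$trials,
                      window = c(0, 4000), units = lo$units)
  tr <- time_resolved(fx, "rate", window = 400, step = 50)
  expect_true(all(abs(tr$value[tr$t_center <= 2000 - 200] - 5) < 1.5))
  expect_true(all(abs(tr$value[tr$t_center >= 2000 + 200] - 40) < 4))
  mid <- tr$value[tr$t_center > 1800 & tr$t_center < 2200]
  expect_true(all(diff(mid) > -1))   # monotone-ish transition over one window
})

test_that("two-state switching inflates FF but not CV2", {
  fx <- gen_switching(rate_low = 3, rate_high = 40, switch_rate = 2,
                      duration = 2000, n_trials = 60, n_units = 12,
                      seed = 49)
  ff <- time_resolved(fx, "FF", window = 1000, step = 500)
  cv <- time_resolved(fx, "CV2", window = 1000, step = 500)
  expect_true(mean(ff$value) > 1.5)
  expect_true(abs(mean(cv$value) - 1) < 0.12)
})

test_that("synchrony is 1 for duplicated trains and ~1/sqrt(N) for Poisson", {
  # N identical spike trains
  t <- cumsum(rep(25, 40))
  dup <- spike_data(time = rep(t, 10), unit = rep(1:10, each = length(t)),
                    units = data.frame(unit = 1:10), duration = 1000)
  expect_equal(synchrony_chi(dup, bin = 20), 1)

  # 100 independent Poisson units
  fx <- gen_poisson(10, 20000, n_trials = 1, n_units = 100, seed = 50)
  sdx <- spike_data(fx$spikes$time, fx$spikes$unit, fx$units,
                    duration = 20000)
  chi <- synchrony_chi(sdx, bin = 20)
  expect_gt(chi, 0.05); expect_lt(chi, 0.2)

  silent <- spike_data(numeric(0), integer(0), data.frame(unit = 1:5),
                       duration = 100)
  expect_true(is.na(synchrony_chi(silent, bin = 20)))
})

test_that("triangular rate kernel is unit-area and unbiased", {
  one <- rate_kernel(times = 500, width = 50, duration = 1000, dt = 1)
  expect_equal(sum(one$rate) / 1000, 1, tolerance = 1e-6)   # area = 1 spike
  expect_equal(one$time[which.max(one$rate)], 500, tolerance = 1)
  expect_true(all(one$rate[abs(one$time - 500) > 26] < 1e-9))

  fx <- gen_poisson(30, 60000, seed = 51)
  tr <- rate_kernel(fx$spikes$time, width = 50, duration = 60000)
  inner <- tr$rate[tr$time > 100 & tr$time < 59900]
  expect_equal(mean(inner), 30, tolerance = 0.1)
})

test_that("delta_stats is zero for identical epochs and scales with counts", {
  units <- data.frame(unit = 1:20, population = "E",
                      cluster = rep(0:3, each = 5))
  fx <- gen_poisson(15, 1000, n_trials = 30, n_units = 20, seed = 52)
  fx$units <- units
  ds <- delta_stats(fx, fx, units, stim_clusters = 0:1)
  expect_equal(ds$d_ff, c(0, 0), tolerance = 1e-12)
  # identical epochs: non-stimulated rate difference is exactly zero; the
  # stimulated one only moves by the active-period mask's selection bias
  expect_equal(ds$d_rate[ds$group == "non_stimulated"], 0, tolerance = 1e-12)
  expect_lt(abs(ds$d_rate[ds$group == "stimulated"]), 3)

  # doubled counts: per-trial duplication doubles rate and (about) doubles FF
  fx2 <- fx
  fx2$spikes <- rbind(fx$spikes, transform(fx$spikes, time = time + 0.1))
  ds2 <- delta_stats(fx, fx2, units, stim_clusters = integer(0))
  ns <- ds2[ds2$group == "non_stimulated", ]
  expect_equal(ns$d_rate, 15, tolerance = 1.5)
})

test_that("renewal consistency links CV^2, serial correlations and FF", {
  set.seed(53)
  gam <- rgamma(20000, shape = 4, scale = 10)
  rc <- renewal_consistency(gam)
  expect_equal(unname(rc["cv_sq"]), 0.25, tolerance = 0.03)
  expect_lt(abs(rc["xi"]), 0.05)
  expect_equal(unname(rc["ff_pred"]), 0.25, tolerance = 0.05)

  pois <- rexp(20000, 1)
  expect_equal(unname(renewal_consistency(pois)["ff_pred"]), 1,
               tolerance = 0.06)

  # alternating long/short intervals: xi_1 < 0 and predicted FF < CV^2
  alt <- rep(c(2, 10), 5000) + rexp(10000, 10)
  rca <- renewal_consistency(alt)
  expect_lt(unname(rca["ff_pred"]), unname(rca["cv_sq"]))
})

test_that("unit inclusion requires both criteria in every condition", {
  # 3 units x 2 conditions x 1 direction; unit 1 passes everywhere, unit 2
  # is too sparse in condition 2, unit 3 has too few trials recorded
  mk <- function(unit, trial, n_spikes)
    if (n_spikes == 0) NULL
    else data.frame(time = seq(1, 1999, length.out = n_spikes),
                    unit = unit, trial = trial)
  trials <- data.frame(trial = 1:8, condition = rep(1:2, each = 4),
                       final = 1)
  rows <- list()
  for (tr in 1:8) {
    rows[[length(rows) + 1]] <- mk(1, tr, 15)
    rows[[length(rows) + 1]] <- mk(2, tr, if (tr <= 4) 15 else 3)
    if (tr %in% c(1, 5)) rows[[length(rows) + 1]] <- mk(3, tr, 15)
  }
  sp <- do.call(rbind, rows)
  al <- trial_aligned(sp$time, sp$unit, sp$trial, trials = trials,
                      window = c(0, 2000),
                      units = data.frame(unit = 1:3))
  out <- unit_inclusion_filter(al, min_spikes = 10, min_trials = 4)
  expect_equal(unique(attr(out, "kept")$unit), 1)

  silent <- trial_aligned(numeric(0), integer(0), integer(0), trials = trials,
                          window = c(0, 2000),
                          units = data.frame(unit = 1:3))
  out0 <- unit_inclusion_filter(silent, min_spikes = 10, min_trials = 4)
  expect_equal(nrow(attr(out0, "kept")), 0)
})

test_that("statistics are invariant under global time translation", {
  fx <- gen_gamma(20, shape = 2, duration = 2000, n_trials = 20,
                  n_units = 5, seed = 54)
  shifted <- fx
  shifted$spikes$time <- shifted$spikes$time + 300
  shifted$window <- fx$window + 300
  a <- time_resolved(fx, "FF", window = 400, step = 100)
  b <- time_resolved(shifted, "FF", window = 400, step = 100)
  expect_equal(a$value, b$value)

  sd1 <- spike_data(fx$spikes$time, fx$spikes$unit, fx$units, duration = 2000)
  sd2 <- spike_data(fx$spikes$time + 300, fx$spikes$unit, fx$units,
                    duration = 2300)
  expect_equal(synchrony_chi(sd1, bin = 20, from = 0, to = 2000),
               synchrony_chi(sd2, bin = 20, from = 300, to = 2300))
})
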