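# Task protocol, decoder and decision logic (network-free parts).

test_that("task protocol draws only the permitted cue sets", {
  pr <- make_task_protocol(conditions = 1:3, trials_per_condition = 30,
                           amplitude = 0.1, seed = 1)
  tr <- pr$trials
  expect_equal(nrow(tr), 90)
  cued <- eiclust:::parse_cued(tr$cued)
  expect_true(all(lengths(cued) == tr$condition))
  expect_true(all(mapply(function(f, s) f %in% s, tr$final, cued)))
  allowed2 <- list(1:2, 3:4, 5:6)
  allowed3 <- list(c(6L, 1L, 2L), c(3L, 4L, 5L))
  expect_true(all(vapply(cued[tr$condition == 2], function(s)
    any(vapply(allowed2, identical, TRUE, y = s)), TRUE)))
  expect_true(all(vapply(cued[tr$condition == 3], function(s)
    any(vapply(allowed3, identical, TRUE, y = s)), TRUE)))
  # epoch timing invariants
  expect_true(all(tr$PS - tr$TS == 500))
  expect_true(all(tr$RS - tr$PS == 1000))
  expect_true(all(tr$RS_end - tr$RS == 400))
  iti <- tr$TS[-1] - (tr$TS[-nrow(tr)] + 2000)
  expect_true(all(iti >= 1500 & iti <= 1700))
  # condition 1 over 6k trials covers all six singleton cues
  expect_setequal(unlist(cued[tr$condition == 1]), 1:6)
  expect_error(make_task_protocol(conditions = 4), "conditions")
})

test_that("leaky integration has the right fixed point and decay", {
  z <- leaky_integrate(matrix(0, 100, 3), tau_I = 50)
  expect_true(all(z == 0))

  cst <- leaky_integrate(matrix(2, 5000, 1), tau_I = 50, bin = 1)
  expect_equal(cst[5000, 1], 2 / (1 - exp(-1/50)), tolerance = 1e-6)
  expect_equal(cst[5000, 1], 2 * 50, tolerance = 0.02)  # ~ c * tau_I

  imp <- matrix(0, 200, 1); imp[1, 1] <- 1
  I <- leaky_integrate(imp, tau_I = 50, bin = 1)
  expect_equal(I[101, 1] / I[1, 1], exp(-100/50), tolerance = 1e-10)
  expect_true(all(I >= 0))
})

test_that("decision variables normalize and handle degenerate input", {
  I <- matrix(1, 10, 6)
  DV <- decision_variable(I)
  expect_true(all(abs(DV - 1/6) < 1e-12))

  I2 <- matrix(0, 4, 6); I2[2, 3] <- 5
  DV2 <- decision_variable(I2)
  expect_equal(DV2[2, 3], 1)
  expect_true(all(DV2[1, ] == 1/6))          # all-zero row -> uniform
  expect_equal(rowSums(DV2), rep(1, 4))
})

test_that("detect_decision implements the RS window, anticipation and ties", {
  tm <- seq(1, 600, by = 1)
  mk <- function(f) {
    DV <- matrix(0.1, length(tm), 6)
    attr(DV, "time") <- tm
    f(DV)
  }
  # never crossing
  d0 <- detect_decision(mk(identity), theta = 0.6, rs_time = 100)
  expect_true(is.na(d0$chosen) && !d0$success)

  # already above threshold at RS -> anticipatory, RT 0
  d1 <- detect_decision(mk(function(D) { D[, 4] <- 0.9; D }),
                        theta = 0.6, rs_time = 100, final = 4)
  expect_equal(d1$rt, 0); expect_true(d1$success)

  # first crossing in window wins
  d2 <- detect_decision(mk(function(D) { D[tm >= 180, 2] <- 0.95; D }),
                        theta = 0.6, rs_time = 100, final = 2)
  expect_equal(d2$chosen, 2); expect_equal(d2$rt, 80)

  # crossing after the window: unsuccessful
  d3 <- detect_decision(mk(function(D) { D[tm >= 550, 2] <- 0.95; D }),
                        theta = 0.6, rs_time = 100, final = 2)
  expect_true(is.na(d3$chosen))

  # simultaneous crossings: lower direction index
  d4 <- detect_decision(mk(function(D) { D[tm >= 200, c(3, 5)] <- 0.7; D }),
                        theta = 0.6, rs_time = 100)
  expect_equal(d4$chosen, 3)
})

test_that("decoding accuracy is ~1 on separable counts and ~1/6 on shuffled labels", {
  # 6 units, unit d fires strongly only for direction d
  set.seed(20)
  n_per <- 10
  trials <- data.frame(trial = 1:(6 * n_per), condition = 1,
                       final = rep(1:6, each = n_per))
  rows <- lapply(seq_len(nrow(trials)), function(k) {
    d <- trials$final[k]
    n_hi <- rpois(1, 40); n_lo <- rpois(5, 2)
    data.frame(time = runif(n_hi + sum(n_lo), 0, 1000),
               unit = rep(c(d, setdiff(1:6, d)), c(n_hi, n_lo)),
               trial = trials$trial[k])
  })
  sp <- do.call(rbind, rows)
  al <- trial_aligned(sp$time, sp$unit, sp$trial, trials = trials,
                      window = c(0, 1000), units = data.frame(unit = 1:6))
  acc <- decoding_accuracy(al, window = 400, step = 300, seed = 2)
  expect_true(all(acc$accuracy > 0.9))

  al_sh <- al
  al_sh$trials$final <- local({ set.seed(21); sample(al$trials$final) })
  acc_sh <- decoding_accuracy(al_sh, window = 1000, step = 1000, seed = 2)
  expect_lt(mean(acc_sh$accuracy), 0.35)
})

test_that("threshold tuning reports zero accuracy for unreachable thresholds", {
  # hand-built task: two clusters alternate spikes, so both DVs hover near
  # 1/2 and never approach 0.99; the correct cluster fires first in each pair
  t1 <- seq(600, 1840, by = 10)     # unit 1 -> cluster 0 -> direction 1
  t5 <- seq(605, 1845, by = 10)     # unit 5 -> cluster 2 -> direction 3
  fake_task <- list(
    trials = data.frame(trial = 1, condition = 1, final = 1,
                        TS = 0, PS = 500, RS = 1500, RS_end = 1900),
    spikes = spike_data(time = c(t1, t5),
                        unit = rep(c(1L, 5L), c(length(t1), length(t5))),
                        units = data.frame(unit = 1:12, population = "E",
                                           cluster = rep(0:5, each = 2)),
                        duration = 2000))
  res <- tune_threshold(fake_task, theta_grid = 0.99)
  expect_equal(res$accuracy, 0)
  res2 <- tune_threshold(fake_task, theta_grid = c(0.5, 0.7))
  expect_equal(res2$accuracy, 1)
  expect_error(tune_threshold(fake_task, theta_grid = numeric(0)), "empty")
})
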