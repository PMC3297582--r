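test_that("immigration-death time average matches the analytic mean", {
  net <- bd_network(birth = 10, death = 1)
  tr <- ssa_simulate(net, t_end = 100, seed = 3, dt_max = 1000, grid_dt = 0.1,
                     record_events = FALSE)
  keep <- tr$times >= 10
  avg <- mean(tr$counts[keep, "M"])
  # stationary mean birth/death = 10; autocorrelated samples, generous band
  expect_gt(avg, 9)
  expect_lt(avg, 11)
  expect_true(all(tr$counts >= 0))
})

test_that("stationary counts are Poisson: variance equals mean", {
  net <- bd_network(birth = 10, death = 1)
  finals <- vapply(1:1000, function(i) {
    tr <- ssa_simulate(net, t_end = 10, seed = 100 + i, dt_max = 1000,
                       grid_dt = 10, record_events = FALSE)
    tr$counts[nrow(tr$counts), "M"]
  }, 0L)
  expect_equal(mean(finals), 10, tolerance = 0.1)
  expect_equal(var(finals) / mean(finals), 1, tolerance = 0.15)
})

test_that("identical seeds give bit-identical trajectories", {
  net <- build_network(uptick_strain("wt"), default_params())
  a <- ssa_simulate(net, t_end = 2, seed = 7)
  b <- ssa_simulate(net, t_end = 2, seed = 7)
  expect_identical(a$event_times, b$event_times)
  expect_identical(a$event_ids, b$event_ids)
  expect_identical(a$counts, b$counts)
  c <- ssa_simulate(net, t_end = 2, seed = 8)
  expect_false(identical(a$event_times, c$event_times))
})

test_that("a network with zero propensities stays in the absorbing state", {
  net <- bd_network(birth = 0, death = 1)
  tr <- ssa_simulate(net, t_end = 5, seed = 1, dt_max = 1000)
  expect_equal(tr$n_events, 0)
  expect_true(all(tr$counts[, "M"] == 0))
  expect_length(tr$event_times, 0)
})

test_that("invalid simulation arguments are rejected", {
  net <- bd_network()
  expect_error(ssa_simulate(net, t_end = 0), "positive")
  expect_error(ssa_simulate(net, t_end = -3), "positive")
  expect_error(run_ensemble(net, n_runs = 0), ">= 1")
})

test_that("a single-run ensemble reproduces the bare simulation", {
  net <- bd_network()
  ens <- run_ensemble(net, n_runs = 1, t_end = 5, base_seed = 11,
                      dt_max = 1000)
  tr <- ssa_simulate(net, t_end = 5, seed = 11, dt_max = 1000,
                     record_events = FALSE)
  expect_identical(ens$tx_times[[1]], tr$tx_times[[1]])
  expect_equal(ens$mean_counts[, "M"], unname(tr$counts[, "M"]))
})

test_that("ensemble seeds are distinct and runs independent", {
  net <- bd_network()
  ens <- run_ensemble(net, n_runs = 3, t_end = 5, base_seed = 21,
                      dt_max = 1000)
  expect_false(identical(ens$mrna_runs[[1]][1, ], ens$mrna_runs[[1]][2, ]))
  tr2 <- ssa_simulate(net, t_end = 5, seed = 22, dt_max = 1000,
                      record_events = FALSE)
  expect_equal(unname(ens$mrna_runs[[1]][2, ]), unname(tr2$counts[, "M"]))
})

test_that("stationary mRNA distribution matches the telegraph master equation", {
  kon <- 1; koff <- 2; ktx <- 8; kdeg <- 1
  net <- telegraph_network(kon, koff, ktx, kdeg)
  pmf <- telegraph_stationary(kon, koff, ktx, kdeg)
  finals <- vapply(1:10000, function(i) {
    tr <- ssa_simulate(net, t_end = 8, seed = 10000 + i, dt_max = 100,
                       grid_dt = 8, record_events = FALSE)
    tr$counts[nrow(tr$counts), "M"]
  }, 0L)
  cap <- 10  # pool the sparse tail so expected counts stay comfortably > 5
  obs <- tabulate(pmin(finals, cap) + 1L, nbins = cap + 1L)
  gof <- stats::chisq.test(obs, p = c(pmf[1:cap], 1 - sum(pmf[1:cap])))
  expect_gt(gof$p.value, 0.01)
  expect_equal(mean(finals), ktx * kon / (kon + koff) / kdeg, tolerance = 0.05)
})

test_that("halving the propensity-refresh cap changes ensemble means by < 1%", {
  # the time dependence enters transcription through g(t); use the strain
  # whose propensity is purely g(t)-driven so the capping bias is isolated
  net <- build_network(uptick_strain("d_rok_d_spo0A"), default_params())
  totals <- function(dt) {
    ens <- run_ensemble(net, n_runs = 4000, t_end = 6, base_seed = 31,
                        dt_max = dt)
    sum(lengths(ens$tx_times)) / ens$n_runs
  }
  t1 <- totals(0.01)
  t2 <- totals(0.005)
  expect_lt(abs(t1 - t2) / t1, 0.01)
})

test_that("ensemble-mean standard error scales as one over sqrt(n)", {
  net <- build_network(uptick_strain("d_rok_d_spo0A"), default_params())
  ens <- run_ensemble(net, n_runs = 1000, t_end = 3, base_seed = 51)
  i_t0 <- which.min(abs(ens$times - 2.25))
  counts <- ens$mrna_runs[[1]][, i_t0]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  ratio <- sem(counts[1:250]) / sem(counts)
  expect_gt(ratio, 2 - 0.4)
  expect_lt(ratio, 2 + 0.4)
})

test_that("no species count ever goes negative in full-model snapshots", {
  net <- build_network(uptick_strain("wt", n_promoters = 2), default_params())
  tr <- ssa_simulate(net, t_end = 6, seed = 99, record_events = FALSE)
  expect_true(all(tr$counts >= 0))
  # conservation: each site is either free or bound
  a1 <- tr$counts[, "A1_free_p1"] + tr$counts[, "A1_OAP_p1"]
  expect_true(all(a1 == 1))
  a2 <- tr$counts[, "A2_free_p2"] + tr$counts[, "A2_OAP_p2"] +
    tr$counts[, "A2_Rok_p2"]
  expect_true(all(a2 == 1))
})

test_that("the simulate generic dispatches to single runs and ensembles", {
  net <- bd_network()
  tr <- simulate(net, nsim = 1, seed = 5, t_end = 2, dt_max = 1000)
  expect_s3_class(tr, "uptick_trajectory")
  ens <- simulate(net, nsim = 3, seed = 5, t_end = 2, dt_max = 1000)
  expect_s3_class(ens, "uptick_ensemble")
  expect_identical(ens$tx_times_runs[[1]][[1]], tr$tx_times[[1]])
})
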