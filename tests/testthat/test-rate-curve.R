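test_that("rate curves histogram transcription events per run per hour", {
  ens <- fake_ensemble(list(list(c(1.0, 1.1))), t_end = 4)
  cv <- mean_rate_curve(ens, bin_width = 1)
  expect_s3_class(cv, "uptick_rate_curve")
  # both events fall in one 1-h bin: rate 2 events/h there, 0 elsewhere
  i <- which(cv$times > 1 & cv$times < 2)
  expect_equal(cv$rate[i], 2)
  expect_equal(sum(cv$rate), 2)
  expect_error(mean_rate_curve(ens, bin_width = 0), "positive")
})

test_that("a constant-rate Poisson process is recovered bin by bin", {
  lambda <- 5
  set.seed(2024)
  runs <- lapply(1:1000, function(i) {
    n <- stats::rpois(1, lambda * 4)
    sort(stats::runif(n, 0, 4))
  })
  cv <- mean_rate_curve(fake_ensemble(list(runs), t_end = 4), bin_width = 0.5)
  se <- sqrt(lambda / (0.5 * 1000))
  expect_true(all(abs(cv$rate - lambda) < 3.5 * se))
})

test_that("rate curve integrates exactly to mean transcripts per cell", {
  net <- build_network(uptick_strain("d_rok_d_spo0A"), default_params())
  ens <- run_ensemble(net, n_runs = 50, t_end = 6, base_seed = 61)
  cv <- mean_rate_curve(ens, bin_width = 0.25)
  expect_equal(sum(cv$rate) * cv$bin_width,
               sum(lengths(ens$tx_times)) / ens$n_runs)
})

test_that("peak amplitude takes the smoothed maximum with earliest-time ties", {
  mk <- function(rate, bw = 1) {
    runs <- list(list(numeric(0)))
    cv <- mean_rate_curve(fake_ensemble(runs, t_end = length(rate) * bw), bw)
    cv$rate <- rate
    cv$times <- seq_along(rate) - 0.5
    cv
  }
  # raw maximum and its time (no smoothing)
  pk <- peak_amplitude(mk(c(0, 1, 3, 2)), window = 1)
  expect_equal(unname(pk["value"]), 3)
  expect_equal(which(mk(c(0, 1, 3, 2))$rate == 3), 3L)
  # flat curve: documented earliest-time tie-break
  pk_flat <- peak_amplitude(mk(c(2, 2, 2)))
  expect_equal(unname(pk_flat["value"]), 2)
  expect_equal(unname(pk_flat["time"]), mk(c(2, 2, 2))$times[1])
  # linearity: scaling rates scales the value, not the time
  a <- peak_amplitude(mk(c(0, 1, 3, 2, 1)))
  b <- peak_amplitude(mk(10 * c(0, 1, 3, 2, 1)))
  expect_equal(unname(b["value"]), 10 * unname(a["value"]))
  expect_equal(b["time"], a["time"])
  # all-zero curve warns and reports zero at the first bin
  expect_warning(pz <- peak_amplitude(mk(c(0, 0, 0))), "all-zero")
  expect_equal(unname(pz["value"]), 0)
})

test_that("amplitude ratios compare smoothed peaks", {
  ens <- fake_ensemble(list(list(c(0.4, 1.1, 1.2, 2.3))), t_end = 4)
  cv <- mean_rate_curve(ens, bin_width = 0.5)
  expect_equal(amplitude_ratio(cv, cv), 1)
  cv2 <- cv
  cv2$rate <- cv$rate * 3
  expect_equal(amplitude_ratio(cv2, cv), 3)
  cvz <- cv
  cvz$rate <- cv$rate * 0
  expect_error(suppressWarnings(amplitude_ratio(cv, cvz)), "zero peak")
  cvb <- mean_rate_curve(ens, bin_width = 0.25)
  expect_error(amplitude_ratio(cv, cvb), "same bin width")
})

test_that("peak normalization yields max 1 and is idempotent", {
  ens <- fake_ensemble(list(list(c(0.4, 1.1, 1.2, 2.3, 1.3))), t_end = 4)
  cv <- mean_rate_curve(ens, bin_width = 0.5)
  nz <- normalize_peak(cv)
  expect_equal(max(nz$rate), 1)
  expect_equal(normalize_peak(nz)$rate, nz$rate)
  cvz <- cv
  cvz$rate <- 0 * cv$rate
  expect_error(normalize_peak(cvz), "zero peak")
})

test_that("decay half-time interpolates linearly and flags censoring", {
  mk <- function(rate, times) {
    ens <- fake_ensemble(list(list(numeric(0))), t_end = max(times) + 0.5)
    cv <- mean_rate_curve(ens, bin_width = 1)
    cv$rate <- rate
    cv$times <- times
    cv
  }
  # triangle peaking at 10 (t = 2) and reaching 5 at t = 3: half-time 1 h
  tri <- mk(c(0, 5, 10, 5, 0), 0:4)
  ht <- decay_halftime(tri)
  expect_equal(as.numeric(ht), 1)
  expect_false(attr(ht, "censored"))
  # scale invariance
  tri10 <- mk(10 * c(0, 5, 10, 5, 0), 0:4)
  expect_equal(as.numeric(decay_halftime(tri10)), 1)
  # never dropping below half peak before the horizon is censored
  flat <- mk(c(1, 2, 2, 1.9, 1.8), 0:4)
  htc <- decay_halftime(flat)
  expect_true(attr(htc, "censored"))
  expect_equal(as.numeric(htc), 4 - 1)
})

test_that("run subsets rebuild consistent reductions", {
  net <- build_network(uptick_strain("d_rok"), default_params())
  ens <- run_ensemble(net, n_runs = 40, t_end = 3, base_seed = 71)
  sub <- subset_runs(ens, 1:20)
  expect_equal(sub$n_runs, 20L)
  expect_equal(sort(unlist(sub$tx_times_runs[[1]])), sort(sub$tx_times[[1]]))
  full_first <- subset_runs(ens, seq_len(ens$n_runs))
  expect_equal(full_first$tx_times[[1]], ens$tx_times[[1]])
  expect_error(subset_runs(ens, 0), "out of range")
})
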