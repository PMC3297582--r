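test_that("threshold calibration uses the nearest-rank upper quantile", {
  early <- as_cell_table(data.frame(cell_id = 1:100, cfp = sample(1:100),
                                    yfp = 0))
  late <- as_cell_table(data.frame(cell_id = 1:100, cfp = 0,
                                   yfp = c(rep(10, 75), rep(80, 25))))
  cal <- calibrate_threshold(late, comg_cutoff = 50, early = early)
  expect_equal(cal$fraction, 0.25)
  expect_equal(cal$threshold, 75)
  # exactly the upper 25 cells exceed the threshold under strict inequality
  expect_equal(sum(early$cfp > cal$threshold), 25)
})

test_that("degenerate calibration populations are rejected", {
  early <- as_cell_table(data.frame(cell_id = 1:10, cfp = 1:10, yfp = 0))
  all_low <- as_cell_table(data.frame(cell_id = 1:10, cfp = 0, yfp = 10))
  expect_error(calibrate_threshold(all_low, 50, early), "degenerate")
  all_high <- as_cell_table(data.frame(cell_id = 1:10, cfp = 0, yfp = 90))
  expect_error(calibrate_threshold(all_high, 50, early), "degenerate")
})

test_that("classification uses strict inequality against the threshold", {
  cells <- as_cell_table(data.frame(cell_id = 1:3, cfp = c(10, 40, 36),
                                    yfp = 0))
  cls <- classify_competent(cells, 36)
  expect_equal(cls$labels, c(FALSE, TRUE, FALSE))
  expect_equal(cls$fraction, 1 / 3)
  expect_equal(classify_competent(cells, 100)$fraction, 0)
  expect_error(classify_competent(cells, 0), "positive")
})

test_that("competent fraction is nonincreasing in the threshold", {
  gen <- generate_cells(synth_cell_params(n_cells = 3000), seed = 3)
  fr <- vapply(seq(10, 120, by = 5),
               function(th) classify_competent(gen$cells, th)$fraction, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("binned competent fractions normalize within bins and flag empties", {
  cells <- as_cell_table(data.frame(cell_id = 1:10, cfp = 0,
                                    yfp = c(rep(5, 10))))
  labels <- c(rep(TRUE, 3), rep(FALSE, 7))
  out <- binned_competence_fraction(cells, labels, c(0, 10, 20))
  expect_equal(out$percent_competent[1], 30)
  expect_true(out$empty[2])
  expect_true(is.na(out$percent_competent[2]))
  # all-competent table: every nonempty bin at 100%
  out2 <- binned_competence_fraction(cells, rep(TRUE, 10), c(0, 10, 20))
  expect_equal(out2$percent_competent[1], 100)
  expect_error(binned_competence_fraction(cells, labels, c(0, 10, 5)),
               "strictly increasing")
  expect_error(binned_competence_fraction(cells, labels[1:3], c(0, 10, 20)),
               "match")
})

test_that("the two-proportion z-test matches the printed single-cell analysis", {
  # counts reconstructed from the published figure: 11,238 cells, 1,419
  # competent, 48 competent above the boundary comprising 2.9% of that side
  tab <- list(n_comp_above = 48, n_total_above = round(48 / 0.029),
              n_comp_below = 1419 - 48,
              n_total_below = 11238 - round(48 / 0.029))
  res <- boundary_proportion_test(tab)
  expect_equal(res$p_above, 2.9, tolerance = 0.01)
  expect_equal(res$p_below, 14.3, tolerance = 0.01)
  expect_lt(res$p_value, 0.001)
  # agrees with the uncorrected chi-square equivalent
  pt <- stats::prop.test(c(48, 1371), c(tab$n_total_above, tab$n_total_below),
                         correct = FALSE)
  expect_equal(res$p_value, pt$p.value, tolerance = 1e-10)
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-10)
})

test_that("equal proportions give z = 0 and small tables fall back to Fisher", {
  eq <- boundary_proportion_test(list(n_comp_above = 50, n_total_above = 100,
                                      n_comp_below = 500, n_total_below = 1000))
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  ext <- boundary_proportion_test(list(n_comp_above = 0, n_total_above = 10,
                                       n_comp_below = 10, n_total_below = 10))
  expect_lt(ext$p_fisher, 0.001)
  expect_equal(ext$p_fisher,
               stats::fisher.test(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))$p.value)
  expect_error(boundary_proportion_test(list(n_comp_above = 1,
                                             n_total_above = 0,
                                             n_comp_below = 1,
                                             n_total_below = 10)), "positive")
})

test_that("cell tables validate their schema on read", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cell_id = 1:3, cfp = c(1, 2, 3)), f,
                   row.names = FALSE)
  expect_error(read_cell_table(f), "yfp")
  utils::write.csv(data.frame(cell_id = 1:3, cfp = c(1, 2, NA),
                              yfp = c(1, 2, 3)), f, row.names = FALSE)
  expect_error(read_cell_table(f), "missing values")
  utils::write.csv(data.frame(cell_id = 1:3, cfp = 1:3, yfp = 4:6), f,
                   row.names = FALSE)
  tab <- read_cell_table(f)
  expect_s3_class(tab, "cell_table")
  expect_equal(nrow(tab), 3)
})

test_that("calibrate-then-classify recovers planted fraction and threshold", {
  sp <- synth_cell_params(n_cells = 10000, competent_fraction_target = 0.133,
                          cfp_threshold_planted = 36)
  gen <- generate_cells(sp, seed = 21)
  early <- gen$cells
  # late calibration population: the ComK-dependent reporter (yfp channel)
  # separates ON cells cleanly above the 50 a.u. cutoff
  set.seed(22)
  late <- early
  late$yfp <- ifelse(gen$truth,
                     80 + stats::rlnorm(nrow(early), log(20), 0.4),
                     stats::runif(nrow(early), 5, 35))
  cal <- calibrate_threshold(late, comg_cutoff = 50, early = early)
  true_frac <- mean(gen$truth)
  se <- sqrt(true_frac * (1 - true_frac) / nrow(early))
  expect_lt(abs(cal$fraction - true_frac), 2 * se + 1e-12)
  expect_lt(abs(cal$fraction - 0.133), 0.01)
  expect_lt(abs(cal$threshold - 36), 2)
  cls <- classify_competent(early, cal$threshold)
  expect_lt(abs(cls$fraction - true_frac), 2 * se + 1e-12)
})

test_that("classification matches the planted competent fraction at scale", {
  sp <- synth_cell_params(n_cells = 11238, competent_fraction_target = 0.126)
  gen <- generate_cells(sp, seed = 31)
  cls <- classify_competent(gen$cells, sp$cfp_threshold_planted)
  expect_lt(abs(cls$fraction - 0.126), 0.007)
  # the generator separates ON/OFF exactly at the planted threshold
  expect_equal(cls$labels, gen$truth)
})

test_that("proportion test keeps its nominal type-I error on null tables", {
  sp <- synth_cell_params(n_cells = 2000)
  rejected <- 0L
  n_tables <- 1000L
  for (i in seq_len(n_tables)) {
    gen <- generate_null_cells(sp, seed = 5000 + i)
    boundary <- stats::median(gen$cells$yfp)
    tab <- competence_contingency(gen$cells, gen$truth, boundary)
    res <- boundary_proportion_test(tab)
    if (res$p_value < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / n_tables
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
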