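test_that("strain presets and validation behave as documented", {
  expect_error(uptick_strain("nonexistent"), "valid presets")
  expect_error(uptick_strain("wt", n_promoters = 3), "1 or 2")
  expect_error(uptick_strain("wt", site_mult = c(Q9 = 1)), "unknown site")
  s <- uptick_strain("d_rok_d_spo0A")
  expect_false(s$rok_present)
  expect_false(s$spo0a_present)
  a2 <- uptick_strain("A2")
  expect_equal(unname(a2$site_mult[["RokA2"]]), 0)
  expect_lt(a2$site_mult[["A2"]], 1)
})

test_that("knockouts remove the corresponding species and reactions", {
  p <- default_params()
  dr <- build_network(uptick_strain("d_rok"), p)
  expect_false("Rok" %in% names(dr$species))
  expect_false(any(grepl("Rok", dr$reactions$label)))
  ds <- build_network(uptick_strain("d_spo0A"), p)
  expect_false("OAP" %in% names(ds$species))
  expect_false(any(grepl("OAP", ds$reactions$label)))
  # Rok still acts in the spo0A knockout, through A2 and the auxiliary site
  expect_true(all(c("A2_Rok_p1", "RokAux_Rok_p1") %in% names(ds$species)))
  # A/R sites cannot be occupied without OA~P
  expect_false(any(grepl("^R1|^R2|^A1|^A3", names(ds$species))))
})

test_that("a destroyed site loses its binding reactions", {
  p <- default_params()
  s <- uptick_strain("wt", site_mult = c(A1 = 0, R2 = 0))
  net <- build_network(s, p)
  expect_false(any(grepl("A1", net$reactions$label)))
  expect_false(any(grepl("R2", net$reactions$label)))
  expect_true(any(grepl("A3", net$reactions$label)))
})

test_that("spo0A knockout without rok equals the double knockout, structurally", {
  p <- default_params()
  a <- build_network(uptick_strain("d_spo0A", rok_present = FALSE,
                                   label = "d_rok_d_spo0A"), p)
  b <- build_network(uptick_strain("d_rok_d_spo0A"), p)
  expect_identical(a$species, b$species)
  expect_identical(a$reactions, b$reactions)
  expect_identical(a$stoich, b$stoich)
})

test_that("dual-promoter networks duplicate site reactions over shared pools", {
  p <- default_params()
  net <- build_network(uptick_strain("wt", n_promoters = 2), p)
  expect_length(net$mrna_idx, 2)
  expect_equal(sum(grepl("^mRNA_", names(net$species))), 2)
  expect_equal(sum(net$species[grepl("^mRNA_", names(net$species))]), 0)
  r1 <- net$reactions[grepl("_p1$", net$reactions$label), ]
  r2 <- net$reactions[grepl("_p2$", net$reactions$label), ]
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$const, r2$const)  # identical binding affinities
  expect_equal(sum(names(net$species) == "OAP"), 1)  # one shared pool
  expect_equal(sum(names(net$species) == "Rok"), 1)
})

test_that("n_promoters outside 1..2 is an unsupported configuration", {
  s <- uptick_strain("wt")
  s$n_promoters <- 3L  # bypass constructor validation
  expect_error(build_network(s, default_params()), "1 or 2")
})

test_that("transcription propensity multiplies occupancy factors", {
  p <- default_params()
  t0 <- p$t0
  # empty promoter at the activity peak fires at the base rate
  expect_equal(transcription_propensity(list(), t0, p), p$k_tx_base)
  # Rok at both of its sites: the repressed basal state
  expect_equal(transcription_propensity(list(A2 = "Rok", RokAux = "Rok"), t0, p),
               p$k_tx_base * p$rho_rok^2)
  # OA~P on all A sites boosts transcription alpha-fold per site
  full_a <- list(A1 = "OAP", A2 = "OAP", A3 = "OAP")
  expect_equal(transcription_propensity(full_a, t0, p),
               p$k_tx_base * p$alpha^3)
  expect_gt(transcription_propensity(full_a, t0, p),
            transcription_propensity(list(), t0, p))
  # joint repression is stronger than either repressor alone
  joint <- transcription_propensity(list(A2 = "Rok", R1 = "OAP"), t0, p)
  expect_lt(joint, transcription_propensity(list(A2 = "Rok"), t0, p))
  expect_lt(joint, transcription_propensity(list(R1 = "OAP"), t0, p))
  expect_error(transcription_propensity(list(A1 = "Rok"), t0, p),
               "invalid occupant")
  expect_error(transcription_propensity(list(Z1 = "OAP"), t0, p),
               "unknown promoter site")
})

test_that("all-or-none activation only boosts the fully bound promoter", {
  p <- default_params(activation_mode = "all_or_none")
  t0 <- p$t0
  expect_equal(transcription_propensity(list(A1 = "OAP"), t0, p), p$k_tx_base)
  expect_equal(
    transcription_propensity(list(A1 = "OAP", A2 = "OAP", A3 = "OAP"), t0, p),
    p$k_tx_base * p$alpha^3)
})

test_that("configuration files round-trip through read_run_config", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("params:",
               "  alpha: 3.5",
               "  rok_copies: 80",
               "strain:",
               "  preset: d_rok",
               "  n_promoters: 2"), cfg)
  rc <- read_run_config(cfg)
  expect_equal(rc$params$alpha, 3.5)
  expect_equal(rc$params$rok_copies, 80)
  expect_equal(rc$params$t0, default_params()$t0)
  expect_false(rc$strain$rok_present)
  expect_equal(rc$strain$n_promoters, 2L)
})
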