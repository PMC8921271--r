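elig_fixture <- function(...) {
  generate_fixture(fixture_spec(...))
}

test_that("a well-behaved cryo structure passes every eligibility filter", {
  rep <- check_eligibility(elig_fixture())
  expect_true(rep$overall)
  expect_length(rep$failure_reasons, 0)
})

test_that("each eligibility boundary follows the stated conventions", {
  # temperature: closed interval 80-120 K
  expect_true(check_eligibility(elig_fixture(metadata = list(temperature = 80)))$overall)
  expect_true(check_eligibility(elig_fixture(metadata = list(temperature = 120)))$overall)
  r293 <- check_eligibility(elig_fixture(metadata = list(temperature = 293)))
  expect_false(r293$overall)
  expect_false(r293$temperature_in_80_120K)
  expect_match(paste(r293$failure_reasons, collapse = " "), "temperature")
  expect_false(check_eligibility(
    elig_fixture(metadata = list(temperature = 79.9)))$temperature_in_80_120K)

  # resolution: 3.5 A or better (<=)
  expect_true(check_eligibility(
    elig_fixture(metadata = list(resolution = 3.5)))$resolution_le_3p5)
  expect_false(check_eligibility(
    elig_fixture(metadata = list(resolution = 3.51)))$resolution_le_3p5)

  # R_free: at most 0.4
  expect_true(check_eligibility(
    elig_fixture(metadata = list(r_free = 0.4)))$rfree_le_0p4)
  expect_false(check_eligibility(
    elig_fixture(metadata = list(r_free = 0.401)))$rfree_le_0p4)

  # missing metadata fails with an explanatory reason
  runk <- check_eligibility(elig_fixture(metadata = list(temperature = NA_real_)))
  expect_false(runk$overall)
  expect_match(paste(runk$failure_reasons, collapse = " "), "unknown")
})

test_that("the 20-oxygen rule counts side-chain oxygens, not residues", {
  # 9 Asp = 18 oxygens: fails; 10 Asp = 20 oxygens: passes
  m18 <- elig_fixture(n_chains = 1, residues_per_chain = 45,
                      composition = c(ASP = 0.2, GLU = 0, ASN = 0.2, GLN = 0.2,
                                      ALA = 0.4))
  n18 <- nrow(select_oxygens(m18, "asp_glu"))
  r <- check_eligibility(m18)
  expect_equal(r$ge_20_carboxyl_oxygens, n18 >= 20)
  expect_equal(r$n_carboxyl_oxygens, n18)

  m <- elig_fixture()
  expect_true(check_eligibility(m)$ge_20_carboxyl_oxygens)
  m$atoms <- m$atoms[!(m$atoms$residue_name %in% c("ASP", "GLU") &
                         !m$atoms$atom_name %in% c("N", "CA", "C", "O")), ]
  r0 <- check_eligibility(m)
  expect_false(r0$ge_20_carboxyl_oxygens)
  expect_false(r0$has_asp_glu)
})

test_that("B-factor model and occupancy filters fire", {
  flat <- elig_fixture()
  flat$atoms$b_iso <- 25
  rf <- check_eligibility(flat)
  expect_false(rf$per_atom_bfactors_not_flat)
  expect_match(paste(rf$failure_reasons, collapse = " "), "flat")

  perres <- elig_fixture()
  perres$atoms <- dplyr::group_by(perres$atoms, chain_id, residue_seq)
  perres$atoms <- dplyr::ungroup(dplyr::mutate(perres$atoms, b_iso = mean(b_iso)))
  rp <- check_eligibility(perres)
  expect_false(rp$per_atom_bfactors_not_flat)
  expect_match(paste(rp$failure_reasons, collapse = " "), "residue")

  partial <- elig_fixture()
  ox <- which(partial$atoms$residue_name == "ASP" & partial$atoms$atom_name == "OD1")
  partial$atoms$occupancy[ox[1]] <- 0.5
  ro <- check_eligibility(partial)
  expect_false(ro$asp_glu_full_occupancy)

  nucleic <- elig_fixture()
  nucleic$atoms$residue_name[1:4] <- "DA"
  expect_false(check_eligibility(nucleic)$is_protein_no_nucleic)
})

test_that("percentile extremes behave as the rank convention dictates", {
  withr::with_seed(10, {
    tbl <- tibble::tibble(
      structure_id = sprintf("S%04d", 1:1000),
      resolution = seq(1, 3, length.out = 1000),
      bnet = stats::rlnorm(1000, 0, 0.3))
  })
  out <- bnet_percentile(tbl, window_size = 1000)
  expect_equal(out$bnet_percentile[which.max(tbl$bnet)], 1.0)
  expect_equal(out$bnet_percentile[which.min(tbl$bnet)], 0.001)
  expect_true(all(out$bnet_percentile > 0 & out$bnet_percentile <= 1))
})

test_that("windowed percentiles match the brute-force oracle", {
  withr::with_seed(21, {
    tbl <- tibble::tibble(
      structure_id = sprintf("S%03d", 1:300),
      resolution = rep(seq(1, 3.5, length.out = 100), each = 3),  # grid with ties
      bnet = stats::rlnorm(300, 0, 0.4))
  })
  out <- bnet_percentile(tbl, window_size = 50)
  expect_equal(out$bnet_percentile, oracle_percentile(tbl, 50))
  # monotone in bnet within a fixed comparison set: global window
  out_all <- bnet_percentile(tbl, window_size = 300)
  expect_equal(order(out_all$bnet_percentile), order(tbl$bnet))
})

test_that("missing resolutions yield NA percentiles with a warning", {
  tbl <- tibble::tibble(structure_id = c("A", "B", "C"),
                        resolution = c(1.5, NA, 2.5),
                        bnet = c(1, 2, 3))
  expect_warning(out <- bnet_percentile(tbl, window_size = 2), "resolution")
  expect_true(is.na(out$bnet_percentile[2]))
  expect_false(anyNA(out$bnet_percentile[c(1, 3)]))
})

test_that("dose fits recover exact and noisy gradients", {
  fit <- fit_dose_series(tibble::tibble(dose = c(0, 1, 2), bnet = c(1, 2, 3)))
  expect_equal(fit$gradient, 1.0, tolerance = 1e-12)
  expect_equal(fit$y_intercept, 1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0)

  expect_error(fit_dose_series(tibble::tibble(dose = c(0, 1, 2, 9), bnet = 1:4),
                               exclude_above_dose = 1),
               ">= 3")
  expect_error(fit_dose_series(tibble::tibble(dose = rep(2, 4), bnet = 1:4)),
               "degenerate|identical")

  withr::with_seed(33, {
    dose <- seq(0, 18, length.out = 10)
    bnet <- 1 + 0.1 * dose + stats::rnorm(10, sd = 0.05)
  })
  noisy <- fit_dose_series(tibble::tibble(dose = dose, bnet = bnet))
  se <- 0.05 / sqrt(sum((dose - mean(dose))^2))
  expect_lt(abs(noisy$gradient - 0.1), 3 * se)
})

test_that("fit-consistency summaries compute relative standard deviations", {
  mk_fit <- function(g, ic) structure(list(gradient = g, y_intercept = ic),
                                      class = "dose_series_fit")
  same <- summarise_fit_consistency(list(mk_fit(0.1, 1), mk_fit(0.1, 1)))
  expect_equal(same$gradient_rsd, 0)
  expect_equal(same$intercept_rsd, 0)

  two <- summarise_fit_consistency(list(mk_fit(1, 0.5), mk_fit(3, 0.5)))
  expect_equal(two$gradient_rsd, sqrt(2) / 2, tolerance = 1e-12)

  # consistent (damage-signal-like) slopes vs scattered (control-like) slopes
  tight <- summarise_fit_consistency(lapply(c(0.09, 0.1, 0.11), mk_fit, ic = 1))
  loose <- summarise_fit_consistency(lapply(c(0.02, 0.1, 0.35), mk_fit, ic = 1))
  expect_lt(tight$gradient_rsd, loose$gradient_rsd)

  zero <- summarise_fit_consistency(list(mk_fit(-1, 1), mk_fit(1, 1)))
  expect_true(zero$gradient_rsd_is_absolute)
})

test_that("Spearman scans respect perfect, inverse and constant covariates", {
  withr::with_seed(14, {
    tbl <- tibble::tibble(
      structure_id = sprintf("S%02d", 1:40),
      bnet = stats::rlnorm(40, 0, 0.3))
  })
  tbl$resolution <- tbl$bnet                     # rho = 1
  tbl$r_work <- -tbl$bnet                        # rho = -1
  tbl$temperature <- 100                         # constant -> NA
  tbl$molecular_mass <- exp(tbl$bnet)            # monotone transform -> 1
  sp <- spearman_matrix(tbl, "bnet")
  rho <- setNames(sp$rho, sp$covariate)
  expect_equal(unname(rho["resolution"]), 1)
  expect_equal(unname(rho["r_work"]), -1)
  expect_true(is.na(rho["temperature"]))
  expect_equal(unname(rho["molecular_mass"]), 1)
})

test_that("advisory flags follow the strict thresholds", {
  expect_true(flag_suspect(25.1, 1.0))          # far over both thresholds
  expect_false(flag_suspect(1.61, 0.489))       # ordinary structure
  expect_false(flag_suspect(3.0, 0.5))          # boundary is strict
  expect_true(flag_suspect(3.0001, 0.5))
  expect_true(flag_suspect(1.0, 0.96))          # percentile alone can flag
  expect_false(flag_suspect(1.0, 0.95))
  expect_false(flag_suspect(2.0))               # missing percentile ignored
})
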