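test_that("observed discrimination matches the mass-balance arithmetic", {
  # xi = 400/40 = 10; Delta = 0.040/(1 + 0.004 - 0.040)
  expect_equal(observed_discrimination(400, 360, 0, 4), 41.49378,
               tolerance = 1e-5)
  expect_equal(observed_discrimination(400, 360, 2.5, 2.5), 0)
  expect_error(observed_discrimination(400, 400, 0, 4), "drawdown")
})

test_that("observed discrimination depends only on xi and the deltas", {
  d1 <- observed_discrimination(400, 360, 1, 5)
  d2 <- observed_discrimination(800, 720, 1, 5)   # same xi after rescaling
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("epsilon_w is pinned at 25 degC and decreases with temperature", {
  expect_equal(epsilon_w(25), 41.2, tolerance = 1e-3)
  expect_gt(epsilon_w(25), epsilon_w(35))
  expect_error(epsilon_w(-5), "Tleaf")
  # coefficient changes propagate linearly into the equilibrated delta
  c1 <- fractionation_constants(eps_w_coeffs = c(17604, 17.844))
  c2 <- fractionation_constants(eps_w_coeffs = c(17604, 16.844))
  expect_equal(equilibrated_source_delta(0, 25, c2) -
                 equilibrated_source_delta(0, 25, c1), 1, tolerance = 1e-3)
})

test_that("equilibrated source delta uses exact ratio algebra", {
  expect_equal(equilibrated_source_delta(0, 25), epsilon_w(25))
  # (1.010)(1 + eps_w/1000) - 1 with eps_w(25) = 41.2
  expect_equal(equilibrated_source_delta(10, 25), 51.612, tolerance = 2e-3)
  # inverse is exact under ratio algebra
  d_eq <- equilibrated_source_delta(10, 25)
  back <- ((1 + d_eq / 1000) / (1 + epsilon_w(25) / 1000) - 1) * 1000
  expect_equal(back, 10, tolerance = 1e-10)
})

test_that("Cm inversion is the exact inverse of the supply relation", {
  a_bar <- 8.8; Ca <- 300; dea <- 25
  for (cm in c(5, 50, 150, 250)) {
    D <- (a_bar / 1000 + (cm / (Ca - cm)) * dea / 1000) * 1000
    expect_equal(cm_from_discrimination(D, dea, a_bar, Ca), cm,
                 tolerance = 1e-10)
  }
  expect_equal(cm_from_discrimination(8.8, 25, 8.8, 300), 0)
  expect_error(cm_from_discrimination(5, 25, 8.8, 300), "diffusional floor")
  # enormous source enrichment drives the inferred Cm toward zero
  expect_lt(cm_from_discrimination(20, 1e5, 8.8, 300), 0.05)
})

test_that("gm_equilibrium is Fick's law with the expected magnitude", {
  expect_equal(gm_equilibrium(20, 100, 52.4), 0.4201681, tolerance = 1e-6)
  expect_equal(gm_equilibrium(0, 100, 50), 0)
  expect_equal(gm_equilibrium(20, 100, 76.2), 2 * gm_equilibrium(20, 100, 52.4),
               tolerance = 1e-10)
  expect_error(gm_equilibrium(20, 100, 120), "exceed")
})

test_that("CA-limited correction inflates gm and vanishes for fast CA", {
  expect_equal(gm_ca_corrected(0.42, 6.5), 0.5209924, tolerance = 1e-6)
  expect_equal(gm_ca_corrected(0.42, 6.5) / 0.42, 1.2404583, tolerance = 1e-6)
  expect_equal(gm_ca_corrected(0.42, 1e9), 0.42, tolerance = 1e-6)
  expect_true(all(gm_ca_corrected(c(0.42, 0.46, 0.55, 0.59), 6.5) >
                    c(0.42, 0.46, 0.55, 0.59)))
  expect_error(gm_ca_corrected(2.2, 6.5), "CA too slow")
})

test_that("delta arithmetic uses exact ratio products with bounded additive error", {
  # estimator operating point: chamber CO2 around -21 permil, source water CO2
  # equilibrated near +4 permil (CO2 scale)
  d_a <- -21.2; d_eq <- 3.9
  exact <- ((1 + d_eq / 1000) / (1 + d_a / 1000) - 1) * 1000
  additive <- d_eq - d_a
  # the discrepancy is exactly -additive * d_a/(1 + d_a) under ratio algebra
  bound <- 1.001 * abs(additive * (d_a / 1000) / (1 + d_a / 1000))
  expect_lt(abs(exact - additive), bound)
  expect_gt(abs(exact - additive), 0)
})

test_that("estimate_gm recovers the generating conductance exactly at zero noise", {
  for (gm in c(0.2, 0.42, 0.59, 1.0)) {
    rec <- gen_isotope_records(gm, cfg = quiet_cfg())
    est <- estimate_gm(rec)
    expect_equal(est$gm_mean, gm, tolerance = 1e-9)  # far inside the 0.5% bound
    expect_equal(est$gm_se, 0, tolerance = 1e-12)
    expect_equal(est$n_valid, 10)
  }
  # single noiseless reading inverts exactly too
  one <- gen_isotope_records(0.42, n_readings = 1, cfg = quiet_cfg())
  expect_equal(estimate_gm(one)$gm_mean, 0.42, tolerance = 1e-9)
})

test_that("finite-kCA data are underestimated in equilibrium mode and corrected in ca_limited mode", {
  rec <- gen_isotope_records(0.42, theta_mode = "finite_kCA", kCA = 6.5,
                             cfg = quiet_cfg())
  eq <- estimate_gm(rec, mode = "equilibrium")
  ca <- estimate_gm(rec, mode = "ca_limited", kCA = 6.5)
  expect_lt(eq$gm_mean, 0.42)
  expect_lt(abs(ca$gm_mean - 0.42), abs(eq$gm_mean - 0.42))
  expect_equal(ca$gm_mean, 0.42, tolerance = 1e-9)
  # near-infinite kCA makes the two modes coincide
  rec2 <- gen_isotope_records(0.42, theta_mode = "finite_kCA", kCA = 1e6,
                              cfg = quiet_cfg())
  expect_equal(estimate_gm(rec2, mode = "ca_limited", kCA = 1e6)$gm_mean,
               estimate_gm(rec2, mode = "equilibrium")$gm_mean,
               tolerance = 1e-5)
})

test_that("estimate_gm surfaces invalid records with reasons instead of dropping them", {
  rec <- gen_isotope_records(0.42, n_readings = 4, cfg = quiet_cfg())
  rec$delta_o[2] <- rec$delta_e[2] - 30   # discrimination below the floor
  est <- estimate_gm(rec)
  expect_equal(est$n_valid, 3)
  expect_equal(est$n_excluded, 1)
  expect_match(est$per_record$reason[2], "floor|Cm")
  rec$delta_o <- rec$delta_e - 30
  expect_error(estimate_gm(rec), "all records invalid")
  expect_error(estimate_gm(rec[0, ]), "no records")
  expect_error(estimate_gm(rec, mode = "ca_limited"), "kCA")
})

test_that("mean-record averaging mode inverts the averaged reading", {
  rec <- gen_isotope_records(0.42, cfg = sim_config(seed = 3))
  est <- estimate_gm(rec, average = "mean_record")
  expect_equal(est$n_valid, 1)
  expect_lt(abs(est$gm_mean - 0.42), 0.15)
  # at zero noise the two averaging modes agree
  rec0 <- gen_isotope_records(0.42, cfg = quiet_cfg())
  expect_equal(estimate_gm(rec0, average = "mean_record")$gm_mean,
               estimate_gm(rec0)$gm_mean, tolerance = 1e-9)
})

test_that("estimate metadata records the variant that produced the numbers", {
  rec <- gen_isotope_records(0.42, n_readings = 2, cfg = quiet_cfg())
  est <- estimate_gm(rec, mode = "ca_limited", kCA = 6.5)
  expect_equal(est$metadata$mode, "ca_limited")
  expect_match(est$metadata$ca_correction, "series-resistance")
  expect_equal(est$metadata$kCA, 6.5)
  expect_true(est$metadata$ternary)
})

test_that("isotope CSV round trip preserves the readings", {
  rec <- gen_isotope_records(0.42, n_readings = 3, cfg = sim_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(rec, path, type = "isotope")
  back <- read_isotope_csv(path)
  expect_equal(back$delta_o, rec$delta_o, tolerance = 1e-10)
  expect_equal(estimate_gm(back)$gm_mean, estimate_gm(rec)$gm_mean,
               tolerance = 1e-10)
  utils::write.csv(rec[, 1:4], path, row.names = FALSE)
  expect_error(read_isotope_csv(path), "missing required columns")
})
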