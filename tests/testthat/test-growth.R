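test_that("log transform floors the OD and round-trips through exp", {
  t <- seq(0, 30, by = 0.5)
  od <- 0.05 * 2^(t / 2)
  cu <- growth_curve(t, od)
  lt <- log_transform(cu)
  # exponential growth becomes a straight line of slope ln2/td
  slopes <- diff(lt$od) / diff(t)
  expect_equal(slopes, rep(log(2) / 2, length(slopes)), tolerance = 1e-10)
  expect_equal(exp(lt$od), pmax(od, 0.001), tolerance = 1e-12)
  # all-floor curve becomes constant
  flat <- log_transform(growth_curve(t, rep(0, length(t))), floor = 0.001)
  expect_true(all(flat$od == log(0.001)))
  expect_error(log_transform(cu, floor = 0), "positive")
})

test_that("stationary onset finds the logistic plateau and errors without one", {
  pair <- gen_growth_curves(1, cfg = quiet_cfg())
  ts <- stationary_onset(pair$untreated)
  # logistic with r=0.5, K=1.2, od0=0.05 flattens in the 12-18 h range;
  # tolerance of one detection window
  expect_gt(ts, 10)
  expect_lt(ts, 20)
  # monotone exponential never plateaus
  t <- seq(0, 24, by = 1 / 6)
  expo <- growth_curve(t, 0.01 * exp(0.3 * t))
  expect_error(stationary_onset(expo), "plateau")
  # flat curve degenerates to the first window end
  flat <- growth_curve(t, rep(0.05, length(t)))
  expect_equal(stationary_onset(flat, window = 2), t[t >= 2][1])
})

test_that("percent AUC anchors at 100 for identical curves and 0 for no growth", {
  pair <- gen_growth_curves(1, cfg = quiet_cfg())
  expect_equal(percent_auc(pair$untreated, pair$untreated), 100)
  flat <- gen_growth_curves(0, cfg = quiet_cfg())
  expect_equal(percent_auc(flat$treated, flat$untreated), 0, tolerance = 1e-8)
  # a control that fails to grow is an error, not a division
  t <- seq(0, 24, by = 1 / 6)
  dead <- growth_curve(t, rep(0.05, length(t)))
  expect_error(percent_auc(dead, dead), "plateau|grow")
})

test_that("percent AUC decreases with the delay of the treated curve", {
  pair <- gen_growth_curves(1, cfg = quiet_cfg())
  un <- pair$untreated
  pct <- vapply(c(0, 2, 4, 8), function(lag) {
    tr <- growth_curve(un$t, stats::approx(un$t + lag, un$od, xout = un$t,
                                           rule = 2)$y, condition = "treated")
    percent_auc(tr, un)
  }, numeric(1))
  expect_equal(pct[1], 100, tolerance = 1e-8)
  expect_true(all(diff(pct) < 0))
})

test_that("percent AUC is invariant to a shared positive OD scale", {
  pair <- gen_growth_curves(0.1, cfg = quiet_cfg())
  base <- percent_auc(pair$treated, pair$untreated)
  sc <- 3.7
  tr <- growth_curve(pair$treated$t, sc * pair$treated$od, condition = "treated")
  un <- growth_curve(pair$untreated$t, sc * pair$untreated$od)
  expect_equal(percent_auc(tr, un), base, tolerance = 1e-8)
})

test_that("values above 100 are reported, not clamped", {
  pair <- gen_growth_curves(1, cfg = quiet_cfg())
  un <- pair$untreated
  # treated culture growing faster than its control (same inoculum, higher r)
  t <- un$t
  od_fast <- 1.2 / (1 + ((1.2 - 0.05) / 0.05) * exp(-0.8 * t))
  tr <- growth_curve(t, od_fast, condition = "treated")
  expect_gt(percent_auc(tr, un), 100)
})

test_that("treated curves resampled onto a different time base still integrate", {
  pair <- gen_growth_curves(0.1, cfg = quiet_cfg())
  tr <- pair$treated
  coarse <- growth_curve(tr$t[seq(1, length(tr$t), by = 2)],
                         tr$od[seq(1, length(tr$t), by = 2)],
                         condition = "treated")
  expect_equal(percent_auc(coarse, pair$untreated),
               percent_auc(tr, pair$untreated), tolerance = 0.01)
})

test_that("trapezoid AUC converges to the analytic logistic integral", {
  r <- 0.5; K <- 1.2; n0 <- 0.05; T_end <- 15
  # integral of log(logistic/n0): closed form via the logistic primitive
  f <- function(t) log((K / (1 + ((K - n0) / n0) * exp(-r * t))) / n0)
  exact <- stats::integrate(f, 0, T_end, rel.tol = 1e-10)$value
  err <- vapply(c(1, 0.5, 0.1), function(dt) {
    t <- seq(0, T_end, by = dt)
    abs(pracma::trapz(t, f(t)) - exact)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("plate summary pairs wells explicitly and aggregates per strain", {
  mk <- function(seed, sf, strain, tw, uw) {
    p <- gen_growth_curves(sf, cfg = sim_config(seed = seed), strain = strain)
    p$treated$well_id <- tw; p$untreated$well_id <- uw
    list(p$treated, p$untreated)
  }
  curves <- c(mk(1, 0.5, "s1", "A1", "A2"), mk(2, 0.5, "s1", "B1", "B2"),
              mk(3, 0.05, "s2", "C1", "C2"))
  pairs <- data.frame(treated_well = c("A1", "B1", "C1"),
                      untreated_well = c("A2", "B2", "C2"))
  sm <- plate_summary(curves, pairs)
  expect_equal(nrow(sm), 2)
  s1 <- sm[sm$strain == "s1", ]
  s2 <- sm[sm$strain == "s2", ]
  expect_equal(s1$n, 2)
  expect_equal(s2$se_pct_auc, 0)
  expect_gt(s1$mean_pct_auc, s2$mean_pct_auc)
  expect_error(plate_summary(curves, data.frame(treated_well = "Z9",
                                                untreated_well = "A2")),
               "matched 0")
})

test_that("growth CSV round trip preserves wells", {
  pair <- gen_growth_curves(0.2, cfg = sim_config(seed = 11), strain = "s")
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(pair, path, type = "growth")
  back <- read_growth_csv(path)
  expect_equal(length(back), 2)
  ids <- vapply(back, function(cu) cu$well_id, character(1))
  expect_setequal(ids, c("T1", "U1"))
  expect_equal(back[[which(ids == "U1")]]$od, pair$untreated$od,
               tolerance = 1e-10)
})
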