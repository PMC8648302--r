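test_that("closed-form slope relation reproduces frozen arithmetic values", {
  # 0.42*250/(0.42*82+250) = 105/284.44
  expect_equal(initial_slope_from_gm(0.42, 250, 82), 0.3691464, tolerance = 1e-6)
  # 0.59*250/(0.59*82+250) = 147.5/298.38
  expect_equal(initial_slope_from_gm(0.59, 250, 82), 0.4943361, tolerance = 1e-6)
  # near-infinite gm approaches the PEPC-limited asymptote Vpmax/Kp
  expect_equal(initial_slope_from_gm(1e6, 250, 82), 250 / 82, tolerance = 1e-4)
  # low-gm limit: diffusion dominates, slope -> gm
  expect_equal(initial_slope_from_gm(1e-4, 250, 82), 1e-4, tolerance = 1e-4)
})

test_that("slope is bounded by min(gm, Vpmax/Kp) and increasing in gm", {
  g <- 10^seq(-3, 3, length.out = 60)
  s <- initial_slope_from_gm(g)
  expect_true(all(s > 0))
  expect_true(all(s < pmin(g, 250 / 82)))
  expect_true(all(diff(s) > 0))
})

test_that("gm_from_initial_slope inverts the slope relation to 10 significant digits", {
  g <- 10^seq(-3, 3, length.out = 41)
  back <- gm_from_initial_slope(initial_slope_from_gm(g))
  expect_equal(back, g, tolerance = 1e-10)
  # control-plant printed slope 0.41: gm = 102.5/216.38
  expect_equal(gm_from_initial_slope(0.41), 0.4737037, tolerance = 1e-6)
  expect_error(gm_from_initial_slope(250 / 82), "asymptote")
  expect_error(gm_from_initial_slope(-0.1), "positive")
})

test_that("domain errors are raised for non-positive kinetic inputs", {
  expect_error(initial_slope_from_gm(0), "positive")
  expect_error(initial_slope_from_gm(0.42, Vpmax = -1), "positive")
  expect_error(c4_params(Kp = 0), "positive")
  expect_error(c4_params(Rd = 1, Rm = 2), "Rm")
})

test_that("enzyme-limited assimilation is linear in Cm at low Cm and saturates", {
  p <- c4_params(Rd = 0, Rm = 0)
  expect_equal(enzyme_limited_assimilation(0, p), 0)
  # Cm = 1 ubar: Vp = 250/83 plus the small gbs leak-in term
  expect_equal(enzyme_limited_assimilation(1, p), 250 / 83 + p$gbs,
               tolerance = 1e-9)
  cm <- seq(0, 2000, by = 10)
  a <- enzyme_limited_assimilation(cm, p)
  expect_true(all(diff(a) >= 0))
  # saturation: capped by the Rubisco-limited rate
  expect_equal(a[length(a)], p$Vcmax - p$Rd)
  expect_error(enzyme_limited_assimilation(-5, p), "non-negative")
})

test_that("solve_A_from_Ci finds the supply-demand fixed point", {
  p <- c4_params(Rd = 0, Rm = 0)
  s0 <- solve_A_from_Ci(0, gm = 0.42, p)
  expect_equal(s0$A, 0)
  expect_equal(s0$Cm, 0)
  # residual of the fixed point vanishes
  s <- solve_A_from_Ci(c(10, 50, 200, 800), gm = 0.42, p)
  resid <- 0.42 * (s$Ci - s$Cm) - enzyme_limited_assimilation(s$Cm, p)
  expect_true(all(abs(resid) < 1e-9))
  # Cm within [0, Ci] when A >= 0
  expect_true(all(s$Cm >= 0 & s$Cm <= s$Ci))
  # gm -> infinity removes the diffusive drawdown: Cm -> Ci
  sb <- solve_A_from_Ci(100, gm = 1e7, p)
  expect_equal(sb$Cm, 100, tolerance = 1e-4)
})

test_that("finite-difference slope of the solved curve matches the closed form", {
  # window kept at 1-2 ubar: the closed form is the Ci -> 0 tangent, and PEPC
  # saturation curvature already costs ~2% by Ci = 20 ubar at high gm
  p <- c4_params(Rd = 0, Rm = 0)
  for (gm in c(0.2, 0.42, 0.59, 1.0)) {
    s <- solve_A_from_Ci(c(1, 2), gm, p)
    fd <- diff(s$A) / diff(s$Ci)
    expect_equal(fd, initial_slope_from_gm(gm), tolerance = 0.01)
  }
})

test_that("solved assimilation is monotone in Ci and in gm", {
  p <- c4_params(Rd = 1, Rm = 0.5)
  ci <- seq(0, 600, by = 20)
  a1 <- solve_A_from_Ci(ci, 0.3, p)$A
  a2 <- solve_A_from_Ci(ci, 0.6, p)$A
  expect_true(all(diff(a1) >= -1e-12))
  expect_true(all(diff(a2) >= -1e-12))
  # monotone in gm wherever the leaf is a net sink (A >= 0); below the
  # compensation point a larger gm only vents respiratory CO2 faster
  sink <- a1 >= 0
  expect_true(all((a2 - a1)[sink] >= -1e-12))
})

test_that("predicted_slope_curve evaluates the study conductances", {
  pc <- predicted_slope_curve(c(0.42, 0.46, 0.55, 0.59))
  expect_equal(pc$slope, oracle_slope(c(0.42, 0.46, 0.55, 0.59)),
               tolerance = 1e-12)
  # frozen arithmetic: 115/287.72 and 137.5/295.1 for the middle grid points
  expect_equal(pc$slope[2], 0.3996942, tolerance = 1e-6)
  expect_equal(pc$slope[3], 0.4659438, tolerance = 1e-6)
  expect_true(all(diff(pc$slope) > 0))
  # concave in gm
  expect_true(all(diff(diff(initial_slope_from_gm(seq(0.1, 2, by = 0.05)))) < 0))
  # singleton grid equals the scalar form; doubling Vpmax raises every slope
  expect_equal(predicted_slope_curve(0.42)$slope, initial_slope_from_gm(0.42))
  expect_true(all(predicted_slope_curve(c(0.42, 0.59), Vpmax = 500)$slope >
                    predicted_slope_curve(c(0.42, 0.59), Vpmax = 250)$slope))
  expect_error(predicted_slope_curve(numeric(0)), "non-empty")
})
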