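#' Simulation configuration
#'
#' Ground-truth environmental conditions and per-channel noise levels for the
#' forward simulators. Defaults follow the study's measurement conditions:
#' 2% O2, 380 umol mol-1 reference CO2, leaf temperature 25 degC, relative
#' humidity 55%, saturating irradiance. Noise defaults are typical instrument
#' precisions: 0.3 umol m-2 s-1 on A (IRGA), 0.3 permil on each d18O channel
#' (laser analyser), 1% multiplicative on stopped-flow fluorescence, 0.002 OD
#' on plate-reader absorbance.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   bit-reproducible. Channel substreams are derived deterministically.
#' @param sigma_A Gas-exchange noise on A, umol m-2 s-1.
#' @param sigma_delta Isotope noise on each delta channel, permil.
#' @param sigma_F Fractional (multiplicative) fluorescence noise.
#' @param sigma_OD Additive OD noise.
#' @param Tleaf Leaf temperature, degC.
#' @param Patm Atmospheric pressure, bar.
#' @param O2 Oxygen, percent.
#' @param co2_ref_ppm Reference-side CO2 mole fraction, umol mol-1.
#' @param RH Relative humidity, percent.
#' @param gsw Stomatal conductance to water vapor, mol m-2 s-1 (constant
#'   stomatal rule; the study found no genotype effect on gsw).
#' @param flow_umol_s Chamber molar flow, umol s-1.
#' @param leaf_area_m2 Leaf area in the chamber, m2.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sigma_A = 0.3, sigma_delta = 0.3,
                       sigma_F = 0.01, sigma_OD = 0.002,
                       Tleaf = 25, Patm = 1, O2 = 2, co2_ref_ppm = 380,
                       RH = 55, gsw = 0.45, flow_umol_s = 300,
                       leaf_area_m2 = 6e-4) {
  stopifnot(sigma_A >= 0, sigma_delta >= 0, sigma_F >= 0, sigma_OD >= 0)
  structure(list(seed = as.integer(seed), sigma_A = sigma_A,
                 sigma_delta = sigma_delta, sigma_F = sigma_F,
                 sigma_OD = sigma_OD, Tleaf = Tleaf, Patm = Patm, O2 = O2,
                 co2_ref_ppm = co2_ref_ppm, RH = RH, gsw = gsw,
                 flow_umol_s = flow_umol_s, leaf_area_m2 = leaf_area_m2),
            class = "sim_config")
}

# Deterministic per-channel substream: one seeded generator per run, channels
# offset by fixed primes so channels never share a stream.
set_substream <- function(cfg, channel) {
  offsets <- c(aci = 101L, isotope = 211L, stopped_flow = 307L, growth = 401L)
  set.seed((cfg$seed %% 1000000L) * 2011L + offsets[[channel]])
}

# Saturation vapor pressure (kPa), Buck-form; transpiration from constant gsw.
transpiration_rate <- function(cfg) {
  es <- 0.61365 * exp(17.502 * cfg$Tleaf / (240.97 + cfg$Tleaf))
  wi <- es / (cfg$Patm * 100)          # leaf-interior mole fraction
  wa <- (cfg$RH / 100) * wi            # chamber air
  cfg$gsw * (wi - wa)
}

#' Simulate an A-Ci gas-exchange curve
#'
#' Forward model: for each ambient CO2 setpoint, the intercellular CO2 follows
#' from a constant-gsw stomatal rule (`A = gsw/1.6 * (Ca - Ci)/Patm`) coupled
#' to [solve_A_from_Ci()], and Gaussian noise `sigma_A` is added to A.
#'
#' @param gm True mesophyll conductance, mol m-2 s-1 bar-1.
#' @param params A [c4_params()] object.
#' @param ca_grid Ambient CO2 setpoints, umol mol-1, in the 0-1600 range of the
#'   stepwise protocol.
#' @param cfg A [sim_config()] object.
#' @param genotype,replicate Metadata labels.
#' @return An [aci_curve()] object (partial pressures in ubar).
#' @export
gen_aci <- function(gm, params = c4_params(),
                    ca_grid = c(0, 25, 50, 75, 100, 125, 150, 200, 300, 400,
                                600, 800, 1100, 1400, 1600),
                    cfg = sim_config(), genotype = NA_character_,
                    replicate = NA_character_) {
  if (any(ca_grid < 0) || any(ca_grid > 1600))
    stop("ca_grid must lie within [0, 1600] ppm", call. = FALSE)
  if (any(diff(ca_grid) <= 0))
    stop("ca_grid must be strictly increasing", call. = FALSE)
  set_substream(cfg, "aci")
  gsc <- cfg$gsw / 1.6 / cfg$Patm      # stomatal CO2 conductance, mol m-2 s-1 bar-1
  one <- function(ca_ppm) {
    ca <- ca_ppm * cfg$Patm
    f <- function(ci) gsc * (ca - ci) - solve_A_from_Ci(ci, gm, params)$A
    hi <- ca + (params$Rd + 1) / gsc + 1
    ci <- if (f(0) <= 0) 0 else stats::uniroot(f, c(0, hi), tol = 1e-10)$root
    sol <- solve_A_from_Ci(ci, gm, params)
    c(Ca = ca, Ci = ci, A = sol$A)
  }
  grid <- t(vapply(ca_grid, one, numeric(3)))
  rec <- data.frame(Ca = grid[, "Ca"], Ci = grid[, "Ci"],
                    A = grid[, "A"] + stats::rnorm(nrow(grid), 0, cfg$sigma_A),
                    gsw = cfg$gsw, Tleaf = cfg$Tleaf, Patm = cfg$Patm)
  aci_curve(rec, genotype = genotype, replicate = replicate)
}

#' Simulate a batch of isotope-exchange readings
#'
#' Forward chain: the steady-state operating point (A, Ci) is solved from the
#' C4 model and the constant-gsw stomatal rule at the configured reference CO2;
#' `Cm = Ci - A/gm` gives the exchange-site CO2; the supply relation (with the
#' same ternary correction the estimator applies) gives the observed
#' discrimination; and the outlet delta is back-calculated from the
#' open-chamber mass balance, so the generator is the exact inverse of
#' [estimate_gm()] at zero noise. Under `theta_mode = "finite_kCA"` the
#' isotopic exchange-site signal reflects incomplete equilibration, modelled as
#' the series-resistance apparent conductance `1/(1/gm + 3/kCA)`; assimilation
#' itself still uses the true `gm`.
#'
#' Gaussian noise `cfg$sigma_delta` is added independently to every delta
#' channel (inlet CO2, outlet CO2, vapor) of every reading.
#'
#' @param gm_true True mesophyll conductance, mol m-2 s-1 bar-1.
#' @param theta_mode `"full_equilibrium"` or `"finite_kCA"`.
#' @param kCA CA hydration constant, mol m-2 s-1 bar-1 (required for
#'   `"finite_kCA"`).
#' @param water_delta d18O of chamber water vapor, permil VSMOW.
#' @param n_readings Number of readings (the study protocol took 10 per leaf).
#' @param cfg A [sim_config()] object.
#' @param params A [c4_params()] object.
#' @param consts A [fractionation_constants()] object.
#' @param delta_e_co2 d18O of inlet CO2, permil on the CO2 scale.
#' @param ternary Include the ternary correction in the forward model.
#' @return data.frame of readings in the [estimate_gm()] dialect.
#' @export
gen_isotope_records <- function(gm_true,
                                theta_mode = c("full_equilibrium", "finite_kCA"),
                                kCA = NULL, water_delta = -5, n_readings = 10,
                                cfg = sim_config(), params = c4_params(),
                                consts = fractionation_constants(),
                                delta_e_co2 = -25, ternary = TRUE) {
  theta_mode <- match.arg(theta_mode)
  if (gm_true <= 0) stop("gm_true must be positive", call. = FALSE)
  if (theta_mode == "finite_kCA" && is.null(kCA))
    stop("theta_mode = 'finite_kCA' requires kCA", call. = FALSE)
  set_substream(cfg, "isotope")

  gsc <- cfg$gsw / 1.6 / cfg$Patm
  Ce <- cfg$co2_ref_ppm
  # steady-state operating point: A consistent with chamber drawdown, stomata
  # and the C4 model at the true gm
  ci_of_A <- function(A) (Ce - A * cfg$leaf_area_m2 * 1e6 / cfg$flow_umol_s) *
    cfg$Patm - A / gsc
  f <- function(A) A - solve_A_from_Ci(max(ci_of_A(A), 0), gm_true, params)$A
  A <- stats::uniroot(f, c(0, params$Vpr + params$Vcmax), tol = 1e-12)$root
  Co <- Ce - A * cfg$leaf_area_m2 * 1e6 / cfg$flow_umol_s
  Ca <- Co * cfg$Patm
  Ci <- Ca - A / gsc
  Cm_true <- Ci - A / gm_true
  if (Cm_true <= 0)
    stop(sprintf("infeasible operating point: Cm = %.2f ubar <= 0", Cm_true),
         call. = FALSE)
  gm_app <- if (theta_mode == "finite_kCA") 1 / (1 / gm_true + 3 / kCA) else gm_true
  Cm_iso <- Ci - A / gm_app
  if (Cm_iso <= 0)
    stop("infeasible operating point for the isotopic signal (Cm_iso <= 0)",
         call. = FALSE)

  E <- transpiration_rate(cfg)
  t_tern <- if (ternary) ternary_factor(E, cfg$gsw, consts$a_bar) else 0
  d_lw <- vsmow_to_co2_scale(
    frac_to_permil((1 + permil_to_frac(water_delta)) *
                     alpha_liquid_vapor(cfg$Tleaf) - 1), consts)
  d_eq <- permil_to_frac(equilibrated_source_delta(d_lw, cfg$Tleaf, consts))
  de <- permil_to_frac(delta_e_co2)
  ab <- permil_to_frac(consts$a_bar)
  xi <- Ce / (Ce - Co)

  # outlet delta from the supply relation; Delta_ea depends on delta_o, so
  # solve the small fixed point by iteration (contraction, converges fast)
  do <- de
  for (it in 1:100) {
    Dea <- (1 + d_eq) / (1 + do) - 1
    Dsup <- ab + (Cm_iso / (Ca - Cm_iso)) * Dea
    Dobs <- Dsup / (1 - t_tern)
    do_new <- (Dobs + xi * de * (1 + Dobs)) / (xi * (1 + Dobs) - Dobs)
    if (abs(do_new - do) < 1e-16) { do <- do_new; break }
    do <- do_new
  }

  noise <- function(n) stats::rnorm(n, 0, cfg$sigma_delta)
  n <- n_readings
  data.frame(
    Ce_ppm = rep(Ce, n), Co_ppm = rep(Co, n),
    delta_e = delta_e_co2 + noise(n),
    delta_o = frac_to_permil(do) + noise(n),
    delta_vap_in = water_delta + noise(n),
    delta_vap_out = water_delta + noise(n),
    flow_umol_s = cfg$flow_umol_s, leaf_area_m2 = cfg$leaf_area_m2,
    Tleaf = cfg$Tleaf, Patm_bar = cfg$Patm,
    A = A, Ci_ppm = Ci / cfg$Patm, gsw = cfg$gsw, E = E)
}

#' Simulate a stopped-flow acidification trace
#'
#' Exponential fluorescence quench with rate constant `k = P * 6/diameter`,
#' sampled on a uniform grid over the acquisition window, with multiplicative
#' Gaussian noise `cfg$sigma_F`.
#'
#' @param P True membrane CO2 permeability, m s-1.
#' @param geom A [cell_geometry()] object.
#' @param duration Acquisition window, s. Default 0.2 s.
#' @param n_samples Samples across the window.
#' @param cfg A [sim_config()] object.
#' @param amplitude,baseline Trace shape, arbitrary fluorescence units.
#' @return data.frame with columns `t` (s) and `F` (a.u.).
#' @export
gen_stopped_flow <- function(P, geom = cell_geometry(), duration = 0.2,
                             n_samples = 200, cfg = sim_config(),
                             amplitude = 1, baseline = 0.2) {
  if (P <= 0) stop("P must be positive", call. = FALSE)
  set_substream(cfg, "stopped_flow")
  k <- P * surface_to_volume(geom)
  t <- seq(0, duration, length.out = n_samples)
  f0 <- baseline + amplitude * exp(-k * t)
  data.frame(t = t, F = f0 * (1 + stats::rnorm(n_samples, 0, cfg$sigma_F)))
}

#' Simulate a paired freeze-thaw growth experiment
#'
#' Untreated control: logistic growth from inoculum `od0`. Treated: only the
#' surviving fraction of the inoculum grows (logistic from
#' `od0 * survival_frac`), while killed cells still scatter light and
#' contribute a constant `od0 * (1 - survival_frac)` - so both wells start at
#' the same OD and freeze-thaw damage expresses itself as a longer effective
#' lag (about `ln(1/survival_frac)/r` hours). Sampling every 10 min by
#' default; additive OD noise.
#'
#' @param survival_frac Fraction of the inoculum surviving freeze-thaw, in
#'   [0, 1].
#' @param r Logistic growth rate, h-1.
#' @param K Carrying capacity, OD units.
#' @param od0 Untreated inoculum OD.
#' @param duration Run length, h (study runs spanned 24-30 h).
#' @param dt Sampling interval, h. Default 1/6 (10 min).
#' @param cfg A [sim_config()] object.
#' @param strain Strain label.
#' @return List with `treated` and `untreated` [growth_curve()] objects.
#' @export
gen_growth_curves <- function(survival_frac, r = 0.5, K = 1.2, od0 = 0.05,
                              duration = 30, dt = 1 / 6, cfg = sim_config(),
                              strain = NA_character_) {
  if (survival_frac < 0 || survival_frac > 1)
    stop("survival_frac must be in [0, 1]", call. = FALSE)
  set_substream(cfg, "growth")
  t <- seq(0, duration, by = dt)
  logistic <- function(n0) {
    if (n0 <= 0) return(rep(0, length(t)))
    K / (1 + ((K - n0) / n0) * exp(-r * t))
  }
  add_noise <- function(od) pmax(od + stats::rnorm(length(od), 0, cfg$sigma_OD), 0)
  od_treated <- od0 * (1 - survival_frac) + logistic(od0 * survival_frac)
  list(
    treated = growth_curve(t, add_noise(od_treated),
                           well_id = "T1", strain = strain, condition = "treated"),
    untreated = growth_curve(t, add_noise(logistic(od0)),
                             well_id = "U1", strain = strain,
                             condition = "untreated"))
}

#' Write simulated records in the CSV dialects the readers consume
#'
#' @param x An [aci_curve()], isotope-record data.frame, stopped-flow trace, or
#'   list of [growth_curve()] objects.
#' @param path Output CSV path.
#' @param type One of `"aci"`, `"isotope"`, `"stopped_flow"`, `"growth"`.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(x, path,
                              type = c("aci", "isotope", "stopped_flow", "growth")) {
  type <- match.arg(type)
  df <- switch(type,
    aci = {
      r <- x$records
      data.frame(Ca_ppm = r$Ca / r$Patm, Ci_ppm = r$Ci / r$Patm, A = r$A,
                 gsw = r$gsw, Tleaf = r$Tleaf, Patm_bar = r$Patm)
    },
    isotope = x,
    stopped_flow = data.frame(t_s = x$t, F = x$F),
    growth = do.call(rbind, lapply(x, function(cu)
      data.frame(well_id = cu$well_id, strain = cu$strain,
                 condition = cu$condition, t_h = cu$t, od650 = cu$od))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
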