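# All delta/Delta arithmetic is carried out on fractional ratios (permil/1000)
# with exact ratio products, never additive approximations; public interfaces
# take and return permil.

permil_to_frac <- function(x) x / 1000
frac_to_permil <- function(x) x * 1000

#' Fractionation constants for C18O16O discrimination analysis
#'
#' Physical constants of the oxygen-isotope gas-exchange method, collected in
#' one overridable object so every estimate records which constants produced it.
#'
#' @param a_bar Weighted diffusional fractionation of C18O16O through boundary
#'   layer and stomata, permil. Default 8.8 permil, the diffusional
#'   fractionation of C18O16O in air with boundary-layer weighting neglected.
#' @param eps_w_coeffs Coefficients `c(a, b)` of the CO2-water 18O equilibrium
#'   fractionation `eps_w(T) = a/T_K - b` in permil with `T_K` in kelvin. The
#'   default pins `eps_w(25 degC) = 41.2` permil.
#' @param vsmow_to_co2_shift Scale shift, permil, converting water-referenced
#'   (VSMOW) deltas onto the CO2 working scale of the laser analyser:
#'   `1 + d_co2 = (1 + d_vsmow) / (1 + shift/1000)`. A single explicit constant,
#'   default 41.47 permil.
#' @return An object of class `frac_constants`.
#' @export
fractionation_constants <- function(a_bar = 8.8,
                                    eps_w_coeffs = c(17604, 17.844),
                                    vsmow_to_co2_shift = 41.47) {
  if (a_bar <= 0 || a_bar >= 20)
    stop("a_bar must lie in (0, 20) permil", call. = FALSE)
  ew25 <- eps_w_coeffs[1] / 298.15 - eps_w_coeffs[2]
  if (ew25 <= 35 || ew25 >= 50)
    stop(sprintf("eps_w(25 degC) = %.2f permil is outside the plausible (35, 50) range",
                 ew25), call. = FALSE)
  structure(list(a_bar = a_bar, eps_w_coeffs = eps_w_coeffs,
                 vsmow_to_co2_shift = vsmow_to_co2_shift),
            class = "frac_constants")
}

#' CO2-water 18O equilibrium fractionation as a function of temperature
#'
#' Temperature dependence of the equilibrium 18O fractionation between CO2 and
#' liquid water, `eps_w(T) = a/T_K - b` (permil), decreasing with temperature.
#'
#' @param Tleaf Leaf temperature, degC (0 < Tleaf < 50).
#' @param consts A [fractionation_constants()] object.
#' @return eps_w, permil.
#' @export
epsilon_w <- function(Tleaf, consts = fractionation_constants()) {
  if (any(Tleaf <= 0) || any(Tleaf >= 50))
    stop("Tleaf must be in (0, 50) degC", call. = FALSE)
  consts$eps_w_coeffs[1] / (Tleaf + 273.15) - consts$eps_w_coeffs[2]
}

# Equilibrium liquid-vapor 18O fractionation factor alpha (liquid/vapor > 1),
# Majoube-form polynomial in absolute temperature.
alpha_liquid_vapor <- function(Tleaf) {
  TK <- Tleaf + 273.15
  exp(1137 / TK^2 - 0.4156 / TK - 2.0667e-3)
}

# VSMOW-referenced delta onto the CO2 working scale (exact ratio algebra).
vsmow_to_co2_scale <- function(delta_vsmow_permil, consts = fractionation_constants()) {
  s <- permil_to_frac(consts$vsmow_to_co2_shift)
  frac_to_permil((1 + permil_to_frac(delta_vsmow_permil)) / (1 + s) - 1)
}

#' Observed photosynthetic C18O16O discrimination from open-chamber records
#'
#' Open-chamber mass-balance discrimination
#' \deqn{\Delta_{obs} = \xi (\delta_o - \delta_e) /
#'       (1 + \delta_o - \xi(\delta_o - \delta_e)),\quad \xi = C_e/(C_e - C_o)}
#' with deltas as fractional ratios internally. Depends only on `xi` and the
#' deltas, so it is invariant under rescaling of the absolute CO2 mole
#' fractions.
#'
#' @param Ce,Co CO2 mole fraction entering / leaving the chamber, umol mol-1.
#' @param delta_e,delta_o d18O of CO2 entering / leaving, permil (CO2 scale).
#' @return Observed discrimination, permil. Vectorised.
#' @examples
#' observed_discrimination(400, 360, 0, 4)  # 41.49 permil
#' @export
observed_discrimination <- function(Ce, Co, delta_e, delta_o) {
  if (any(Ce == Co))
    stop("no net CO2 drawdown: Ce equals Co", call. = FALSE)
  xi <- Ce / (Ce - Co)
  de <- permil_to_frac(delta_e)
  do <- permil_to_frac(delta_o)
  frac_to_permil(xi * (do - de) / (1 + do - xi * (do - de)))
}

#' d18O of CO2 in isotopic equilibrium with a given water pool
#'
#' Exact ratio composition of the water delta with the temperature-dependent
#' CO2-water equilibrium fractionation:
#' `(1 + d_eq) = (1 + d_water) * (1 + eps_w(T))`. Both deltas are on the common
#' CO2 working scale (convert VSMOW water values first, see
#' [fractionation_constants()]).
#'
#' @param delta_water d18O of the equilibrating water, permil, CO2 scale.
#' @param Tleaf Leaf temperature, degC.
#' @param consts A [fractionation_constants()] object.
#' @return d18O of equilibrated CO2, permil.
#' @examples
#' equilibrated_source_delta(0, 25)   # = eps_w(25) = 41.2
#' @export
equilibrated_source_delta <- function(delta_water, Tleaf,
                                      consts = fractionation_constants()) {
  ew <- permil_to_frac(epsilon_w(Tleaf, consts))
  frac_to_permil((1 + permil_to_frac(delta_water)) * (1 + ew) - 1)
}

#' Mesophyll CO2 partial pressure from observed discrimination
#'
#' Inverts the supply relation
#' `Delta_obs = a_bar + (Cm/(Ca - Cm)) * Delta_ea` for the CO2 partial pressure
#' at the mesophyll exchange site:
#' `Cm = Ca (Delta_obs - a_bar) / (Delta_obs - a_bar + Delta_ea)`.
#' `Delta_ea` is the 18O enrichment of CO2 equilibrated with evaporating-site
#' water relative to the chamber CO2.
#'
#' @param delta_obs Observed discrimination, permil.
#' @param delta_ea Source-water CO2 enrichment over chamber CO2, permil.
#' @param a_bar Diffusional fractionation, permil.
#' @param Ca CO2 partial pressure around the leaf, ubar.
#' @return Cm, ubar; errors if the discrimination sits at or below the
#'   diffusional floor, or if the inversion leaves (0, Ca).
#' @export
cm_from_discrimination <- function(delta_obs, delta_ea, a_bar, Ca) {
  D <- permil_to_frac(delta_obs)
  Dea <- permil_to_frac(delta_ea)
  ab <- permil_to_frac(a_bar)
  if (D < ab)
    stop("discrimination below diffusional floor (Delta_obs < a_bar)", call. = FALSE)
  cm <- Ca * (D - ab) / (D - ab + Dea)
  if (!is.finite(cm) || cm < 0 || cm >= Ca)
    stop(sprintf("inverted Cm = %.3f ubar outside (0, Ca = %g)", cm, Ca),
         call. = FALSE)
  cm
}

#' Mesophyll conductance under full isotopic equilibrium
#'
#' `g_m = A / (Ci - Cm)`: Fick's law across the airspace-to-cytosol path, valid
#' when carbonic anhydrase fully equilibrates the 18O of CO2 with cytosolic
#' water so that the discrimination-derived `Cm` is the true exchange-site
#' partial pressure.
#'
#' @param A Net assimilation, umol m-2 s-1.
#' @param Ci Intercellular CO2 partial pressure, ubar.
#' @param Cm Mesophyll CO2 partial pressure, ubar (must be below `Ci`).
#' @return g_m, mol m-2 s-1 bar-1.
#' @export
gm_equilibrium <- function(A, Ci, Cm) {
  if (Ci <= Cm)
    stop(sprintf("Ci (%.2f) must exceed Cm (%.2f) for a positive drawdown",
                 Ci, Cm), call. = FALSE)
  A / (Ci - Cm)
}

#' Carbonic anhydrase limited correction to an equilibrium g_m estimate
#'
#' When CA activity is finite, 18O equilibration between CO2 and cytosolic
#' water is incomplete and the full-equilibrium estimate understates g_m. The
#' default correction treats incomplete equilibration as a series resistance,
#' `1/g_m = 1/g_m_eq - 3/k_CA` (the factor 3 reflecting the three-oxygen
#' exchange stoichiometry of the hydration cycle); it is an approximation to
#' the full CA-limited inversion, always >= the equilibrium value, and
#' converges to it as `k_CA` grows.
#'
#' @param gm_eq Full-equilibrium estimate, mol m-2 s-1 bar-1.
#' @param kCA CA hydration rate constant, mol m-2 s-1 bar-1 (study value 6.5).
#' @return Corrected g_m, mol m-2 s-1 bar-1.
#' @examples
#' gm_ca_corrected(0.42, 6.5)  # 0.521, ratio 1.24
#' @export
gm_ca_corrected <- function(gm_eq, kCA = 6.5) {
  if (any(!is.finite(gm_eq)) || any(gm_eq <= 0))
    stop("gm_eq must be finite and positive", call. = FALSE)
  if (kCA <= 0) stop("kCA must be positive", call. = FALSE)
  if (any(gm_eq >= kCA / 3))
    stop("CA too slow for correction - full model required (gm_eq >= kCA/3)",
         call. = FALSE)
  1 / (1 / gm_eq - 3 / kCA)
}

# Ternary (transpiration) correction factor t = (1 + a_bar) E / (2 g_ac),
# with the CO2 diffusion conductance taken as gsw/1.6 (boundary layer
# neglected). Deltas in fractions.
ternary_factor <- function(E, gsw, a_bar_permil) {
  gac <- gsw / 1.6
  (1 + permil_to_frac(a_bar_permil)) * E / (2 * gac)
}

# One-record inversion chain shared by estimate_gm(); deltas in permil in, gm out.
invert_isotope_record <- function(rec, consts, ternary = TRUE) {
  dobs <- observed_discrimination(rec$Ce_ppm, rec$Co_ppm, rec$delta_e, rec$delta_o)
  t <- if (ternary) ternary_factor(rec$E, rec$gsw, consts$a_bar) else 0
  dobs_adj <- frac_to_permil(permil_to_frac(dobs) * (1 - t))
  # evaporating-site water: steady-state equilibrium with measured chamber vapor
  d_lw_vsmow <- frac_to_permil(
    (1 + permil_to_frac(rec$delta_vap_out)) * alpha_liquid_vapor(rec$Tleaf) - 1)
  d_lw <- vsmow_to_co2_scale(d_lw_vsmow, consts)
  d_eq <- equilibrated_source_delta(d_lw, rec$Tleaf, consts)
  delta_ea <- frac_to_permil(
    (1 + permil_to_frac(d_eq)) / (1 + permil_to_frac(rec$delta_o)) - 1)
  Ca <- rec$Co_ppm * rec$Patm_bar
  Cm <- cm_from_discrimination(dobs_adj, delta_ea, consts$a_bar, Ca)
  Ci <- rec$Ci_ppm * rec$Patm_bar
  gm <- gm_equilibrium(rec$A, Ci, Cm)
  list(Delta_obs = dobs, Delta_ea = delta_ea, Ca = Ca, Ci = Ci, Cm = Cm, gm = gm)
}

#' Estimate mesophyll conductance from isotope-exchange records
#'
#' Runs the full inversion chain per reading: observed discrimination ->
#' evaporating-site water -> equilibrated CO2 delta -> `Delta_ea` ->
#' [cm_from_discrimination()] -> [gm_equilibrium()], optionally followed by the
#' CA-limited correction [gm_ca_corrected()]. Invalid readings are excluded
#' with their reasons recorded, never silently dropped.
#'
#' @param records data.frame of isotope-exchange readings with columns
#'   `Ce_ppm, Co_ppm, delta_e, delta_o, delta_vap_in, delta_vap_out,
#'   flow_umol_s, leaf_area_m2, Tleaf, Patm_bar, A, Ci_ppm, gsw, E`
#'   (deltas in permil; vapor deltas on VSMOW, CO2 deltas on the CO2 scale).
#' @param consts A [fractionation_constants()] object.
#' @param mode `"equilibrium"` (full isotopic equilibrium) or `"ca_limited"`.
#' @param kCA CA hydration rate constant, mol m-2 s-1 bar-1; required for
#'   `mode = "ca_limited"`.
#' @param ternary Apply the ternary (transpiration) correction. Default TRUE.
#' @param average `"per_reading"` (default) inverts each reading and averages
#'   the per-reading g_m; `"mean_record"` averages the readings first and
#'   inverts once.
#' @return An object of class `gm_estimate`: per-record table, `gm_mean`,
#'   `gm_se`, counts, and a metadata list recording mode, constants and the
#'   CA-correction variant used.
#' @export
estimate_gm <- function(records, consts = fractionation_constants(),
                        mode = c("equilibrium", "ca_limited"), kCA = NULL,
                        ternary = TRUE,
                        average = c("per_reading", "mean_record")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  if (mode == "ca_limited" && is.null(kCA))
    stop("mode = 'ca_limited' requires kCA", call. = FALSE)
  if (nrow(records) < 1) stop("no records supplied", call. = FALSE)

  if (average == "mean_record") {
    records <- as.data.frame(as.list(colMeans(records[vapply(records, is.numeric,
                                                             logical(1))])))
  }

  n <- nrow(records)
  res <- data.frame(reading = seq_len(n), Delta_obs = NA_real_, Cm = NA_real_,
                    gm = NA_real_, valid = FALSE, reason = NA_character_)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    out <- tryCatch(invert_isotope_record(rec, consts, ternary = ternary),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      res$reason[i] <- out
      next
    }
    gm_i <- out$gm
    if (mode == "ca_limited") {
      gm_i <- tryCatch(gm_ca_corrected(gm_i, kCA),
                       error = function(e) conditionMessage(e))
      if (is.character(gm_i)) {
        res$reason[i] <- gm_i
        next
      }
    }
    res$Delta_obs[i] <- out$Delta_obs
    res$Cm[i] <- out$Cm
    res$gm[i] <- gm_i
    res$valid[i] <- TRUE
  }
  ok <- res$valid
  if (!any(ok))
    stop("all records invalid:\n", paste0("  reading ", res$reading, ": ",
                                          res$reason, collapse = "\n"),
         call. = FALSE)
  gms <- res$gm[ok]
  structure(list(
    per_record = res,
    gm_mean = mean(gms),
    gm_se = if (length(gms) > 1) stats::sd(gms) / sqrt(length(gms)) else 0,
    n_valid = sum(ok), n_excluded = sum(!ok),
    metadata = list(mode = mode, kCA = kCA, ternary = ternary,
                    a_bar = consts$a_bar,
                    eps_w_25 = epsilon_w(25, consts),
                    vsmow_to_co2_shift = consts$vsmow_to_co2_shift,
                    ca_correction = if (mode == "ca_limited")
                      "series-resistance approximation (1/gm = 1/gm_eq - 3/kCA)"
                    else NA_character_,
                    averaging = average)),
    class = "gm_estimate")
}

#' @export
print.gm_estimate <- function(x, ...) {
  cat(sprintf("g_m (%s mode): %.4f +/- %.4f mol m-2 s-1 bar-1 (n = %d valid, %d excluded)\n",
              x$metadata$mode, x$gm_mean, x$gm_se, x$n_valid, x$n_excluded))
  if (!is.na(x$metadata$ca_correction))
    cat("  CA correction:", x$metadata$ca_correction, "\n")
  invisible(x)
}

#' Read an isotope-exchange CSV
#'
#' Comma-separated dialect with header
#' `Ce_ppm,Co_ppm,delta_e,delta_o,delta_vap_in,delta_vap_out,flow_umol_s,leaf_area_m2,Tleaf,Patm_bar,A,Ci_ppm,gsw,E`.
#'
#' @param path CSV file path.
#' @return data.frame of readings suitable for [estimate_gm()].
#' @export
read_isotope_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("Ce_ppm", "Co_ppm", "delta_e", "delta_o", "delta_vap_out",
           "Tleaf", "Patm_bar", "A", "Ci_ppm", "gsw", "E")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}
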