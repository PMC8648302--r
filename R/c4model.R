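#' Kinetic parameter set for the enzyme-limited C4 model
#'
#' Bundles the kinetic constants of the enzyme-limited C4 photosynthesis model.
#' `Vpmax` and `Kp` govern the PEP-carboxylase (PEPC) carboxylation that sets the
#' initial slope of the A-Ci curve; the remaining constants shape the saturated
#' part of the curve and the respiratory offsets.
#'
#' Defaults: `Vpmax = 250` umol m-2 s-1 and `Kp = 82` ubar are the values used for
#' the slope-vs-g_m comparison in this workflow; `Vpr`, `Vcmax`, `gbs`, `Rd`, `Rm`
#' are a named default set drawn from the standard C4 modelling literature, since
#' only the slope relation requires `Vpmax` and `Kp`. `Rm` defaults to 0 so that
#' the closed-form slope relation (which carries no mesophyll-respiration term)
#' and the full model agree in the linear regime.
#'
#' @param Vpmax Maximal PEPC activity, umol m-2 s-1.
#' @param Kp Michaelis constant of PEPC for CO2, ubar.
#' @param Vpr PEP-regeneration-limited cap on the carboxylation rate, umol m-2 s-1.
#' @param Vcmax Maximal Rubisco carboxylation rate, umol m-2 s-1.
#' @param gbs Bundle-sheath conductance to CO2, mol m-2 s-1 bar-1.
#' @param Rd Day respiration, umol m-2 s-1.
#' @param Rm Mesophyll fraction of `Rd`, umol m-2 s-1. Must not exceed `Rd`.
#' @return An object of class `c4_params` (a named list).
#' @examples
#' p <- c4_params()
#' p$Vpmax / p$Kp   # PEPC-limited slope asymptote, mol m-2 s-1 bar-1
#' @export
c4_params <- function(Vpmax = 250, Kp = 82, Vpr = 80, Vcmax = 35,
                      gbs = 0.003, Rd = 0, Rm = 0) {
  stopifnot(is.numeric(Vpmax), is.numeric(Kp))
  if (Vpmax <= 0 || Kp <= 0 || Vpr <= 0 || Vcmax <= 0 || gbs <= 0)
    stop("Vpmax, Kp, Vpr, Vcmax and gbs must be strictly positive", call. = FALSE)
  if (Rd < 0 || Rm < 0) stop("Rd and Rm must be non-negative", call. = FALSE)
  if (Rm > Rd) stop("Rm cannot exceed Rd", call. = FALSE)
  structure(list(Vpmax = Vpmax, Kp = Kp, Vpr = Vpr, Vcmax = Vcmax,
                 gbs = gbs, Rd = Rd, Rm = Rm),
            class = "c4_params")
}

#' @export
print.c4_params <- function(x, ...) {
  cat("Enzyme-limited C4 model parameters:\n")
  cat(sprintf("  Vpmax = %g umol m-2 s-1, Kp = %g ubar (PEPC)\n", x$Vpmax, x$Kp))
  cat(sprintf("  Vpr = %g, Vcmax = %g umol m-2 s-1\n", x$Vpr, x$Vcmax))
  cat(sprintf("  gbs = %g mol m-2 s-1 bar-1, Rd = %g, Rm = %g umol m-2 s-1\n",
              x$gbs, x$Rd, x$Rm))
  invisible(x)
}

#' Initial slope of the A-Ci curve for a given mesophyll conductance
#'
#' Closed-form relation between mesophyll conductance `gm` and the initial slope
#' of the CO2-response curve of a C4 leaf:
#' \deqn{dA/dC_i = g_m V_{pmax} / (g_m K_p + V_{pmax})}
#' i.e. the series combination of the membrane diffusion conductance and the
#' PEPC carboxylation efficiency `Vpmax/Kp`. With `A` in umol m-2 s-1 and partial
#' pressures in ubar, the slope is numerically in mol m-2 s-1 bar-1, the same
#' units as `gm`.
#'
#' @param gm Mesophyll conductance, mol m-2 s-1 bar-1. May be vectorised.
#' @param Vpmax Maximal PEPC activity, umol m-2 s-1.
#' @param Kp Michaelis constant of PEPC for CO2, ubar.
#' @return Initial slope dA/dCi, mol m-2 s-1 bar-1; always strictly between 0 and
#'   `min(gm, Vpmax/Kp)` and strictly increasing in `gm`.
#' @examples
#' initial_slope_from_gm(0.42)  # 0.3692
#' @export
initial_slope_from_gm <- function(gm, Vpmax = 250, Kp = 82) {
  if (any(!is.finite(gm)) || any(gm <= 0))
    stop("gm must be finite and strictly positive", call. = FALSE)
  if (Vpmax <= 0 || Kp <= 0)
    stop("Vpmax and Kp must be strictly positive", call. = FALSE)
  gm * Vpmax / (gm * Kp + Vpmax)
}

#' Mesophyll conductance from a measured initial slope
#'
#' Algebraic inverse of [initial_slope_from_gm()]. The slope cannot exceed the
#' PEPC-limited asymptote `Vpmax/Kp` reached as `gm` grows without bound.
#'
#' @param slope Initial slope of the A-Ci curve, mol m-2 s-1 bar-1.
#' @inheritParams initial_slope_from_gm
#' @return Mesophyll conductance, mol m-2 s-1 bar-1.
#' @examples
#' gm_from_initial_slope(0.41)  # control-magnitude slope -> gm ~ 0.47
#' @export
gm_from_initial_slope <- function(slope, Vpmax = 250, Kp = 82) {
  if (Vpmax <= 0 || Kp <= 0)
    stop("Vpmax and Kp must be strictly positive", call. = FALSE)
  if (any(!is.finite(slope)) || any(slope <= 0))
    stop("slope must be finite and strictly positive", call. = FALSE)
  if (any(slope >= Vpmax / Kp))
    stop(sprintf("slope exceeds PEPC-limited asymptote Vpmax/Kp = %.4f",
                 Vpmax / Kp), call. = FALSE)
  slope * Vpmax / (Vpmax - slope * Kp)
}

#' Enzyme-limited net assimilation at a given mesophyll CO2 partial pressure
#'
#' Enzyme-limited C4 assimilation as the minimum of the PEPC-limited supply of
#' CO2 to the bundle sheath and the Rubisco-limited consumption there:
#' \itemize{
#'   \item PEP carboxylation `Vp = min(Cm*Vpmax/(Cm+Kp), Vpr)`;
#'   \item PEPC-limited branch `Ap = Vp + gbs*Cm - Rm` (mesophyll CO2 balance,
#'     with bundle-sheath conductance `gbs` carrying the direct diffusion term);
#'   \item Rubisco-limited branch `Ar = Vcmax - Rd` (CO2-saturated bundle sheath).
#' }
#' Competing limitations are resolved by taking the minimum rate. At small `Cm`
#' with `Rm = 0` this reduces to `A ~ Cm*Vpmax/Kp`.
#'
#' @param Cm Mesophyll (cytosolic) CO2 partial pressure, ubar. Vectorised.
#' @param params A [c4_params()] object.
#' @return Net assimilation A, umol m-2 s-1.
#' @export
enzyme_limited_assimilation <- function(Cm, params = c4_params()) {
  stopifnot(inherits(params, "c4_params"))
  if (any(!is.finite(Cm)) || any(Cm < 0))
    stop("Cm must be finite and non-negative", call. = FALSE)
  Vp <- pmin(Cm * params$Vpmax / (Cm + params$Kp), params$Vpr)
  Ap <- Vp + params$gbs * Cm - params$Rm
  Ar <- params$Vcmax - params$Rd
  pmin(Ap, Ar)
}

#' Solve net assimilation and mesophyll CO2 from intercellular CO2
#'
#' Couples the diffusion supply `A = gm * (Ci - Cm)` with the enzyme-limited
#' demand [enzyme_limited_assimilation()] and returns their intersection. The
#' fixed point is found by bracketed root search on `Cm` with a convergence
#' check on the flux residual.
#'
#' @param Ci Intercellular CO2 partial pressure, ubar (scalar or vector).
#' @param gm Mesophyll conductance, mol m-2 s-1 bar-1.
#' @param params A [c4_params()] object.
#' @param tol Residual tolerance on `|gm*(Ci-Cm) - A(Cm)|`, umol m-2 s-1.
#' @return A data.frame with columns `Ci`, `Cm` (ubar) and `A` (umol m-2 s-1).
#' @examples
#' solve_A_from_Ci(c(10, 50, 200), gm = 0.42)
#' @export
solve_A_from_Ci <- function(Ci, gm, params = c4_params(), tol = 1e-9) {
  stopifnot(inherits(params, "c4_params"))
  if (any(!is.finite(Ci)) || any(Ci < 0))
    stop("Ci must be finite and non-negative", call. = FALSE)
  if (!is.finite(gm) || gm <= 0) stop("gm must be strictly positive", call. = FALSE)

  solve_one <- function(ci) {
    # Root in A (not Cm) keeps the flux residual well-conditioned at large gm:
    # f(A) = A - demand(Ci - A/gm) is strictly increasing in A. A <= gm*Ci
    # keeps Cm >= 0; A >= -Rd covers respiratory efflux (Cm > Ci).
    f <- function(a) a - enzyme_limited_assimilation(max(ci - a / gm, 0), params)
    lo <- -params$Rd - 1
    hi <- gm * ci + params$Rm + 1
    r <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)
    a <- r$root
    # Newton polish: at small gm the bracketing tolerance on A leaves a flux
    # residual above tol; a couple of steps push it to machine level.
    for (it in 1:8) {
      fa <- f(a)
      if (abs(fa) <= tol / 4) break
      h <- 1e-7 * max(1, abs(a))
      fp <- (f(a + h) - f(a - h)) / (2 * h)
      if (!is.finite(fp) || abs(fp) < 1e-12) break
      a <- a - fa / fp
    }
    cm <- max(ci - a / gm, 0)
    resid <- a - enzyme_limited_assimilation(cm, params)
    if (abs(resid) > tol)
      stop(sprintf(
        "solve_A_from_Ci failed to converge at Ci = %g (residual %.3e, Cm = %g)",
        ci, resid, cm), call. = FALSE)
    list(Cm = cm, A = a)
  }
  out <- lapply(Ci, solve_one)
  data.frame(Ci = Ci,
             Cm = vapply(out, `[[`, numeric(1), "Cm"),
             A  = vapply(out, `[[`, numeric(1), "A"))
}

#' Predicted initial slope over a grid of mesophyll conductances
#'
#' Evaluates the closed-form slope relation on a grid of `gm` values, as used to
#' compare measured (slope, g_m) pairs against the model prediction.
#'
#' @param gm_grid Strictly positive, sorted vector of conductances,
#'   mol m-2 s-1 bar-1.
#' @inheritParams initial_slope_from_gm
#' @return A data.frame with columns `gm` and `slope`.
#' @export
predicted_slope_curve <- function(gm_grid, Vpmax = 250, Kp = 82) {
  if (length(gm_grid) == 0) stop("gm_grid must be non-empty", call. = FALSE)
  if (is.unsorted(gm_grid, strictly = FALSE))
    stop("gm_grid must be sorted in increasing order", call. = FALSE)
  data.frame(gm = gm_grid,
             slope = initial_slope_from_gm(gm_grid, Vpmax, Kp))
}
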