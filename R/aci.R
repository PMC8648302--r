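#' Construct an A-Ci curve object
#'
#' An ordered series of steady-state gas-exchange records over ascending CO2
#' setpoints, as produced by a stepwise CO2-response protocol (typically 0 to
#' 1600 ppm at the reference side).
#'
#' @param records data.frame with columns `Ca` and `Ci` (ubar), `A`
#'   (umol m-2 s-1), and optionally `gsw` (mol m-2 s-1), `Tleaf` (degC),
#'   `Patm` (bar).
#' @param genotype Genotype / line label.
#' @param replicate Replicate identifier.
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(records, genotype = NA_character_, replicate = NA_character_) {
  req <- c("Ca", "Ci", "A")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) < 4)
    stop("an A-Ci curve needs at least 4 records", call. = FALSE)
  if (any(diff(records$Ca) <= 0))
    stop("Ca setpoints must be strictly increasing", call. = FALSE)
  # allow small instrument noise: Ci can nominally exceed Ca only slightly
  eps <- 0.05
  bad <- which(records$Ci > records$Ca * (1 + eps) + 1)
  if (length(bad))
    stop("Ci exceeds Ca beyond instrument tolerance at rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(records = as.data.frame(records),
                 genotype = genotype, replicate = replicate),
            class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-Ci curve: %d steps, Ca %g-%g ubar (genotype %s, rep %s)\n",
              nrow(x$records), min(x$records$Ca), max(x$records$Ca),
              x$genotype, x$replicate))
  invisible(x)
}

#' Fit the initial slope of an A-Ci curve
#'
#' Ordinary least-squares regression of `A` on `Ci` over the low-Ci points
#' (`Ci <= ci_max`), mirroring the linear fitting used to report initial slopes
#' of CO2-response curves. The default window of 60 ubar keeps PEPC inside its
#' quasi-linear regime (Kp = 82 ubar). Unweighted OLS.
#'
#' @param curve An [aci_curve()] object.
#' @param ci_max Upper Ci bound of the fitting window, ubar.
#' @return A list with `slope` (mol m-2 s-1 bar-1), `intercept` (umol m-2 s-1),
#'   `stderr` (standard error of the slope), and `n_points`.
#' @export
fit_initial_slope <- function(curve, ci_max = 60) {
  stopifnot(inherits(curve, "aci_curve"))
  sel <- curve$records[curve$records$Ci <= ci_max, , drop = FALSE]
  if (nrow(sel) < 3)
    stop(sprintf("need at least 3 records with Ci <= %g ubar (found %d)",
                 ci_max, nrow(sel)), call. = FALSE)
  fit <- stats::lm(A ~ Ci, data = sel)
  cf <- stats::coef(fit)
  # slope stderr computed directly so an exactly collinear curve returns 0
  # instead of tripping the near-perfect-fit heuristics in summary.lm
  sxx <- sum((sel$Ci - mean(sel$Ci))^2)
  se <- sqrt(sum(stats::resid(fit)^2) / (nrow(sel) - 2) / sxx)
  list(slope = unname(cf[["Ci"]]), intercept = unname(cf[["(Intercept)"]]),
       stderr = se, n_points = nrow(sel))
}

#' CO2-saturated assimilation rate from an A-Ci curve
#'
#' Mean of `A` over the plateau of the curve, defined as records whose Ca
#' reaches at least `plateau_fraction` of the highest Ca measured.
#'
#' @param curve An [aci_curve()] object spanning saturating Ca.
#' @param plateau_fraction Fraction of the maximum Ca defining the plateau
#'   window; 1 selects only the single highest-Ca record.
#' @return A_max, umol m-2 s-1.
#' @export
amax <- function(curve, plateau_fraction = 0.75) {
  stopifnot(inherits(curve, "aci_curve"))
  if (plateau_fraction <= 0 || plateau_fraction > 1)
    stop("plateau_fraction must be in (0, 1]", call. = FALSE)
  ca_max <- max(curve$records$Ca)
  sel <- curve$records[curve$records$Ca >= plateau_fraction * ca_max, , drop = FALSE]
  if (nrow(sel) == 0) stop("no records in the plateau window", call. = FALSE)
  mean(sel$A)
}

#' Read a gas-exchange CSV into an A-Ci curve
#'
#' Expects the comma-separated dialect with header
#' `Ca_ppm,Ci_ppm,A,gsw,Tleaf,Patm_bar`. Mole fractions (ppm) are converted to
#' partial pressures (ubar) with the recorded atmospheric pressure; if
#' `Patm_bar` is absent, 1 bar exactly is assumed and a warning is issued.
#'
#' @param path CSV file path.
#' @param genotype,replicate Metadata labels attached to the curve.
#' @return An [aci_curve()] object with `Ca` and `Ci` in ubar.
#' @export
read_gas_exchange_csv <- function(path, genotype = NA_character_,
                                  replicate = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("Ca_ppm", "Ci_ppm", "A")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if ("Patm_bar" %in% names(df)) {
    patm <- df$Patm_bar
  } else {
    warning(sprintf("%s: no Patm_bar column; assuming 1 bar exactly", path))
    patm <- rep(1, nrow(df))
  }
  if (any(!is.finite(patm)) || any(patm <= 0))
    stop(sprintf("%s: Patm_bar must be positive and finite", path), call. = FALSE)
  rec <- data.frame(Ca = df$Ca_ppm * patm, Ci = df$Ci_ppm * patm, A = df$A,
                    Patm = patm)
  for (col in c("gsw", "Tleaf")) if (col %in% names(df)) rec[[col]] <- df[[col]]
  if (any(diff(rec$Ca) <= 0))
    stop(sprintf("%s: Ca_ppm must be strictly increasing down the file", path),
         call. = FALSE)
  aci_curve(rec, genotype = genotype, replicate = replicate)
}
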