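---
title: "Mesophyll conductance, membrane CO2 permeability and freeze-thaw survival: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesophyll conductance, membrane CO2 permeability and freeze-thaw survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoflux)
```

# The scientific problem

In C4 leaves, CO2 must diffuse from the intercellular airspace across the
mesophyll cell wall and plasma membrane into the cytosol, where carbonic
anhydrase (CA) hydrates it and PEP carboxylase (PEPC) fixes the resulting
bicarbonate. The conductance of that path - the mesophyll conductance,
$g_m$ (mol m$^{-2}$ s$^{-1}$ bar$^{-1}$) - is a candidate limitation on C4
photosynthesis, and membrane aquaporins are candidate carriers of much of it.
`mesoflux` implements the quantitative chain such a study needs: the C4 model
that predicts how $g_m$ shapes the CO2-response curve, the oxygen-isotope
route that measures $g_m$, the stopped-flow assay that measures single-cell
membrane CO2 permeability, and the freeze-thaw growth assay that screens
aquaporin water transport. Every estimator has a forward simulator, so the
whole chain is validated by parameter recovery rather than against
irreproducible instrument records.

# The enzyme-limited C4 model and the slope relation

PEP carboxylation follows Michaelis-Menten kinetics in the mesophyll CO2
partial pressure $C_m$, capped by PEP regeneration:
$V_p = \min\!\left(\frac{C_m V_{pmax}}{C_m + K_p},\, V_{pr}\right)$.
Net assimilation is the minimum of the PEPC-limited supply to the bundle
sheath ($V_p + g_{bs} C_m - R_m$) and the Rubisco-limited ceiling
($V_{cmax} - R_d$); competing limitations are resolved by taking the minimum
rate. Coupling this demand with Fick's law across the mesophyll,
$A = g_m (C_i - C_m)$, and linearising PEPC at low $C_m$ gives the closed
form at the centre of the package:

$$\frac{dA}{dC_i} = \frac{g_m V_{pmax}}{g_m K_p + V_{pmax}}$$

i.e. the series combination of the diffusional conductance $g_m$ and the
carboxylation efficiency $V_{pmax}/K_p$. The initial slope of an A-Ci curve
therefore rises with $g_m$ toward the PEPC-limited asymptote
$V_{pmax}/K_p$ = 250/82 $\approx$ 3.05 mol m$^{-2}$ s$^{-1}$ bar$^{-1}$,
and is strictly below $\min(g_m, V_{pmax}/K_p)$. `gm_from_initial_slope()`
is the exact algebraic inverse.

Parameters and defaults (`c4_params()`):

| parameter | meaning | default | unit |
|---|---|---|---|
| `Vpmax` | maximal PEPC activity | 250 | µmol m⁻² s⁻¹ |
| `Kp` | PEPC Michaelis constant for CO2 | 82 | µbar |
| `Vpr` | PEP-regeneration cap | 80 | µmol m⁻² s⁻¹ |
| `Vcmax` | maximal Rubisco carboxylation | 35 | µmol m⁻² s⁻¹ |
| `gbs` | bundle-sheath conductance | 0.003 | mol m⁻² s⁻¹ bar⁻¹ |
| `Rd`, `Rm` | day respiration, mesophyll share | 0, 0 | µmol m⁻² s⁻¹ |

`Vpmax` and `Kp` are the values used for the slope comparison; the others are
a named default set in the range the C4 modelling literature uses for
*Setaria*-type leaves (`Vcmax` chosen so the simulated ambient assimilation
plateaus near 35 µmol m⁻² s⁻¹). Respiration defaults to zero because the
closed-form slope relation carries no $R_m$ term; `Rm` is exposed for users
who want the offset. Units are fixed package-wide - $A$ in µmol m⁻² s⁻¹,
partial pressures in µbar, conductances and slopes in mol m⁻² s⁻¹ bar⁻¹
(numerically equal to µmol m⁻² s⁻¹ µbar⁻¹) - so printed numbers are
comparable without conversion.

`solve_A_from_Ci()` finds the supply-demand intersection by bracketed root
search *in A* (not $C_m$), which keeps the flux residual well conditioned
when $g_m$ is very large; a short Newton polish pushes the residual below
$10^{-9}$ µmol m⁻² s⁻¹ and non-convergence is a hard error with diagnostics.

```{r}
initial_slope_from_gm(c(0.42, 0.59))
gm_from_initial_slope(0.41)       # conductance implied by the control slope
solve_A_from_Ci(c(20, 100, 400), gm = 0.42)
```

# Fitting A-Ci curves

`fit_initial_slope()` is unweighted OLS of $A$ on $C_i$ over points with
$C_i \le$ `ci_max`. The default window of 60 µbar keeps PEPC inside its
quasi-linear regime ($K_p$ = 82 µbar); because the true response is concave,
the fitted slope carries a small negative curvature bias (about 1-2% at this
window, shrinking monotonically as the window narrows - tested). `amax()`
averages the plateau records (Ca within `plateau_fraction` of the maximum;
1.0 degenerates to the single highest step). CSV input uses mole fractions
(ppm) converted to partial pressures with the recorded pressure; a missing
pressure column assumes exactly 1 bar with a warning.

# Mesophyll conductance from C18O16O discrimination

Because CA exchanges oxygen between CO2 and cytosolic water, CO2 that enters
the mesophyll and diffuses back out carries the $^{18}$O signature of leaf
water. The observed photosynthetic discrimination in an open chamber,

$$\Delta_{obs} = \frac{\xi(\delta_o - \delta_e)}{1 + \delta_o -
\xi(\delta_o - \delta_e)}, \qquad \xi = \frac{C_e}{C_e - C_o},$$

therefore grows with the retro-diffusion ratio $C_m/(C_a - C_m)$:

$$\Delta_{obs} = \bar a + \frac{C_m}{C_a - C_m}\,\Delta_{ea},$$

where $\bar a$ is the diffusional fractionation of C$^{18}$O$^{16}$O through
stomata and boundary layer and $\Delta_{ea}$ is the enrichment of CO2 in
equilibrium with evaporating-site water over the chamber CO2. Inverting for
$C_m$ and applying Fick's law, $g_m = A/(C_i - C_m)$, gives the
full-equilibrium estimate. All delta arithmetic uses exact ratio products
($1+\delta$ algebra), never additive approximations; the additive error at
this operating point is a few tenths of a permil and is bounded and tested.

Constants (`fractionation_constants()`), every one recorded in the estimate
metadata:

* `a_bar` = 8.8 permil - diffusional fractionation of C$^{18}$O$^{16}$O in
  air, with boundary-layer weighting neglected at typical chamber flow.
* `eps_w_coeffs` - CO2-water equilibrium fractionation
  $\varepsilon_w(T) = 17604/T_K - 17.844$ permil, pinned to 41.2 permil at
  25 °C and decreasing with temperature. The exact functional form used by
  any given laboratory varies; the coefficients are configuration.
* `vsmow_to_co2_shift` = 41.47 permil - the single explicit scale conversion
  between water-referenced (VSMOW) deltas and the CO2 working scale of the
  laser analyser.

Design choices where the method leaves room:

* **Evaporating-site water.** The default takes leaf water at the
  evaporating sites to be in equilibrium with the measured chamber vapor at
  leaf temperature (liquid-vapor fractionation via the Majoube-form
  polynomial). This avoids committing to a particular Craig-Gordon
  parameterisation; since the forward simulator uses the same rule, recovery
  tests are exact, but users analysing real data should treat this as the
  point to substitute their own leaf-water model.
* **Ternary correction.** Transpiration advects CO2 and distorts the supply
  relation; we apply a first-order factor $t = (1+\bar a)E/(2 g_{ac})$ with
  $g_{ac} = g_{sw}/1.6$, dividing the supply-side discrimination by $(1-t)$.
  It is toggleable and on by default; $t \approx 0.01$ at the default
  conditions, so the correction is a percent-level refinement.
* **CA-limited variant.** When CA is finite, $^{18}$O equilibration is
  incomplete and the full-equilibrium inversion understates $g_m$. The
  package models this as a series resistance, $1/g_m = 1/g_{m,eq} - 3/k_{CA}$
  (factor 3 from the three-oxygen exchange stoichiometry of the hydration
  cycle). It is an explicit approximation to the full CA-limited inversion,
  labelled as such in the output metadata; it always inflates the estimate,
  never reorders genotypes, and vanishes as $k_{CA} \to \infty$. At the
  measured $k_{CA}$ = 6.5 mol m⁻² s⁻¹ bar⁻¹ it inflates the four
  genotype-level conductances by 1.24-1.37x (mean 1.31x).
* **Averaging.** The protocol takes 10 readings per leaf; the default
  inverts each reading and averages the per-reading $g_m$ (mean ± SE).
  Inverting the averaged reading is available via `average = "mean_record"`.

```{r}
rec <- gen_isotope_records(0.42, n_readings = 10,
                           cfg = sim_config(seed = 1, sigma_delta = 0.3))
estimate_gm(rec, mode = "equilibrium")
```

Invalid readings (discrimination at or below the diffusional floor, inverted
$C_m$ outside $(0, C_a)$, $C_i \le C_m$) are excluded with reasons and
counted, never silently dropped; a batch with no valid reading is an error
listing every reason.

# Stopped-flow CO2 permeability

CO2 entering a dye-loaded cell acidifies the cytosol and quenches the
fluorescein signal. Under the surface-limited entry model - instantaneous
intracellular CA, excess pH buffering - the quench is a single exponential
whose rate constant scales with the surface-to-volume ratio, so for a
spherical cell $P_{CO_2} = k\,d/6$. With the measured mean diameter of
4.63 µm, the study-scale permeability of 1.5×10⁻⁴ m s⁻¹ corresponds to
$k \approx$ 194 s⁻¹, which decays to numerical zero well inside the 0.2 s
acquisition window - the fit is well conditioned. The fit discards a 5 ms
mixing dead time by default, seeds itself with a log-linear regression and
refines by Levenberg-Marquardt; a flat trace or a non-positive fitted rate
is a "no acidification signal" error. The absolute calibration (buffering
capacity, CO2 gradient normalisation) enters as a single `scale` factor,
default 1; recovery tests are scale-consistent by construction, so the
package validates relative, not absolute, calibration.

```{r}
tr <- gen_stopped_flow(1.5e-4, cell_geometry(4.63e-6),
                       cfg = sim_config(seed = 1, sigma_F = 0.01))
f <- fit_acidification_rate(tr)
c(k = f$k, P = pco2_from_rate(f$k, cell_geometry(4.63e-6)))
```

# Freeze-thaw survival as %AUC

Aquaporin-dependent water permeability protects yeast against freeze-thaw;
survival is scored as the cumulative growth of a treated culture relative to
its untreated control. Both OD curves are log-transformed (floor 0.001 OD
against blank-level readings), anchored by subtracting their own $t=0$
value, and integrated by the trapezoid rule from time zero to the control's
stationary onset; the ratio is reported as a percentage. Baseline anchoring
makes identical curves give exactly 100% and makes the metric invariant to a
shared OD scale; values above 100% (treated outgrowing control) are reported
unclamped. Stationary onset is the earliest time after the window of maximal
log-slope at which the rolling 2 h slope drops below 0.01 h⁻¹; a curve that
never plateaus is an error suggesting a longer run, and a curve that never
grows degenerates to the first window end. The raw-OD integration variant is
available via `log_od = FALSE`, since assay descriptions are often ambiguous
about whether the log transform precedes the AUC; the log route is the
default because the transform is applied to the growth data upstream.
Treated/untreated wells are paired by an explicit mapping, never by order.

# What the simulators emulate - and what they do not

Each generator is the documented inverse of its estimator at zero noise, a
property the test suite asserts to solver tolerance. Defaults encode the
study conditions: 2% O2, 380 µmol mol⁻¹ reference CO2, 25 °C leaf
temperature, 55% RH, constant stomatal conductance (0.45 mol m⁻² s⁻¹; the
study found no genotype effect on $g_{sw}$), chamber flow 300 µmol s⁻¹ over
6 cm², 10 isotope readings per leaf, 0.2 s stopped-flow windows, 10-min
plate-reader sampling over 30 h. Noise defaults are typical instrument
precisions: 0.3 µmol m⁻² s⁻¹ on $A$, 0.3 permil per delta channel,
1% multiplicative on fluorescence, 0.002 OD. The isotope generator assumes
tank CO2 at -25 permil (CO2 scale) and chamber vapor at -5 permil (VSMOW),
transpiration-dominated; with these, the simulated discrimination sits
comfortably above the diffusional floor, and the recovered-$g_m$ standard
errors (0.01-0.05 mol m⁻² s⁻¹ bar⁻¹ at $n=10$) match the precision the
$^{18}$O method reports in practice.

The simulators deliberately omit instrument drift, laser calibration cycles,
chamber leaks, boundary-layer heterogeneity, partial stomatal closure
dynamics, proton leak in the stopped-flow assay, and plate-edge effects.
Passing recovery tests therefore demonstrates that the estimators invert
their stated physical models correctly and are robust to stated noise - not
that those models capture every systematic error of real instruments.

All randomness flows from one integer seed; each generator draws from a
deterministic per-channel substream, so fixed seeds give bit-identical
records (and bit-identical CSVs), and consuming one channel does not perturb
another.

# Numerical choices and degenerate inputs

* Root finding: bracketed `uniroot` everywhere, residual tolerances 10⁻⁹
  µmol m⁻² s⁻¹ (flux balance) with explicit convergence errors.
* The isotope forward model solves the small fixed point between the outlet
  delta and the source enrichment by contraction iteration to 10⁻¹⁶.
* Deltas travel as permil at interfaces, fractions internally; scale
  conversions are single explicit constants, applied once.
* Degenerate cases are pinned by tests: zero-CO2 supply, $\xi$ singularities
  (no drawdown), discrimination at the diffusional floor ($C_m = 0$),
  `plateau_fraction = 1`, flat fluorescence traces, flat growth curves,
  single-replicate groups (SE reported as 0 and flagged).

# Reproducibility plumbing

`run_pipeline()` executes a configured chain (simulate-then-fit, or fit on
CSV inputs) and writes its tables with a JSON manifest - config snapshot,
input MD5s, package version, seed, timestamp - so deterministic runs can be
regenerated bit-for-bit. The numbered scripts under `analysis/` are thin
narrative drivers over the same exported functions; `scripts/acceptance.R`
re-runs the four headline recoveries from scratch. Problem sizes throughout
(10-reading batches, 100-trace and 100-seed ensembles, 20-seed growth
ensembles, 400-curve bias checks) were chosen as the smallest sizes at which
the Monte Carlo error is comfortably below the effects being checked.

# Known limitations

* The CA-limited correction is a series-resistance approximation, not the
  full kinetic inversion; for $g_{m,eq} \ge k_{CA}/3$ it diverges and the
  package refuses to apply it rather than extrapolate.
* The leaf-water model is the weakest link of the isotope chain on real
  data; the package's default is internally consistent but simple.
* Absolute stopped-flow permeabilities inherit the configured calibration
  scale; only relative comparisons across lines are calibration-free.
* Light-limited C4 model branches, temperature responses of the kinetic
  constants, $^{13}$C-based leakiness, C3-style partitioning of $g_m$ into
  wall and membrane components, and inferential statistics beyond mean ± SE
  are out of scope.
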