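---
title: "Quantifying membrane modification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane modification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayertools)
```

Small amphiphilic molecules — alkaloids, flavonoids, local anesthetics —
adsorb to lipid bilayers and change the membrane's interfacial
electrostatics and its lipid packing. Both changes propagate to membrane
proteins: reconstituted ion channels report them as altered conductance,
gating kinetics, or pore-forming activity. This package implements the
quantitative chain used to characterize such effects across five assay
types, together with synthetic generators that emulate each instrument with
known ground truth, so every stage of the analysis is testable end to end
without laboratory data.

## Membrane electrostatics

**Boundary potential from carrier conductance.** A neutral cation carrier
(such as nonactin/K⁺) makes the bilayer conductance exponentially sensitive
to the electrical potential drop between the bulk phase and the membrane
interior. Assuming the carrier's surface concentration follows the
Boltzmann distribution, a change in steady-state conductance from
$G_m^0$ to $G_m$ reflects a boundary-potential change

$$\Delta\varphi_b = \frac{kT}{e}\,\ln\frac{G_m}{G_m^0},$$

with $kT/e = 25.69\ \mathrm{mV}$ at 298.15 K. `boltzmann_delta_phi()`
implements this with CODATA-exact constants. Sign convention, used
everywhere in the package: *reductions of the boundary/dipole potential are
reported as positive numbers*, matching how adsorption series are plotted
and tabulated; an increased cation-carrier conductance is interpreted as a
boundary-potential reduction.

**Langmuir adsorption.** The concentration dependence of the potential
reduction follows a first-order adsorption isotherm

$$\Delta\varphi_b(C) = \Delta\varphi_b(\infty)\,\frac{C}{C+K},$$

where $\Delta\varphi_b(\infty)$ is the saturating reduction and $K$ (µM)
the desorption constant. `fit_langmuir()` fits this by Levenberg–Marquardt
nonlinear least squares by default, weighting points by $1/\mathrm{sd}^2$
when per-point replicate standard deviations are available (whether the
original analyses were weighted is not stated; unweighted is the default
when no sd is supplied). The classical linearization is retained as a
validation mode: because the regression of
$\Delta\varphi_b(\infty)/\Delta\varphi_b(C)$ on $1/C$ requires the unknown
plateau, we obtain it first from the double-reciprocal regression of
$1/\Delta\varphi_b$ on $1/C$, then run the stated regression, whose slope
is $K$ and whose intercept should be 1 — reported as a diagnostic. On
noiseless data both routes recover parameters to numerical precision;
degenerate series (no spread, no curvature, too few points) return a
non-converged object with a reason code rather than a number.

**Dipole potential.** The dipole component $\varphi_d$ of the boundary
potential is probed ratiometrically with a voltage-sensitive styryl dye
(dual-wavelength excitation ratio $R$). The mapping is linear,
$R = R_\mathrm{ref} + s\,\Delta\varphi_d$, but its constants are
instrument- and protocol-specific: they are *configuration*
(`dipole_calibration()`), not code, and the shipped defaults
($R_\mathrm{ref}=1$, $s=-0.005\,\mathrm{mV}^{-1}$) are placeholders of a
realistic magnitude, not published calibrations.
`ratio_to_dipole_shift()` inverts the map and returns a series ready for
the same Langmuir fit.

**Detectability floor.** Compounds whose fitted maximal reduction is below
10 mV (the usual screening threshold for a distinguishable
dipole-modifying effect) carry no meaningful $K$; `summarize_compound()`
flags it not-available, mirroring the reporting convention of experimental
tables.

## Lipid melting (DSC)

A lipid phase transition is modelled as a two-state van't Hoff process:
with $\ln K_{eq} = -(\Delta H_{vH}/R)(1/T - 1/T_m)$ and melted fraction
$\Theta = K_{eq}/(1+K_{eq})$, the excess heat capacity is

$$C_p(T) = \Delta H_{cal}\,\frac{\Delta H_{vH}}{R T^2}\,\Theta(1-\Theta),$$

which peaks at $T_m$, integrates to the calorimetric enthalpy
$\Delta H_{cal}$, and has full width at half maximum
$3.5255\,R\,T_m^2/\Delta H_{vH}$ (from solving $\Theta(1-\Theta)=1/8$).
The generator (`gen_thermogram()`) sums such components; a pretransition is
an extra low-enthalpy component (default fixture: 12% of the main
enthalpy, 1.2 °C wide at 33.9 °C, against a main transition at 41.3 °C
with 0.4 °C half-width and 36.4 kJ/mol — the control DPPC regime).

**Half-width convention.** The "half-width" $T_{1/2}$ is interpreted as the
*full* width at half maximum, one interpretation used consistently
everywhere (the common "width at half height" phrasing is ambiguous
between full and half of that width; the full width is the standard
reading and matches the 0.4 °C control value).

**Feature extraction** (`dsc_features()`) is deliberately estimator-heavy
because instrument noise otherwise biases peak descriptors:

* the main peak apex is located by quadratic regression of the *raw* curve
  over ±FWHM/4 around the argmax of a lightly Savitzky–Golay-smoothed
  curve (3rd order; window rescaled to ~FWHM/5 after a pilot pass) —
  symmetric, hence unbiased on noiseless peaks and far more stable than a
  3-point parabola under noise;
* half-height crossings are first bracketed on the smoothed curve, then
  refined by local linear fits of the raw curve (window ±distance/8), which
  removes the inward "first noisy dip" bias of naive crossing detection;
* the enthalpy is the trapezoidal integral of the raw curve over the
  contiguous region above 1% of peak height;
* the pretransition is the most prominent secondary maximum at least 1 °C
  below the main peak; it is declared *abolished* when no secondary peak
  exceeds 3× the robust flank noise (the abolition call is categorical —
  shifts report `NA`, not 0, when the treated pretransition is gone).

**Baseline handling** (`dsc_preprocess()`) fits a polynomial (default
linear) to the scan outside peak regions. Peak support is found from a
smoothed curve against a threshold of 2× the point noise (estimated from
first differences, which is insensitive to peaks and trends) and dilated by
half its width so that endotherm tails do not drag the baseline upward;
when broad peaks leave too few baseline points the undilated mask is used,
and a scan that is all peak is an explicit error.

**Deconvolution** (`dsc_deconvolve()`) fits sums of 1..`max_components`
van't Hoff curves (Gaussian shapes available as a sensitivity flag) and
selects the count by AICc *plus a resolvability rule*: solutions with
component midpoints closer than 0.25× their mean FWHM are treated as
unresolvable and the smaller count is kept. The rule is necessary because
on near-noiseless fixtures the information criterion alone always prefers
more components; with it, two equal 1 °C-wide components 2 °C apart are
resolved while a 0.05 °C separation correctly collapses to one component.
No claim is made that this component model matches any particular
commercial deconvolution software.

## Calcein leakage

Vesicle-encapsulated calcein self-quenches; released dye fluoresces. The
relative fluorescence is

$$RF(t) = 100\,\frac{I(t) - I_0}{I_{max}/0.9 - I_0}\ \%,$$

where $I_{max}$ is measured after complete detergent lysis and the factor
0.9 corrects for dilution by the detergent solution. `compute_rf()` is
invariant to affine rescaling of the fluorescence unit and refuses
non-positive denominators. The generator uses mono-exponential release
kinetics $RF(t) = RF_{max}(1-e^{-t/\tau})$; since published curves are
summarized at a fixed endpoint (80 min), the rise time is a free fixture
parameter (default 10 min). `estimate_rf_max()` extracts the plateau by
exponential fitting (default) with an endpoint fallback (mean of the last
10% of points) and a warning record on non-convergence; which of the two
conventions produced published $RF_{max}$ values is unstated, and the
Monte-Carlo tests show the exponential fit is the better estimator when
the rise is slow relative to the observation window. Negative noise
excursions are retained in the curve but the reported plateau is floored
at 0.

## Single channels

**Simulation.** Gating is a two-state continuous-time Markov chain with
exact exponential sojourns (no time discretization bias), sampled at 5 kHz
after the fact. `open_rate` is the closed→open transition rate — so the
mean *closed* dwell is `1/open_rate`, the mean *open* dwell is
`1/close_rate`, and the stationary open probability is
`open_rate/(open_rate+close_rate)`. White Gaussian noise (amplitude in pA)
is added *before* filtering, instrument-like. Filtering is a causal 4-pole
Bessel-type digital filter: the normalized analog prototype poles are
scaled to the prewarped cutoff and bilinear-transformed (the acquisition
convention is 200 Hz low-pass at 5 kHz sampling; the synthesis path is a
fixture convention, since only the acquisition filter is ever specified).

**Idealization** (`idealize()`) uses the half-amplitude threshold
convention: the baseline is the dominant mode of the all-points amplitude
histogram (refined afterwards from the closed events themselves), the open
level the most prominent secondary mode (candidate modes must clear 3% of
the dominant mode's density, rejecting Gaussian-tail bumps), and
transitions are crossings of the midpoint. Events shorter than the dead
time — default twice the filter rise time, $T_r = 0.3321/f_c$ — are merged
into their neighbours, so dwells always sum exactly to the trace duration.
Per-event amplitudes are means over the event with a one-rise-time guard
band trimmed at each edge so filter settling does not bias the level. A
unimodal histogram yields a no-events result with a reason code. Note the
occupancy caveat: for a channel open more than half the time the dominant
mode *is* the open level.

**Statistics.** Single-channel conductance is $|i/V|$; the normal density
is fitted to the amplitude histogram (Freedman–Diaconis bins) by minimum
χ² over the binned counts, started at the sample moments. This matters for
calibration: with parameters estimated from the raw data the binned χ²
statistic is stochastically larger than its nominal χ²(k−1−2) reference
(the Chernoff–Lehmann phenomenon) and the acceptance test over-rejects;
fitting the histogram itself restores the nominal distribution, and the
400-run calibration check sits at the nominal 5% rejection. Dwell times
are estimated by the truncated-exponential maximum-likelihood estimator
$\hat\tau = \overline{X} - d$ (from $E[X\,|\,X>d] = \tau + d$), with the
histogram χ² (optional logarithmic binning; bins pooled below an expected
count of 5) serving acceptance only — both are reported. An optional
first-order missed-event correction multiplies $\hat\tau$ by
$e^{-d/\hat\tau_\mathrm{other}}$ to undo the inflation caused by
complementary-state sojourns shorter than the dead time fusing adjacent
events; it is off by default (pre-resolved event lists don't need it) and
on in the study pipeline (idealized filtered traces do). Edge events are
excluded from dwell fits as right-censored. G(V) relations are compared
after normalizing each curve by its mean conductance
(`gv_shape_deviation()`), the standard check that a modifier rescales
conductance without changing the shape of the voltage dependence.
Macroscopic pore-forming activity is the ratio $I_\infty/I_\infty^0$ of
windowed steady-state means with propagated error.

## Descriptor screening

Pearson correlations between physicochemical descriptors (LogD, LogP,
dipole moment µ) and measured effects use the Fisher transformation for
interval estimation: $z = \operatorname{atanh} r$,
$z \pm z_{1-\alpha/2}/\sqrt{n-3}$, back-transformed. The "confidence level
of 0.1" convention is read as $\alpha = 0.1$ (90% interval) — the only
coherent interpretation — and the two-sided normal quantile is used with
no small-sample t adjustment, as Fisher's method states. A coefficient is
significant when its interval excludes 0. Spearman rank correlation (with
midranks for ties) confirms significant cells, *except* µ against the
potential-reduction maxima: a parallel-plate-capacitor argument makes that
relationship linear by construction, so rank confirmation is withheld
there. Missing entries are pairwise-deleted, so the pair count $n$ varies
per cell and is always reported; cells with fewer than 4 pairs are marked
not computable. No multiple-testing correction is applied, matching the
source methodology.

The package ships two small tables: `alkaloid_effects.csv`, the published
per-compound effect measurements used as screen input, and
`alkaloid_descriptors_synthetic.csv`, a **synthetic stand-in** for the
unpublished computed descriptor table (LogD values compiled once from
general physicochemical knowledge; the dipole moments are rough plausible
magnitudes). Screens on the stand-in demonstrate the machinery but do not
reproduce the originally published coefficients exactly.

## The synthetic study pipeline

`run_study()` turns a JSON-serializable `study_config()` into a complete
synthetic study: per-compound adsorption series (boundary and dipole),
DSC scans against a shared control, leakage curves, gating traces before
and after the modifier, and macroscopic current pairs — then runs every
analysis stage and reports two tables mirroring the standard reporting
schema (potential parameters + melting shifts + leakage; channel
conductance/dwell/current ratios), plus a long-format comparison of
recovered versus generating values. One global seed drives everything:
per-stage seeds come from `derive_seed()` (a fixed affine counter scheme
modulo a 31-bit prime), so no stage shares random state and identical
config + seed give byte-identical reports. Stage failures are caught,
recorded per compound, and do not stop the run.

### Fixture conditions and problem sizes

Instrument noise amplitudes are never published for these assays, so the
generator defaults are chosen once at realistic magnitudes and fixed:

* adsorption: 2 mV additive noise per bilayer, with each concentration
  averaged over 5 replicate membranes in the pipeline (experimental tables
  average 3–11), pointwise sd/√5 used as fit weights;
* DSC: 40 J mol⁻¹ K⁻¹ of heat-capacity noise — the scale implied by
  ~0.5 µW instrument power noise at ~4 µmol lipid (5 mM) and 0.2 °C/min:
  $C_p^{noise} = P_{noise}/(n\,\dot T) \approx 0.5\,\mu W /(4\,\mu mol
  \times 3.3\times10^{-3}\,K/s) \approx 40$ J mol⁻¹ K⁻¹;
* leakage: 2% of the full fluorescence span;
* traces: 0.5 pA white noise before 200 Hz filtering (SNR ≈ 9–20 at the
  4.5–9.8 pA unit currents used);
* dye ratio: 0.005 ratio units.

The example study places channel dwell times in the millisecond regime
(~100 ms) and uses 180 s traces, giving ~700–800 open events per trace —
approaching, within desk-scale compute, the 1500–2000-event dwell analyses
of instrument practice; event-level statistical checks use 1200–2000
directly simulated events. Tests that need many replicates use 12–50 seeds
per condition and state their Monte-Carlo bands explicitly.

### What passing tests do and do not show

The generators produce exactly the structure the analyses assume: single
exponential dwell distributions, a single normal amplitude class, mono-
exponential leakage, two-state van't Hoff melting, white Gaussian noise.
Real records contain multiple conductance classes, correlated (1/f and
50 Hz) noise, baseline drift, multi-channel superpositions, non-two-state
melting, and photobleaching — none of which are emulated. Recovery of
ground truth here therefore validates the *estimators and their
calibration*, not robustness to instrument pathology. Multi-state gating,
voltage-dependent rates, burst analysis, hidden-Markov idealization, and
Gouy–Chapman surface/dipole decomposition are out of scope by design.

## Numerical choices and degenerate inputs

* Temperatures are °C at every interface, kelvin internally (conversion
  273.15); physical constants are CODATA-exact.
* Langmuir starting values come from the double-reciprocal regression with
  variance-stabilizing weights; the nonlinear fit bounds $K > 0$.
* Thermogram grids must cover each component's midpoint by two half-widths
  (error names the offending component); sub-grid peak location assumes a
  grid step ≤ 0.02 °C for the stated accuracies.
* χ² bins with expected counts below 5 are pooled inward from the ends;
  degrees of freedom are bins − 1 − (fitted parameters).
* Zero-variance inputs (flat adsorption series, constant dwells, constant
  correlates) yield explicit failure/rejection results, never silent
  numbers; empty or comma-decimal CSV inputs raise parse errors.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
report <- run_study(example_study_config(seed = 1))
print(report)
subset(report$truth, compound == "strong")
```

The printed report carries the two tables and, for every quantity, the
generating truth next to the recovered estimate; `scripts/acceptance.R`
(repository root) recomputes the package's headline numbers from scratch
and writes them as JSON.
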