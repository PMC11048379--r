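---
title: "Breakdown-curve thermodynamics: models, parameters and design choices"
author: "cidtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakdown-curve thermodynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidtherm)
```

## The measurement and the model

A collision-induced dissociation (CID) breakdown experiment on a
non-covalent protein oligomer records, at each collision cell voltage
difference ΔCV, the intensities of the intact precursor ("educt") ion and
of its product ions. `cidtherm` models the normalized educt intensity as a
Boltzmann sigmoid of the voltage,

$$y(x) = \mathrm{Final} + \frac{\mathrm{Initial} - \mathrm{Final}}
        {1 + e^{(x - \Delta CV_{50})/dx}},$$

and derives from the fit (a) the classical course characteristics —
plateaus, midpoint, width, and the analytic midpoint tangent slope
$-(\mathrm{Initial}-\mathrm{Final})/(4\,dx)$ — and (b), after converting
the voltage axis to an effective internal ion temperature, the apparent
ambient-temperature kinetics and quasi-thermodynamics of the dissociation
reaction: rate constant $k^\#$, dissociation quotient $K_D^\#$, Gibbs
energy $\Delta G^\#$, enthalpy $\Delta H^\#$ and entropy term
$T\Delta S^\#$.

Key modelling assumptions:

* the educt decays along a single sigmoidal transition (one complex, one
  transition, hence exactly one tangent line, one Arrhenius plot and one
  Gibbs–Helmholtz plot per complex);
* peak *heights* (not areas) quantify ion abundance, and the summed
  assigned intensities at one voltage define 100%;
* educt decay is first order over the collision-cell transit, so the
  survival fraction $s$ gives $k = -\ln s/\tau$ with residence time
  $\tau$;
* each dissociation event releases exactly one dimer and one monomer ion,
  detected with equal efficiency, so the product percentage splits equally
  between the dimer and the monomer within a release channel; hetero-trimer
  channels are summed before the dissociation quotient
  $K = [\mathrm{dimer}][\mathrm{monomer}]/[\mathrm{trimer}]$ is formed
  (per-channel quotients are available as an option — the experimental
  branching between losing an unmodified versus a modified monomer is not
  separately calibrated, so the summed quotient is the conservative
  default).

## Voltage-to-temperature conversion

The default model treats the centre-of-mass collision energy of the
accelerated ion,
$E_{com} = z\,e\,\Delta CV \cdot m_{gas}/(m_{gas}+M_{ion})$, as
equipartitioned over the $3N-6$ vibrational degrees of freedom of an
$N$-atom complex:

$$T_{eff}(\Delta CV) = T_0 +
  \frac{z\,e\,\Delta CV\; m_{gas}}{(m_{gas}+M_{ion})\,(3N-6)\,k_B}.$$

This is why precise atom counts of the oligomers matter, and why the
species calculus validates them. The mapping is affine and strictly
increasing; for a quintuply charged ~9.2 kDa trimer (1299 atoms, argon
collision gas) the 0–55 V grid maps onto roughly 3.5 K above $T_0$. The
conversion is deliberately **pluggable** (`thermo_config(cv_model = ...)`):
instrument-specific calibrations — which typically account for multiple
collisions and yield much larger effective-temperature excursions — can be
substituted without touching any downstream code. All quantities derived
through the default model are therefore *apparent* quantities on that
model's temperature scale; their internal identities
($\Delta G = \Delta H - T\Delta S$ and $\Delta G = -RT\ln K_D$) hold
regardless of the calibration, their absolute magnitudes do not.

A practical consequence of the single-collision scale: an observable
transition within the experimental voltage window corresponds to very
large apparent $\Delta H$ and $\Delta S$ values (thousands of kJ/mol),
because a sub-kelvin-per-volt lever arm has to carry the whole transition.
This is a property of the conversion model, not a defect of the
regression; the package reports what the chosen model implies.

A second consequence concerns signs. With any monotone increasing
voltage-to-temperature mapping, the measured dissociation quotient grows
with effective temperature, so the fitted $\Delta G$-vs-$T$ line has
negative slope and the fitted $\Delta S$ is positive. Published analyses
of this experiment type report *negative* $T\Delta S^\#$ terms; those
arise from calibration equations internal to the original instrument
workflows that are not part of this package. `cidtherm` therefore checks
the canonical sign structure (endergonic $\Delta G^\# > 0$, endothermic
$\Delta H^\# > 0$, entropy-opposed $T\Delta S^\# < 0$) at the level of the
Gibbs–Helmholtz regression itself — quotient curves generated from
reference apparent values are recovered with their signs intact — while
course-level simulations through the default conversion model necessarily
recover the positive-$\Delta S$ geometry they were generated with.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `t0` | 300 | K | ion temperature at ΔCV = 0; near-ambient source |
| `t_amb` | 298 | K | extrapolation target |
| `gas_mass` | 39.948 | Da | argon trap gas |
| `residence_time` | 1e-4 | s | collision-cell transit; scales $k^\#$ multiplicatively and cancels nowhere, so it is surfaced in every report |
| `r_gas` | 8.314 | J/(mol·K) | convention used in gas-phase energetics tables |
| `steep_lo`, `steep_hi` | 0.1, 0.9 | – | fraction-of-transition bounds of the steep region feeding both linear extrapolations |
| `window_mz` | 0.5 | m/z | peak-matching half-width; charge-reduced species are >100 m/z apart in the reference system |

## Numerical choices

* **Fitting.** Levenberg–Marquardt with analytic Jacobian
  (`minpack.lm::nls.lm`), unweighted, on replicate means (the reference
  workflow fits mean courses; per-replicate fitting is an option). Bounds
  keep plateaus in [0, 110]% and $dx \in (10^{-6}, \mathrm{range}(x)]$.
  Start values take the plateaus from the data extremes and the midpoint
  and width from interpolated 50%/25%/75% transition crossings (a
  Boltzmann sigmoid separates the quartile crossings by $2\,dx\ln 3$); the
  coarser mid-range/tenth-of-span start is kept as fallback. The
  crossing-based start matters: on sharp noiseless courses a too-wide
  width start can drive the optimizer into a degenerate step-function
  corner ($dx \to 0$), which the multi-start plus a bound-collapse check
  rejects.
* **Quality gate.** $R^2 \ge 0.99$ is a warning gate, not a failure: a
  flagged row is still reported.
* **Steep region.** Both extrapolations act on the steep part of the
  course. The default evaluates the *fitted* curve on a dense grid there
  (25 points), giving one smooth extrapolation line per complex; the
  `source = "data"` route instead uses the measured replicate-mean points
  inside the steep region. The data route is exact for forward-model
  simulations (the quotient construction inverts exactly) and is what the
  parameter-recovery tests use, because the forward-model course is not
  exactly a Boltzmann sigmoid and the fitted-curve route then carries a
  small (order 1%) representation bias.
* **Degenerate inputs.** All-zero scans, constant courses, increasing
  educt courses, singular regression designs (< 3 usable points, a single
  effective temperature) and non-trimer educts in reaction enumeration all
  raise explicit errors naming the offending quantity. Fully depleted
  points ($s \le 0$) are excluded upstream of the rate construction.
* **Rounding** happens only at reporting surfaces (2 decimals for %, V and
  kJ/mol; 3 significant figures for $k^\#$ and $K_D^\#$); all internal
  computation is full precision, with energies in J/mol internally and
  kJ/mol in reports.

## The synthetic generator

The generator emulates the reference experiment's structure: the dense
17-step 0–55 V series plus the sparse 8-step second series, two
replicates, educt decay along specified Boltzmann parameters (defaults:
the four reference trimer parameter sets in `foldon_reference_fits()`),
complementary product rise split across release channels by a statistical
branching fraction (2/3 loss of the majority monomer for a 2:1
hetero-trimer), additive Gaussian noise in absolute percent (matching the
replicate scatter of measured courses) truncated at zero, and per-scan
renormalization to exactly 100%. A second generator
(`simulate_thermo_course()`) drives the course from known apparent
$(\Delta H, \Delta S)$ through the conversion model by inverting the
quotient relation $K = ((1-s)/2)^2/s$; the test fixture uses
$\Delta H = 4500$ kJ/mol, $\Delta S = 14.9$ kJ/(mol·K), chosen from the
conversion-model geometry so that $\Delta G$ crosses zero mid-grid
(transition midpoint ≈ 31 V, steep width ≈ 18 V — course shapes comparable
to the measured ones).

What the generator does **not** emulate: isotope envelopes, adduct and
oxidation satellites, chemical noise, m/z-dependent detection efficiency
(exposed as an option but flat by default), ion-optics effects, and any
drift between replicate series. Passing recovery tests therefore
demonstrate correctness of the computational pipeline under the stated
noise model, not robustness to every artefact of real spectra.

Problem sizes used by the test-suite studies: 100 simulated experiments
for midpoint recovery at 1% noise and 50 for end-to-end thermodynamic
recovery, both on the standard two-series grids — enough for stable
medians while keeping the default test run fast. Under those conditions
the midpoint is recovered within 2% relative in ≥95% of runs and apparent
$\Delta H$ well within 5% (median ~1.5%); the $T\Delta S$ recovery error
has a median around 1.3–1.9% — the ~6 steep-region grid voltages at 1%
intensity noise simply do not carry more information, which is worth
knowing before planning a real voltage ramp: a finer grid inside the steep
region, or more replicates, is what buys entropy precision.

## Known limitations

* Absolute $k^\#$, $\Delta H^\#$ and $T\Delta S^\#$ values depend entirely
  on the conversion calibration and residence time; only with an
  instrument-matched `cv_model` do they become comparable across
  laboratories.
* One sigmoid family (Boltzmann); multi-transition courses and alternative
  families (Hill, Gompertz) are out of scope.
* Centroided peak lists only; no profile-mode processing, centroiding or
  charge deconvolution.
* The m/z window assignment assumes baseline-resolved species; satellite
  signals can be folded into a parent species via `satellite_of` but are
  not modelled separately.
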