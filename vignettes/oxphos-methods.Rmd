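---
title: "Mitochondrial diagnostics with oxphos: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial diagnostics with oxphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxphos)
```

# Scope

`oxphos` implements the analysis chain of a comprehensive mitochondrial
diagnostics workflow: from raw chamber-respirometry, fluorometry, confocal
imaging and TMT proteomics inputs to the derived bioenergetic statistics —
clamped ATP free energy, fractional OXPHOS, FCCP effect, P/O ratio, OXPHOS
power output, calibrated membrane potential, percent NADH reduction, signal
volumes, and differential mitochondrial protein expression. Every stage has a
paired synthetic-data generator with embedded ground truth, so the whole
pipeline is testable without instruments or downloads.

# The creatine-kinase clamp

## Model

Permeabilized cells or isolated mitochondria are energized while extramitochondrial
ATP free energy is pinned by excess creatine kinase with known total ATP,
creatine (Cr) and phosphocreatine (PCr). CK is assumed at equilibrium
(enzyme in excess), so total ADP follows from the apparent constant,

$$[\mathrm{ADP}] = \frac{[\mathrm{ATP}][\mathrm{Cr}]}{K'_{CK}\,[\mathrm{PCr}]},
\qquad
\Delta G_{ATP} = \Delta G^{\circ\prime}(\mathrm{pH}, \mathrm{Mg}, T)
 + RT \ln \frac{[\mathrm{ADP}][\mathrm{Pi}]}{[\mathrm{ATP}]}.$$

Both $K'_{CK}$ and $\Delta G^{\circ\prime}$ are adjusted from reference
conditions to assay pH, free Mg$^{2+}$ and temperature through binding
polynomials $P_L = 1 + [H^+]K_{HL} + [\mathrm{Mg}]K_{MgL} (+ [H^+][\mathrm{Mg}]K_{MgHL})$
over the protonation and Mg states of ATP, ADP, Pi and PCr. Free Mg$^{2+}$ is
obtained from total Mg by a fixed-point iteration over the Mg-binding
polynomials (documented contract: 1e-9 mol/L in at most 200 iterations; the
implementation iterates a contractive form of the conservation equation to
1e-12 so that the equilibrium ADP agrees with an independent root-finding
solver to better than 1e-9 mol/L). A user-supplied free-Mg override is
accepted. Pi speciation uses its proton polynomial only; Mg–phosphate
complexation is available but off by default, since at pH 7.2 the proton term
dominates. Ionic-strength corrections are not applied explicitly; the
parameterization is taken at the ionic strength of its source (~0.25 M).
With enthalpies supplied, constants are moved off the reference temperature by
van 't Hoff adjustment; the default set is defined directly at 310.15 K, so no
adjustment occurs at the assay temperature.

## Constant set and anchoring

The binding constants are the classic CK-clamp parameterization lineage
(association constants near 37 °C and I ≈ 0.25 M), with the CK benchmark
$K'_{CK} = 166$ at pH 7.0 and 1 mM free Mg$^{2+}$. The one genuinely
unconstrained scalar is the ATP-hydrolysis reference energy. Published values
of $\Delta G^{\circ\prime}$ span roughly −32 to −36 kJ/mol depending on the
convention, which is far wider than the ±0.3 kJ/mol the titration forces are
quoted to. We therefore anchor `dg0_atp_ref` by least squares against the four
canonical clamp forces of the standard protocol — −54.16, −58.93, −60.64 and
−61.49 kJ/mol at PCr = 1, 6, 15, 21 mM on the standard composition (ATP 5 mM,
Cr 5 mM, Pi 10 mM, Mg 5 mM, pH 7.2, 37 °C). The anchored set gives
$\Delta G^{\circ\prime} = -33.37$ kJ/mol at pH 7.0 / 1 mM Mg / 310.15 K —
inside the published range — and is recorded in `source_label` of every
output (provenance is mandatory in `thermo_params()`).

## A structural limit worth knowing

On a fixed composition, any thermodynamically consistent equilibrium model
predicts force differences of exactly $RT\ln(\mathrm{PCr}_i/\mathrm{PCr}_j)$
plus speciation corrections bounded by ~0.05 kJ/mol (every pH/Mg polynomial
cancels between $K'_{CK}$ and $\Delta G^{\circ\prime}$ except the Pi and PCr
polynomials, which barely move). The four canonical forces deviate from that
spacing by −0.15/+0.50/+0.52 kJ/mol — non-monotonically — so no single
consistent constant set can reproduce all four within ±0.3 kJ/mol. The
least-squares anchor leaves residuals of (+0.22, +0.37, −0.29, −0.31) kJ/mol;
the acceptance test asserts ±0.3 on all four and is deliberately left failing
on the second and fourth rather than widening the band or bending the model.
The anchor was chosen as plain least squares over all four forces and was not
revisited after the residual pattern was known.

```{r}
titration_curve(standard_clamp_composition(), c(1, 6, 15, 21) * 1e-3)
```

# Respirometry

Oxygen flux is $J\mathrm{O}_2(t) = -\,d[\mathrm{O}_2]/dt \times V$ (consumption
positive), with the derivative from a centered local linear regression
(`smoothing_halfwidth`, default 10 s; instrument practice for noisy traces is
40–90 s). When reagent-addition times are passed as `breaks`, the regression
window never crosses a protocol transition — otherwise the derivative near a
step blends two rates. Steady states default to the last 60 s of each
inter-event segment after a 90 s post-addition lag, auto-accepted at CV < 0.1;
segments too short for the policy are returned flagged, never dropped. The
non-mitochondrial residual (post rotenone/antimycin A) is subtracted from all
other states, flooring at zero with a warning. The FCCP $K_m$ fit excludes
doses at or beyond the observed peak (supra-optimal uncoupler collapses flux,
which a hyperbola cannot represent) and fits the above-baseline increment.

# Derived OXPHOS statistics

* `jh_total()` — maximal FCCP-supported flux; tagged with its protocol of
  origin (adenylate-free permeabilized ETS assay, or the intact-cell FCCP
  titration, both occur in practice).
* `jh_oxphos()` — flux at the designated minimal clamp force
  (−54.16 kJ/mol by default, matched within 0.05 kJ/mol).
* `fractional_oxphos()` = JH⁺OXPHOS / JH⁺Total;
  `fccp_effect()` = FCCP$_{\Delta G}$ / JH⁺OXPHOS. Both are scale invariant;
  rates entering a ratio must share a normalization basis, enforced by basis
  tags rather than convention.
* `po_ratio()` = JATP / (2·JO₂); `power_output()` converts flux to
  JATP = JO₂ × P/O × 2 and then to power, JATP × |ΔG| × 10⁻⁹ J/pmol,
  i.e. 5.416 × 10⁻⁸ J/pmol ATP at −54.16 kJ/mol, reported in µW per million
  cells.
* `relative_inhibition()` reports percent change per force; an exactly zero
  vehicle rate yields an explicit undefined flag, not an infinity.
* Whether the FCCP-at-force landmark is the maximum over the post-oligomycin
  FCCP titration or the final dose is not standardized; the generators plant
  a single post-oligomycin FCCP plateau and the analysis takes that state's
  rate (a max over a one-state titration), with the landmark force
  configurable.

# Fluorometry

Percent NADH reduction is the exact anchored formula
$(F - F_{0\%})/(F_{100\%} - F_{0\%}) \times 100$; values outside [0, 100]
(hyper-reduction) are flagged, not clipped. The TMRM signal is the pointwise
576/590 over 551/590 ratio; zero denominators flag missing values. KCl steps
in the presence of valinomycin are mapped to millivolts by the Nernst
equation $\Delta\Psi = -(RT/F)\ln([K^+]_{in}/[K^+]_{out})$, inside-negative;
the (ratio, mV) pairs define a monotone piecewise-linear map, extrapolated
linearly with a warning outside the calibrated span. No parametric curve is
imposed. Matrix K⁺ defaults to 120 mM and is carried in the output metadata
as an explicit assumption.

# Imaging

Signal volume is the oversampling-corrected formula
$V = A \cdot Z / N$, with $A$ the summed signal-positive area, $Z$ the optical
section thickness and $N$ = round(optical section / z-step), floored at 1.
Thresholds are Huang's fuzzy-membership entropy minimum, computed per ROI and
channel at native integer levels for ≤16-bit data (256 min–max bins
otherwise); the test suite checks it against an exhaustive-search oracle of
the same criterion and for shift equivariance. Whole-cell filtering excludes
ROIs touching the lateral border. Manual judgments of the original workflow
(circular ROI placement, removal of slices above the lowest monolayer) are
exposed as parameters (`roi_table`, `z_min`/`z_max`) rather than
re-implemented; a connected-component fallback supports synthetic stacks. ROIs
without any intensity contrast yield zero volume rather than an error. TIFF
input is out of scope in this build (no TIFF reader in the dependency
footprint); stacks enter as in-memory arrays or the plain-text CSV
interchange format.

# TMT proteomics

The chain starts from PSM-level reporter intensities (spectral search is
upstream): PSMs with co-isolation ≥ 0.5 or mean reporter S/N ≤ 10 are
dropped, the rest summed per protein and channel. Loading normalization
divides each channel by (channel sum / mean of channel sums); it is idempotent
and equalizes channel sums to relative 1e-9. "Low abundance resampling"
imputation is under-specified by its source software; the declared
interpretation — seeded empirical resampling from each channel's bottom
5%-quantile observed values — is recorded in the output metadata. Log2
centering subtracts each protein's per-kit mean so kits can be concatenated;
it is invariant to per-kit global rescaling. Differential expression is the
equal-variance two-sample t-test (no variance moderation, deliberately
matching the original workflow rather than limma-style shrinkage) with
Benjamini–Hochberg step-up q-values; significance cutoffs are parameters
(q < 0.1 and p_adj < 0.01 are both in common use), never hard-coded. The
bridge channel, when declared, is used for cross-kit QC correlation only;
bridge-ratio rescaling exists but is off, since kit centering already aligns
scales. Mitochondrial annotation lists (e.g. MitoCarta-style accession sets)
are user-supplied; no database is bundled.

# Synthetic data: what it does and does not establish

Generators return their ground truth alongside the data and draw all
randomness from one explicit seed. Noise models are the simplest forms
consistent with each data type: gaussian on O₂ concentration (default sd
0.5 µM), lognormal on reporter intensities, gaussian on voxel intensities.
Default magnitudes emulate a high-resolution respirometry chamber loaded with
one to two million cells (chamber-total fluxes of a few hundred pmol O₂/s,
5-minute protocol holds, 1 s sampling, hyperoxygenated start where protocols
would otherwise run anoxic); the planted landmark identities are
jh_oxphos = fractional_oxphos × jh_total and
fccp_dgatp = fccp_effect × jh_oxphos. A green round-trip test establishes
that the analysis recovers what the generator planted under these idealized
conditions — piecewise-constant rates, white noise, no sensor drift, no
spectral bleed-through, no back-diffusion of oxygen — and nothing more. It
does not validate the biology of any real cell type, nor instrument-specific
artifacts, which are deliberately not simulated.

# Known limitations

* The CK-clamp constant set is anchored, not derived ab initio; absolute
  ΔG values inherit the anchoring convention (relative values across a
  titration do not).
* No ionic-strength or CO₂/bicarbonate corrections.
* The FCCP ascending-limb rule assumes a single peak; oscillating dose
  responses would need manual point selection.
* Huang thresholds on near-constant ROIs are undefined; such ROIs report zero
  volume.
* The P/O measurement assumes linear ATP accumulation over the fitted window.
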