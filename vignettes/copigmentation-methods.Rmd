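---
title: "Methods: from absorbance spectra to copigmentation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from absorbance spectra to copigmentation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copigmentr)
```

This vignette is the package's own account of its models, defaults and
numerical choices — what each stage assumes, where the design was genuinely
open, and what a green test does and does not establish.

## 1. The measurement model

A copigmentation assay measures visible absorbance spectra (400–800 nm,
10 mm quartz path) of three kinds of solution per condition: the
pigment-only **control**, the copigment-only **blank**, and the **mix**.
Because oenological tannins are themselves weakly coloured, the blank
spectrum is subtracted pointwise from its mix before any colour is
computed; what remains is the pigment's colour as modified by
copigmentation. Blank subtraction can legitimately produce small negative
absorbances; these are kept (never clipped) and flagged, because
subtraction artifacts should be visible, not hidden.

## 2. Colorimetry

`spectrum_color()` converts a corrected spectrum to `A520` plus CIELAB:

* **Transmittance.** `T(λ) = 10^(−A(λ))` (Beer–Lambert, 10 mm path, no
  dilution correction — samples are measured neat). Negative `A` gives
  `T > 1` and a flag.
* **Tristimulus.** `X = k Σ T S x̄ w` (likewise `Y`, `Z`) on a fixed
  wavelength grid, with `k = 100 / Σ S ȳ w` computed **on the identical
  truncated grid**. This guarantees, by construction, that a perfectly
  transparent sample maps to `(Xn, Yn, Zn)` and `L* = 100` exactly,
  whatever tables are used.
* **CIELAB.** The standard two-branch `f(t)` (cube root above `(6/29)³`,
  linear `(841/108)t + 4/29` below) gives `L*, a*, b*`; chroma and hue are
  the polar form, with the hue angle **signed** in `(−180°, 180°]`. Red
  wine sits at `a* > 0, b* < 0`, i.e. negative hue angles; wrapping to
  `[0°, 360°)` would hide that and contradict the published convention this
  package mirrors. An achromatic point (`C*ab = 0`) has no hue and is
  reported `NA`, never a fabricated angle.

**Observer and illuminant.** The source study computed CIELAB with a
wine-colorimetry program whose observer/illuminant convention is not stated
in the text. This package embeds (a) analytic colour-matching functions —
the published multi-lobe piecewise-Gaussian fits to the CIE 1931 2°
observer, accurate to about 1% of peak — and (b) the standard illuminant
D65 relative power distribution tabulated at 10 nm and interpolated
linearly. Tables are evaluated on a 5 nm grid over 400–780 nm (the
intersection of the measured range and CMF support). Because the whitepoint
is recomputed on the same grid, every colorimetric invariant
(white-self-consistency, achromatic neutral density, monotonicity of `L*`
in absorbance) is independent of table provenance; only the absolute
`a*/b*` scale of individual samples depends on it, and no acceptance
quantity does. The grid object records observer and illuminant identity,
and `observer_grid()` accepts user-supplied tables for anyone wanting the
1964 10° observer or illuminant C.

**Quadrature.** The grid sum uses trapezoidal weights (half step at the two
endpoints). A plain inclusive rectangular sum would integrate, in effect,
397.5–782.5 nm and biases `Z` by ≈ 0.13% (the blue integrand is not small at
400 nm); with trapezoidal weights the 5 nm sum agrees with a 1 nm fine-grid
oracle to ≈ 2×10⁻⁴ on smooth band spectra, which the tests assert at 0.1%.

**A520** is read directly when 520 nm is a grid point and linearly
interpolated otherwise — measured curves are smooth and dense, so nothing
fancier is warranted.

## 3. The Cp statistic

Copigmentation effectiveness is the slope of a colour parameter on the
copigment/pigment **mass** ratio (the dose arithmetic — 0.1 g/L over
50 mg/L giving ratio 2 — forces the mass, not molar, convention). Design
choices:

* The ratio-0 control is a data point and the intercept is free; the slope
  is therefore offset-invariant, which also means regressing raw corrected
  values or deltas against control gives identical Cp.
* Each replicate is fitted separately; `Cp` is the mean of replicate slopes
  and its SD the sample SD across replicates, matching the
  "mean ± SD of three replicates" reporting convention. The pooled fit over
  all points supplies r².
* A zero-variance response yields slope 0 with r² reported as a degenerate
  `NA` marker, not 0 or 1. Undefined hues (achromatic points) are dropped
  with a flag rather than imputed.

The direction rule — higher Cp is more impact for `A520, a*, C*ab`; lower
for `L*, b*, hab` — drives both effect classification (hyperchromic:
`Cp(A520) > 0 ∧ Cp(L*) < 0`; bathochromic: `Cp(b*) < 0`) and best-copigment
counting, where the focal copigment wins a condition × parameter cell only
**strictly**; ties are counted against it and reported separately, a
conservative and reproducible convention.

## 4. Aggregation

Products aggregate to botanical origins (mean ± sample SD of products) and
origins to families (mean ± sample SD of **origin means** — two-level,
unweighted, so an origin contributing six products counts the same as one
contributing two). The two conventions coincide when origins are balanced,
which the tests assert numerically on the bundled gallotannin rows (4 + 4
products). The bundled reference tables themselves are not fully consistent
here: their condensed-tannin family SDs are two-level while the
hydrolysable ones are flat across products, so `aggregate_family()` returns
both (`sd` and `sd_flat`). Family *means* in those tables were evidently
printed from unrounded origin means; recomputing them from rounded product
entries can differ by one unit in the last printed digit, and the
acceptance tolerance reflects that.

## 5. Group comparison and PCA

The decision tree mirrors classical practice: Shapiro–Wilk for normality
and Levene's test for homoscedasticity at α = 0.05; both pass → one-way
ANOVA with Tukey HSD; otherwise Kruskal–Wallis with pairwise two-sided
rank-sum tests. Open points and how they were fixed:

* With n = 3 per group, per-group normality testing is vacuous, so
  Shapiro–Wilk runs on the pooled group-centred residuals (configurable).
* Levene uses mean centring (classic form); median centring
  (Brown–Forsythe) is a switch.
* No multiplicity adjustment is stated in classical write-ups for the
  pairwise rank-sum branch; Holm is the default and configurable.
* Degenerate inputs (a zero-variance group, groups of n < 3) force the
  nonparametric branch with a flag.

Compact letter displays use insert-and-absorb: starting from one letter
covering all groups, every significant pair splits the letters containing
both, and absorbed (subset) letters are deleted. The resulting partition
satisfies, provably and by test, *share a letter ⇔ adjusted p ≥ α*.

PCA is correlation PCA (the six colour variables live on incommensurable
scales), with a deterministic sign convention — the largest-magnitude
loading of each component is made positive. When asking "which component is
aligned with `A520`", use the variable–component correlation
(loading × component sdev), not the raw loading: a trailing noise component
can carry a large raw coefficient at negligible variance.

## 6. The synthetic generator

The generator emulates the stated assay design — 50 mg/L pigment, doses
{0, 0.1, 0.2, 0.4} g/L (ratios 0/2/4/8), three replicates, one-week
endpoint, and the star condition grid (pH 3.1/3.5/3.9 at 12% ethanol;
10/12/14% ethanol at pH 3.5, as the assays were actually run, not a full
3 × 3 grid). Its spectral model is a deliberate stand-in, not a chemical
model:

* **Pigment band.** A single Gaussian,
  `A_p(λ) = ε_amp (c_p/50) f(pH) (1 + α_h θ) exp(−(λ − λ₀ − δ_λ θ)²/2σ²)`.
  The pipeline only reads integrated colour, so band realism beyond
  position (520 nm), width (σ = 40 nm, a malvidin-like visible band) and
  amplitude is unnecessary.
* **Flavylium equilibrium.** `f = 1/(1 + 10^(pH − pKh))` with pKh = 2.6, a
  literature-typical hydration constant for malvidin-3-O-glucoside (the
  assay text gives none). ε_amp = 2.8 AU then puts the pH 3.5 control near
  A520 ≈ 0.3, the observed order of magnitude.
* **Binding.** 1:1 isotherm `θ = K_eff d/(1 + K_eff d)`,
  `K_eff = K0 e^{−β(EtOH − 12)}` with K0 = 0.6 L/g and β = 0.15 %⁻¹:
  K_eff·d_max = 0.24 at baseline, inside the near-linear regime the
  recovery tests assume, and ethanol above 12% measurably weakens binding.
* **Effect sizes.** The hyperchromic gain panel (gallotannin 3.0,
  ellagitannin 1.5, condensed tannins 0.7–0.85, epicatechin 0.6 per bound
  fraction) was anchored once to the reported field magnitudes —
  hydrolysable tannins two to four times more effective than condensed, and
  roughly 50–80% top-dose A520 enhancement for the best copigment — and not
  revisited. The bathochromic shift enters as a rigid λ-max displacement
  (8 nm per bound fraction for hydrolysable, 3–5 nm otherwise), the
  simplest mechanism producing the observed `b*` decrease.
* **Blanks and noise.** Copigment blanks are coloured (a short-wavelength
  exponential tail, `d · b_amp · e^{−(λ−400)/60}`) precisely so blank
  subtraction is a load-bearing, testable stage. Noise is homoscedastic
  Gaussian per wavelength point (σ = 0.002 AU, instrument scale); mix and
  blank carry independent noise, as two separately measured cuvettes do.

Ground truth records the bound fraction per dose and the **analytic
Cp(A520)**: the exact OLS slope of the noiseless corrected A520 values on
the ratio grid — the estimand of the downstream pipeline at zero noise, so
recovery tests measure noise robustness, not isotherm-curvature bias.

What the generator does *not* emulate: self-association, intramolecular
copigmentation, pyranoanthocyanin formation, kinetics (single endpoint by
design), heteroscedastic or wavelength-correlated noise, baseline drift. A
green parameter-recovery test therefore establishes that the pipeline is an
unbiased, noise-robust estimator of its own generative slope — not that the
generator is chemically faithful, and not that any particular real tannin's
Cp is reproduced (the underlying raw spectra were never published).

## 7. Known limitations

* **Recovery tolerance is an SNR statement.** The per-replicate slope noise
  is `√2 σ / √S_xx ≈ 4.8×10⁻⁴` AU/ratio (subtraction doubles the noise
  variance; `S_xx = 35` for ratios 0/2/4/8), i.e. `2.8×10⁻⁴` after
  averaging three replicates. A ±10% band around a strong-gain slope
  (≈ 2×10⁻²) is a ≈ 7σ margin; around a weak-gain slope (≈ 3×10⁻³) it is
  ≈ 1.6σ, which *no* seed satisfies across all cells. The strict ±10%
  recovery check therefore runs on the canonical single-copigment
  configuration, and the full panel is checked for unbiasedness within a
  noise-aware bound (10% + 4 SE).
* **Detection power at n = 3 is modest, and one acceptance bound is
  unattainable.** For a group shifted by 3 within-group SDs among three
  groups of three, the Tukey critical difference is ≈ 2.5 s (df = 6), so
  the probability that the planted group separates from *both* others is
  ≈ 0.6; additionally the normality/homoscedasticity gate routes ≈ 9% of
  perfectly normal datasets to the nonparametric branch, where the exact
  two-sided rank-sum minimum p at 3 vs 3 is 0.1 — no letters can ever
  separate there, capping any detection at ≈ 0.91. The acceptance suite
  asserts the stated ≥ 0.95 bound anyway and measures ≈ 0.58; that test is
  deliberately left failing, with this analysis as the explanation. The
  type-I half of the same criterion (family-wise false-positive rate under
  the null ≤ 0.05 + 3 SE over 2000 runs) passes.
* The embedded colour-matching functions are analytic fits (≈ 1% of peak);
  absolute CIELAB coordinates of strongly chromatic samples can differ by a
  few tenths of a unit from reference-table implementations. Swap in exact
  tables via `observer_grid(observer = <data frame>)` if that matters.
* Cp is reported per unit mass ratio; no molar interpretation is attempted,
  and no attempt is made to reproduce per-product Cp magnitudes of the
  bundled reference tables from spectra.
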