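---
title: "Methods: NIR water-structure chemometrics and hydration-shell scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR water-structure chemometrics and hydration-shell scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aquaredox)
```

# The problem

Redox couples such as GSH/GSSG and NADH/NAD⁺ differ chemically at a
single site — a thiol S–H versus a disulfide S–S, a reduced versus an
oxidized nicotinamide ring — and their dilute aqueous solutions look
almost identical in raw near-infrared transmittance. What does
differ is the *water* around the reactive site. A thiol sulfur can both
accept hydrogen bonds from water (OH−S) and donate its own hydrogen
(SH−O); a disulfide sulfur can only accept. The package turns that
asymmetry into two measurable signals:

1. solvation-shell bands in the first overtone of water (1300–1600 nm,
   notably near 1362 and 1381 nm) that appear in *difference spectra*
   (sample minus buffer background) of the reduced form and are absent
   for the oxidized form, quantifiable by latent-variable regression; and
2. the population and residence of waters hydrogen-bonded to the sulfur
   in a solvation trajectory, summarized by a radial distribution
   function and a directional, residence-weighted interaction score,
   with the structural zero SH−O = 0 for any disulfide.

# The chemometric model

## Preprocessing chain

The default quantification pipeline, in order:

| step | operation | default | rationale |
|---|---|---|---|
| 1 | `mask_regions` | keep 1100–1850 + 2050–2400 nm | below 1100 nm and 1850–2050 nm are noise/saturation regions at 1 mm path length (552 channels remain on the 2 nm grid) |
| 2 | `snv` | on | removes per-spectrum scatter gain and offset (row-wise standardization, n−1 denominator) |
| 3 | `savitzky_golay` | window 15 channels, polyorder 2, derivative 0 | noise reduction; each contiguous grid segment is filtered separately so the window never bridges the masked gap |
| 4 | PCA + `mahalanobis_screen` | χ²(k) quantile 0.975, k = components reaching 95% variance | outlier exclusion in score space, d² = Σ score²/λ |
| 5 | `difference_spectra` | subtract the *mean* of the PBS blank spectra | isolates solute + hydration-change signal |
| 6 | `fit_osc` | 1 component | removes the dominant response-orthogonal variance before regression |
| 7 | `fit_plsr` (NIPALS PLS1) | latent variables chosen by minimum LOO RMSECV, cap 10 | concentration model; regression vector b = W(PᵀW)⁻¹q |
| 8 | `cross_validate` / `cv_plsr` | leave-one-out (series), leave-five-spectra-out (mixtures) | held-out RMSE and R²; all response-using steps refit inside each training fold |

Whether row-wise SNV is applied before or after the background
subtraction is a genuinely open choice; the package subtracts the
(identically preprocessed) blank mean *after* SNV/SG, because SNV applied
to near-zero difference spectra would normalize away the concentration
scale itself. Both the order and every parameter above are config keys of
`run_spectra_quant()`.

Mixtures follow the reduced chain the mixture analysis calls for: mask
to 1300–1600 nm, subtract the blank mean, two-response PCR
(`fit_pcr`) with the component count chosen by leave-five-out CV — no
SNV or smoothing.

## Numerical choices

* **PLS and PCA sign convention.** Components are sign-fixed so the
  largest-magnitude weight/loading element is positive; results are then
  reproducible across linear-algebra backends.
* **OSC weight regularization.** The weight vector of each removed
  component is estimated in the subspace holding 99% of the X variance
  (`weight_energy`). The unrestricted pseudo-inverse reproduces the
  score vector exactly — noise directions included — and those
  overfitted weights inject noise when the correction is applied to
  held-out spectra. After the final orthogonalization step each stored
  score satisfies |tᵀy| ≤ 1e−8·‖t‖‖y‖ by construction.
* **Latent-variable / component selection.** One NIPALS (or PCA) run at
  the cap per fold provides held-out predictions for every model size in
  a single pass; the reported size minimizes pooled RMSECV.
* **Rank guards.** PLS stops with an error when the covariance vector
  vanishes (n_lv beyond the effective rank); PCR refuses k above the
  rank of centred X. Degenerate inputs (constant spectra in SNV,
  constant responses in R², zero-variance channels in autoscaling) raise
  descriptive errors rather than NaN.
* **Peak localization.** `regression_vector_peaks` reports local maxima
  of |b(λ)| inside a window (default 1300–1600 nm) ranked by height,
  with a flanking-valley prominence filter.

## Reading band absence

For the oxidized-form (GSSG-like) model the regression vector is *not*
flat around 1381 nm even though no band is designed there: SNV couples
the solute's 1450 nm water-displacement dip to the broad background
band, producing flank lobes near 1380 and 1520 nm (the inflection
regions of the 1450 nm band). "Absence" of the thiol signature is
therefore assessed as: the model's two leading peaks are not the
1362/1381 pair, no leading peak falls on the first-shell 1362 nm band,
and the reduced-form model concentrates several-fold more |b| mass in
1350–1400 nm than the oxidized-form model (measured ≈ 0.23 vs ≈ 0.08 of
total |b| mass on the default series). This is the discrimination the
difference spectra are claimed to carry, stated in a form robust to the
SNV lobes.

# The hydration model

## Geometric hydrogen bonds

A directed bond D–H···A exists when the donor–acceptor minimum-image
distance is within an element-pair cutoff — 3.5 Å for O···O, 4.0 Å for
O···S (motivated by the ≈ 3.8 Å first peak of the sulfur–water RDF) —
and the D–H···A angle is within 30° of linear. All three are
configurable (`hbond_criteria`); only orthorhombic boxes are supported,
anything else is rejected with a clear error.

## RDF, coordination, score

* `compute_rdf`: g(r) = ⟨pair count in shell⟩ / (N_ref·ρ·V_shell)
  averaged over frames, V_shell = (4/3)π(r₂³−r₁³), ρ = N_target/V_box,
  r_max ≤ half the smallest box edge. For a disulfide the reference is
  the union of both sulfurs and per-sulfur quantities divide by 2.
* `first_peak`: first local maximum above g = 1.3 inside 2–5 Å, after a
  3-bin moving average — small-radius shells hold few pairs, so raw bins
  fluctuate around the bulk level of 1 and an unsmoothed threshold of
  ~1 would "find" shells in an ideal gas.
* `coordination_number`: N(r) = 4πρ∫g r²dr by the midpoint rule over the
  histogram bins, which is the quadrature consistent with binned g (it
  reproduces direct shell counts to rounding; verified against direct
  counting within 2% on every fixture).
* `bond_intervals` / `interaction_score`: maximal runs of consecutive
  bonded frames per directed pair; the score sums L^(1+α) over intervals
  with L ≥ a persistence threshold. The defaults (threshold 1, α = 0)
  make the score the total bonded-frame count — a tally in which each
  bond contributes once per frame it survives, i.e. weighted by its
  residence time. Stricter readings of residence weighting are available
  through the two parameters; the default is a documented
  interpretation, not a claim about the original analysis.

# The synthetic generators

## Spectra

`generate_spectra_set` emulates the study layout: 1–10 mM in 1 mM steps,
25 replicates per level per analyte, 25 buffer blanks, on a
1100–2400 nm grid at 2 nm (651 channels). Each spectrum is

```
gain · (background + Σ_a c_a · signature_a) + offset + slope·(λ−λ_mid) + ε
```

with gain ~ N(1, 0.01), offset ~ N(0, 5e−4 AU), slope ~ N(0, 5e−7
AU/nm), ε ~ N(0, 1e−3 AU) per channel. The PBS background is a fixed sum
of broad Gaussians (water first overtone at 1450 nm, σ 60 nm;
combination band at 1940 nm inside the later-masked stretch) plus an
offset. Analyte signatures are Gaussian band sets with per-mM
amplitudes; the built-ins encode the qualitative redox contrast: the
reduced forms carry narrow positive solvation bands (GSH at 1362 and
1381 nm; NADH at 1363 nm; NAD⁺ at 1383 nm) and the oxidized disulfide a
deeper negative 1450 nm dip with no 1362/1381 features; both share amide
combination bands at 2175/2279 nm. Band amplitudes are free parameters
(no molar absorptivities are established for these features), set so
10 mM features are 1–3% of the background. The narrow-band width is
σ = 5 nm (FWHM ≈ 12 nm): two equal Gaussians 19 nm apart only resolve
into two maxima when σ < 9.5 nm, so visibly resolved 1362/1381 peaks —
which the real difference spectra show — require widths in this range,
and σ = 5 keeps them resolved after the default 15-channel smoothing.

What the generator does *not* emulate: temperature-dependent band
shifts, scattering theory, instrument line-shape, correlated (pink)
noise, or any physical coupling between concentration and the hydrogen-
bond network. A pipeline that passes on these fixtures is verified as
*bookkeeping and estimation machinery* — unbiased recovery, correct CV
hygiene, correct band localization — not as validated against real
instrument data.

## Trajectories

`generate_solvation_trajectory` places a thiol (S + bonded H) or
disulfide (S–S) at the centre of a 30 Å box with 200 waters over 2000
frames (a desk-scale stand-in for production-simulation sizes; all
configurable). A hydrogen-bond schedule — either supplied or generated
(`auto_bond_schedule`, mean residence 20 frames, occupancy 0.6 bonds per
frame per direction stream) — is realized geometrically each frame:
scheduled waters sit at donor–acceptor distance U(3.0, 3.6) Å with
D–H···A angle U(160°, 180°), inside the detection criteria with margin;
off-schedule and unscheduled waters are re-drawn uniformly in bulk at
≥ 6 Å from every sulfur, violating the distance criterion by ≥ 2 Å.
Placement cones keep scheduled waters from accidentally satisfying the
*other* direction's geometry (donating waters avoid the S–H axis;
disulfide shell waters stay in the hemisphere away from the second
sulfur, which keeps them ≥ 4.3 Å from it). There is no integrator and
no physics: waters teleport between frames. The generator exists so the
analysis layer has exact ground truth — recovered intervals equal the
schedule exactly, and scores match a naive per-frame counting oracle —
and its occupancy default makes the thiol/disulfide per-sulfur score
ratio ≈ 2 by construction of the donor-direction asymmetry, mirroring
the mechanism (not the magnitudes) of the original comparison.

`ideal_gas_frames` provides the analytic RDF oracle: uniform points give
g(r) = 1 and Poisson neighbour counts ρ·(4/3)πr³.

# Problem sizes and determinism

The shipped tests run the chemometric chain at 10 levels × 25 replicates
(the study layout) for the acceptance-style checks and at 3–6 replicates
for unit tests; trajectory checks use 2000 frames × 200 waters where the
properties are scale-sensitive (oracle equality, the structural zero,
the ideal-gas limit) and a few hundred frames elsewhere. Every stochastic
step is seeded; workflows embed their seed and config in the returned
report, and identical configs reproduce bit-identical metrics.

# Known limitations

* Band amplitudes, widths and the background shape are plausible but not
  fitted to any measured spectrum; absolute RMSE values on synthetic
  data say nothing about instrument performance.
* SNV mixes solute bands with the background shape (the 1380/1520 nm
  flank lobes discussed above); derivative-based preprocessing would
  trade this for other artifacts and is available via the SG derivative
  option but is not the default.
* OSC typically does not improve held-out error here (its value is model
  simplicity — one latent variable instead of several); on these fixtures
  it changes LOO RMSE by −1% to +20% at R²cv ≥ 0.998.
* The hydrogen-bond model is purely geometric; energetic or electronic
  definitions, water orientational order, and proton-transfer modelling
  are out of scope.
* Triclinic boxes, JCAMP/SPC instrument formats, and interpolation
  between mismatched wavelength grids are deliberately unsupported
  (explicit errors instead).
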