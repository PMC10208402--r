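---
title: "Apparent q-space metrics from a single shell: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent q-space metrics from a single shell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amura)
```

## The model

Diffusion MRI measures the attenuation `S(b, u)/S0` of the water signal
under diffusion weighting `b` along gradient direction `u`.  The ensemble
average propagator (EAP) — the displacement density of water in a voxel —
yields restriction indices as q-space integrals of the normalized signal
`E(q)`: the return-to-origin probability `RTOP = ∫ E(q) dq` over R³, the
return-to-plane probability `RTPP = ∫ E(q e₁) dq` over the principal axis,
the return-to-axis probability `RTAP = ∫ E(q) dq` over the plane orthogonal
to `e₁`, and generalized moments `ϒ^γ = ∫ |q|^γ E(q) dq`.  Computing them
exactly needs dense multi-shell sampling of q-space.

This package instead assumes the *mono-exponential* radial model that is
well supported in brain tissue up to `b ≈ 2000 s/mm²`:

```
E(q·u) = exp(-4π²τ q² D(u)),     4π²τ q² = b at the acquired shell,
```

with `D(u) = -log(S(u)/S0)/b` the apparent diffusivity along `u` and `τ`
the effective diffusion time.  The radial integrals then reduce, exactly,
to angular averages of powers of `D`:

* `RTOP = (4πτ)^(-3/2) ⟨D^(-3/2)⟩` over the sphere,
* `RTPP = (4πτ D(e₁))^(-1/2)`,
* `RTAP = (4πτ)^(-1) ⟨D^(-1)⟩` over the equator orthogonal to `e₁`,
* `ϒ^γ = 2π Γ((γ+3)/2) (4π²τ)^(-(γ+3)/2) ⟨D^(-(γ+3)/2)⟩`, with
  `qMSD = ϒ²` and the order-1/2 moment `ϒ^(1/2)`; `ϒ⁰` is RTOP again.

Because the model only holds near the acquired shell, these are *apparent*
values tied to the acquisition's b-value — useful as group-level contrast,
not as absolute EAP quantities.

The two anisotropy indices measure how far a spherical profile lies from
its closest isotropic counterpart in the L² sense.  For spherical-harmonic
coefficients `c` the raw index is `t = sqrt(1 - c₀₀²/Σc²)` ∈ [0, 1],
applied to the attenuation profile `E(u)` (APA) or to `D(u)` (DiA).  The
raw index compresses toward small values, so a fixed monotone contrast map
`σ_ε(t) = t^{3ε}/(1 − 3t^ε + 3t^{2ε})` with `ε = 0.4` is applied by
default (`scale_anisotropy = FALSE` recovers the raw index).  The index is
invariant to overall scaling of the profile; for `D(u)` this also makes
DiA invariant to global diffusivity changes.

## Numerical engine and its choices

**Spherical harmonics.**  All angular averages use a real, antipodally
symmetric (even degrees only), orthonormal basis, coefficients ordered by
degree `l` and order `m` with the constant `Y₀₀ = 1/(2√π)` first.  Fitting
is penalized least squares `c = (BᵀB + λR)⁻¹Bᵀy` with the Laplace–Beltrami
penalty `R = diag(l²(l+1)²)`.  Defaults: order `L = 6` (28 coefficients,
needs ≥ 28 directions; 61 are typical), `λ = 0.006`, the standard values
for single-shell spherical deconvolution-type fitting.  `τ = 70 ms`.

**Transform then fit.**  Each metric fits the SH basis to the required
*power* of `D` (e.g. `D^(-3/2)`) rather than raising a fitted profile to a
power: the closed forms consume spherical means of powers, and the mean of
a fitted profile is exact up to least-squares error (the `c₀₀` term),
avoiding negative-lobe artifacts of powering a truncated expansion.

**Equator averages.**  The average of a degree-`L` expansion over the
great circle orthogonal to an axis is computed in closed form through the
Funk–Radon identity (circle average of `Y_lm` = `P_l(0)·Y_lm(axis)`); it
coincides with the `K ≥ 16`-point sampled trapezoid used by
`eval_on_circle()` because a degree-6 expansion restricted to a circle is a
trigonometric polynomial of degree ≤ 6.

**Clipping and floors.**  `D` is clipped to `[1e-5, 1e-2] mm²/s` before
the negative powers (clip counts are reported as QC), signals are clipped
into `(0, S0]` before logs, and tensor eigenvalues are floored at
`1e-7 mm²/s`, keeping every transform finite on noisy data.  The tensor
itself is ordinary least squares on the log signal — the common default of
clinical DTI tools, adequate at the SNR ~30 regime simulated here —
including the `b = 0` rows, which identify the intercept (on a single
shell the diagonal design columns alone are collinear with it).

**Known bias.**  At `L = 6` the spherical *means* of the `D` powers are
accurate to ≲ 0.5% for profiles up to zeppelin anisotropy ratio 10
(FA ≈ 0.9).  The *pointwise* evaluations behind RTPP (profile at `e₁`) and
especially RTAP (equator ring of the `D^(-1)` fit) additionally inherit
truncation and penalty shrinkage: with `λ = 0.006` the `l = 6` band is
attenuated by roughly a factor 3 at 61 directions, biasing RTAP low by
several percent at high anisotropy.  The bias is common to all subjects
fitted with the same protocol, so group contrasts — the quantity this
package exists for — are unaffected; absolute RTAP/RTPP values should be
read with that caveat.  The test-suite oracles therefore check the radial
q-space calculus against brute-force integration over the same fitted
profiles, and the spherical-mean metrics additionally against the exact
model profiles.

## The synthetic cohort

Real single-shell clinical cohorts of this kind are not public, so the
validation apparatus runs on a generator whose voxels follow a
two-compartment model: a zeppelin (axially symmetric tensor, fraction `f`,
diffusivities `d∥ ≥ d⊥`) plus isotropic free water,

```
S(b, u) = f · exp(-b(d⊥ + (d∥−d⊥)(uᵀμ)²)) + (1−f) · exp(-b·D₀).
```

Defaults are textbook healthy white matter: `d∥ = 1.7e-3`,
`d⊥ = 0.3e-3 mm²/s`, `f = 0.8`, and `D₀ = 3.0e-3 mm²/s` for free water at
body temperature.  The acquisition default is one `b = 0` volume plus 61
electrostatically spread directions at `b = 1000 s/mm²`; direction sets
are deterministic.

**Signal families.**  Two one-parameter families isolate what the q-space
metrics add over DTI.  Sweeping `f` from 0.3 to 1, `d⊥` is root-found per
`f` so the *fitted* tensor keeps either FA or MD at the `f = 1` reference
value (`|ΔFA| ≤ 1e-4`, `|ΔMD| ≤ 1e-4·MD`).  Feasibility shapes both
defaults:

* *Constant FA*: with 70% free water at `D₀ = 3e-3`, the fitted FA cannot
  exceed ≈ 0.46 at `f = 0.3`, so the family's default reference uses
  `d⊥ = 0.82e-3` (target FA ≈ 0.43), the anisotropy level that admits a
  solution over the whole grid.  Along it, MD falls with `f` while RTOP,
  qMSD and `ϒ^(1/2)` rise, and RTAP's curve is the near-mirror image of
  MD's (equal normalized change of opposite sense) — anisotropy pinned,
  the q-space metrics still see the free-water change.
* *Constant MD*: free water is the fastest compartment, so holding the
  fitted MD at the `f = 1` reference is only possible for `f ≳ 0.82`;
  infeasible grid points are reported and excluded.  On the feasible
  branch, pinning MD forces `d⊥` up as `f` grows, de-anisotropizing the
  voxel: FA, DiA and APA all fall together, strictly and monotonically —
  the anisotropy metrics co-vary while MD is blind to the change.

**Cohorts.**  A cohort spec defines three groups (HC/EM/CM, the usual
control / episodic / chronic design, defaults 50/51/56), a toy block atlas
(12 cuboid regions by default, configurable up to 48, each with a
one-voxel-thick central-plane "skeleton"), per-region baseline parameters
and per-group, per-region offsets (the injected effects).  Subject-level
variation has two parts: population scatter on `f` (SD 0.075 by default)
and jitter proportional to each offset (10%).  The scatter value is the
generator's power calibration: with the canonical `−0.05` offset on `f` it
yields per-region Cohen's d ≈ 0.65, which is what makes the prescribed
validation pattern internally consistent — near-complete recovery of
injected regions at 50 subjects per group *and* loss of majority-criterion
significance at 10 per group.  Larger d would never lose significance at
n = 10; smaller d would not recover 5 of 6 regions at n = 50.  Rician
magnitude noise is applied at a baseline SNR of 30.  Everything is a
deterministic function of the cohort seed; subjects are reconstructible
individually.

What the generator does *not* emulate: head geometry, registration and
projection errors, crossing fibers (single zeppelin per voxel),
spatially correlated noise, or atlas mislabeling.  Passing tests therefore
validate the estimators and the statistical machinery under the stated
model, not robustness to those real-data effects.

## ROI statistics, resampling, stability

Per subject, ROI and metric, the summary value is the mean of the voxels
in the ROI–skeleton intersection lying strictly inside the region's 2nd
and 98th percentile bounds (type-7 quantiles; values equal to a bound are
excluded; when nothing lies strictly inside — constant regions — the
closed interval is used, so a constant region returns its value).  Trim
bounds are per ROI by default; a whole-skeleton variant is a config
switch.  ROI id 0 denotes the full-skeleton pseudo-ROI.

Group comparisons are classical pooled-variance two-tailed t-tests
(`df = n₁+n₂−2`) with Cohen's d on the pooled SD, at α = 0.05 and — by
design — no multiple-comparison correction (an FDR switch exists but
defaults off): the goal is per-metric behavior, not a corrected clinical
claim.

The sample-size experiment draws, for each size `n` from the full group
size down to 10 in steps of 5, `B = 5001` subsamples of `n` distinct
subjects per group (without replacement: reduced-size subsamples of
distinct subjects are the only reading under which thousands of
*different* subsamples exist; a with-replacement mode is available), and
repeats the t-tests for the tests that were significant on the full
sample.  A test is flagged at a size when at least `ceiling(B/2)` (2,501
of 5,001) subsamples give p < 0.05.  Note one structural property: at
sizes close to the full N the subsamples share most subjects with the full
sample, so chance full-sample findings on a null cohort remain flagged
there; the flag rate only collapses to ~α once the overlap decays (by
n ≈ 15–10 for N = 50).  Stability per group, ROI, metric and size is the
coefficient of quartile variation `CQV = (Q₃−Q₁)/(Q₃+Q₁)·100`, summarized
over the B subsamples by the median and the 2.5/97.5-percentile interval
(per-subsample CQVs, not pooled values).  The subsample seed schedule is
derived per (size, iteration), so any single draw is reconstructible.

## Problem sizes used in the shipped tests

The validation suite exercises the full pipeline at deliberately small
volume scale — 12 regions of 2×2×2 voxels with 4-voxel skeletons, 50
subjects per group, `B = 501` subsamples, 500 replicate null cohorts for
the type-I calibration and 20 cohort seeds for the power-decay experiment
— sizes chosen so the whole suite runs in minutes on one core while
keeping every statistical property it asserts (rejection rates, majority
criteria, power monotonicity) at the stated group sizes.  The oracle
checks integrate q-space by 4,000-direction × 96-node Gauss–Legendre
quadrature.

## Limitations

* All metrics are apparent, shell-tied quantities; comparing them across
  acquisitions with different b-values is not meaningful.
* The anisotropy scaling exponent `ε = 0.4` and the L² anisotropy index
  are one concrete convention; other conventions differ by monotone maps.
* RTAP assumes axial symmetry about `e₁` only through the equator
  average; in crossing-fiber voxels `e₁` itself is ill-defined.
* The constant-MD family exists only on part of the fraction grid under
  physiological free-water diffusivity (above), which is a property of the
  two-compartment construction, not of the estimators.
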