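---
title: "Ellipsoidal-cavity field corrections for oscillator strengths: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipsoidal-cavity field corrections for oscillator strengths: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavos)
```

## The problem

A molecule dissolved in a transparent solvent absorbs light driven by the
*local* electromagnetic field at the molecule, not by the macroscopic field
`E` propagating in the dielectric. Quantum-chemistry programs compute
oscillator strengths (`f_comp`) for the isolated (or continuum-solvated)
molecule as if the driving field equalled the macroscopic one, while
experimental oscillator strengths (`f_exp`) are extracted from solution
spectra in which the energy flux carries an extra factor of the refractive
index `n`. A fair comparison therefore (i) uses `n * f_exp` as the
experimental reference and (ii) corrects `f_comp` for the ratio of the cavity
field to the macroscopic field.

`cavos` implements the simplest anisotropic version of (ii): the molecule
occupies an **ellipsoidal cavity** (dielectric constant `eps2`, default 1,
because the molecule itself is treated explicitly by the electronic-structure
method) embedded in a continuum dielectric `eps1 = n^2`, with `n` taken at
the sodium D line as the off-resonance optical value. Both defaults can be
overridden.

## Model chain

1. **Cavity geometry.** An ellipsoid is fitted to van der Waals / PCM surface
   points: a linear least-squares fit of the nine quadric coefficients with
   the constant term fixed to −1, followed by diagonalization of the
   quadratic form (`fit_quadric()`, `canonicalize()`, `fit_ellipsoid()`).
   The algebraic residual RMS is reported as the fit quality; geometric
   (orthogonal-distance) fitting and minimum-volume enclosing ellipsoids are
   deliberately out of scope. If the constant-fixed system is singular (a
   surface through the origin) the fit falls back to the unit-norm
   null-vector of the homogeneous system. Semiaxes are returned ascending,
   each paired with its axis direction (row of the rotation matrix); signs
   are fixed deterministically (dominant component positive, determinant +1).

2. **Depolarization factors.** For semiaxes `(a, b, c)` the factor along
   axis `k` is
   \[ A_k = \frac{abc}{2}\int_0^\infty
      \frac{ds}{(s+x_k^2)\sqrt{(s+a^2)(s+b^2)(s+c^2)}}, \]
   with \(\sum_k A_k = 1\) and \(A_k = 1/3\) for a sphere. The integral is
   evaluated with adaptive quadrature on the half line after normalizing the
   semiaxes to unit geometric mean (the factors are scale invariant, and the
   normalization keeps the integrand well conditioned at aspect ratios of
   100:1). Property tests check the sum rule, the sphere limit, the
   closed-form prolate-spheroid values, and monotonicity (longer axis,
   smaller factor).

3. **Cavity-field factors.** Along axis `k`,
   \( h_k = \epsilon_1 / (\epsilon_1 + (\epsilon_2 - \epsilon_1) A_k) \ge 1 \)
   whenever \(\epsilon_1 \ge \epsilon_2\); the sphere limit reproduces
   Onsager's \(3n^2/(2n^2+1)\).

4. **Orientation averaging.** Electronic-structure outputs report transition
   dipole moments (TDMs) along the lab axes, so per-lab-axis correction
   factors are formed by averaging the squared cavity-field component along
   each lab direction over all orientations of the macroscopic field,
   multiplied by 3 because computed oscillator strengths already include the
   isotropic 1/3. The average reduces analytically to
   \( \mathrm{Corr}_d^2 = \sum_k h_k^2 (\hat e_k\cdot\hat d)^2 \)
   (`correction_factors()`); the explicit two-angle Gauss quadrature is kept
   as an independent test oracle only (`correction_factors_quadrature()`,
   degree 21).

5. **Corrected strengths.** Each Cartesian TDM component is multiplied by
   `Corr_d` and the per-gauge oscillator strengths are recomputed
   (`corrected_os()`): length \( (2/3) E |\mu|^2 \), velocity
   \( (2/3)|p|^2/E \), mixed \( (2/3)\,\mu\cdot p \), in atomic units with
   the energy in hartree. The same factors are applied to length- and
   velocity-gauge vectors; a negative mixed-gauge value (inconsistent gauges)
   is passed through and flagged.

## Benchmark statistics

Experimental strengths come either tabulated per band or from digitized
spectra via
\( f_{exp} = 4.319\times10^{-9}\,\mathrm{mol\,L^{-1}\,cm^2}\int\varepsilon\,d\tilde\nu \)
(trapezoidal integration on the native grid; `f_exp_from_spectrum()`), with
the extinction-weighted mean wavenumber as the band energy
(`band_mean_energy()`). The comparison reference is always `n * f_exp`.

Computed transitions are grouped into bands in two modes:

* **EBL (exact band limits):** a transition joins band `k` when its energy
  lies inside the band's window; strengths add.
* **IF (improved fit):** each band's window may be rigidly shifted so that
  the contributing set minimizes `|f_comp - n f_exp|`. The candidate space —
  under-determined in the source description — is taken as all
  contiguous-in-energy runs of still-unassigned transitions whose span fits
  in a window of the original width, plus the empty set; bands are processed
  in ascending energy, ties broken by smallest shift, then fewest
  transitions. This is the most literal deterministic reading of "shifted
  limits"; each transition is assigned at most once.

`benchmark_stats()` reports the MAE over bands, an OLS regression of
`f_comp` on `n f_exp`, and three energy metrics computed over bands with a
nonempty assignment: mean absolute and mean signed error of the
strength-weighted computed band energy against the experimental mean band
energy, and the mean energy ratio.

The **scaling factor** `C` minimizes the MAE between `(C n f_exp_k, f_comp_k)`.
The exact minimizer for a fixed assignment is the weighted median of the
per-band ratios `f_comp/(n f_exp)` with weights `n f_exp`; because the IF
assignment itself depends on the scaled reference, `scaling_factor()`
alternates assignment and median update to a fixed point (`|dC| < 1e-6`,
max 100 iterations). Because the assignment is a step function of the scale,
the iteration can cycle between two assignments on noisy data; a revisited
value is resolved by returning the iterate with the smallest actual L1
objective. The result is therefore a local optimum of a piecewise-linear
objective — the global minimizer can sit at an assignment breakpoint that is
not a fixed point of the median update — which is the price of the simple,
deterministic iteration. The iteration is initialized from the EBL assignment's
weighted-median ratio rather than from 1: when a band contains several
transitions, subsets of them can spuriously match an unscaled reference and
trap a blind iteration at a wrong fixed point, whereas the EBL start is
consistent and, for noise-free data, already exact. Run on the corrected
strength set, the same algorithm yields `C^S`; with every `Corr^2 > 1` and
coinciding assignments, `C^S > C` necessarily.

## Synthetic data: what it emulates, and what it does not

`generate_ellipsoid_cloud()` draws quasi-uniform surface points (uniform
directions projected onto the surface) with optional radial Gaussian noise —
a stand-in for PCM tesserae. `generate_synthetic_benchmark()` builds
disjoint bands with Gaussian extinction spectra (width one sixth of the
window, peak extinction 5,000–30,000 M⁻¹cm⁻¹, typical of strong UV–vis
bands), derives `f_exp` and band energies from those spectra, and plants 1–3
transitions per band whose total length-gauge strength is
`s_true * n * f_exp * (1 + e)`, `e ~ N(0, sigma_f)`; momentum vectors are
set to `E * mu`, making all gauges coincide. Defaults (20 bands, 4000 cm⁻¹
windows, 1000 cm⁻¹ gaps, `n = 1.333`, `sigma_f = 0.1`) describe a clean,
well-separated spectrum. The generator does **not** emulate overlapping or
vibronically structured bands, baselines, gauge disagreement of approximate
wavefunctions, or correlated errors across transitions — so passing recovery
tests demonstrate correctness of the statistics pipeline, not robustness to
real spectral pathology. Noisy-recovery tests use the EBL mode, which is the
unbiased estimator under the generator's conditions; IF is by construction
biased toward agreement and is exercised against the noise-free planted
scaling and an exhaustive grid-search oracle instead. All generators are
seed-deterministic and restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Depolarization quadrature: `rel.tol = abs.tol = 1e-10` target, hard error
  if the estimated error exceeds 1e-7.
* Ellipsoid validity: all eigenvalues of the (sign-normalized) quadratic form
  strictly positive at relative tolerance 1e-10, and a positive centred
  constant; otherwise `NotAnEllipsoid`. Rank-deficient design matrices
  (e.g. coplanar points) raise `DegenerateConfiguration`.
* Unit conventions: coordinates in angstrom, energies in eV at every
  interface (1 eV = 0.0367493 hartree = 8065.544 cm⁻¹), TDMs in atomic
  units; units are encoded in column names, never inferred.
* Weighted median: lower median (first ratio at which the cumulative weight
  reaches half the total) — the exact L1 minimizer, deterministic under ties.
* Problem sizes in the shipped tests (500-point clouds, up to 50 bands,
  20 seeds, 1000 random semiaxis triples) were chosen to give comfortable
  statistical margins while keeping the suite quick to run.

## Known limitations

* The continuum ellipsoid is a rough model at molecular scale; residuals of
  the quadric fit should be inspected for strongly non-ellipsoidal molecules.
* The per-lab-axis correction is *frame dependent*: the orientation-averaged
  `Corr` factors apply to the lab components the electronic-structure output
  happens to use. When the cavity axes are colinear with the lab axes the
  procedure is exact (`Corr_d^2 = h_d^2`); for a molecule oriented obliquely
  to the lab frame the corrected strength differs from the frame-independent
  value `(2/3) E Σ_k h_k^2 (μ·ê_k)^2`. Raw strengths are rotation invariant;
  corrected ones are invariant only under axis relabelings. Orient molecules
  along their cavity axes where possible.
* Only a single off-resonance refractive index is used; no dispersion.
* The combined cavity + reaction field expression is intentionally not
  offered: calculations that already include a continuum reaction field
  (PCM) would double-count it.
* Band deconvolution, baseline correction and digitization of plotted
  spectra are out of scope; overlapping experimental bands must be resolved
  upstream in the band table.
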