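---
title: "Unmixing Raman hyperspectral images of immobilized enzymes with NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing Raman hyperspectral images of immobilized enzymes with NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmf)
```

## The problem

Carrier-bound enzyme immobilization binds an engineered enzyme (here a
pantothenate kinase, PanK) to microporous resin beads. Whether the
immobilization worked — which beads carry enzyme, where the wash buffer
(Bis-Tris) left residue, where the bare substrate shows through — is a
question about the joint spatial and chemical structure of the sample.
Raman hyperspectral imaging answers it label-free: a raster scan collects a
full vibrational spectrum at every pixel, giving a data matrix `A`
(pixels x wavenumbers). The difficulty is that the species of interest
share Raman bands (the enzyme and the resin both show C–H deformation near
1454 cm^-1 and amide I intensity near 1662 cm^-1), so no single band
isolates any one of them.

`ramanmf` unmixes such maps with non-negative matrix factorization (NMF)
and then — this is the methodological core — selects the number of
components by explicit, data-driven criteria instead of the conventional
reconstruction-error elbow.

## Model

NMF approximates `A ≈ W S` with `W` (pixels x k) and `S`
(k x wavenumbers) entry-wise non-negative: `W` holds per-pixel
concentrations, `S` holds component spectra. The factors minimize the
squared Frobenius norm `0.5 * ||A - W S||_F^2` by Lee–Seung multiplicative
updates, whose objective is non-increasing at every iteration. The fit
quality of a model is summarized by the relative reconstruction error

```
RRE = ||A - W S||_F / ||A||_F,
```

zero for a perfect fit. NMF is gauge-ambiguous (rescaling a column of `W`
against the matching row of `S` changes nothing); before any spectrum is
compared we fix `max(S[c, ]) = 1` per component.

A *ladder* of models with k = 1..K components (default K = 10) is fitted,
each independently from its own deterministic initialization. Every
resolved spectrum is compared against a reference spectral library by
cosine similarity on min–max-normalized vectors,

```
sim(a, b) = sum(a * b) / (||a|| * ||b||),  a, b >= 0  =>  sim in [0, 1],
```

yielding a similarity grid — for K = 10 and four references, 220 scores.

## Selection criteria

A component *resolves* a reference when that reference is the component's
best-scoring match, the score reaches `tau` (default 0.5), and the margin
over the component's second-best reference is at least `delta` (default
0). Within a model, references are claimed greedily by descending score so
the assignment is injective. The optimal model is then chosen by:

1. **Completeness** — candidate models must resolve *every* reference.
2. **Similarity** — candidates are ranked by `m(k)`, the worst assigned
   similarity in model k.
3. **Parsimony** — the smallest candidate within `epsilon` (default 0.05)
   of the best `m(k)` wins.

The threshold 0.5 reflects the empirical behaviour of cosine scores
against species that are absent: they stay below 0.5, so a single
threshold separates presence from absence. `epsilon = 0.05` encodes the
judgment that a few hundredths of cosine similarity do not justify extra
components; both are configurable. A third, deliberately manual criterion
is agreement between the resolved concentration maps and the optical
image: the package renders the panels side by side and never scores this —
no meaningful metric exists without registered optical ground truth.

The package ships a worked example: the bundled similarity grid of an
immobilized-PanK map on acrylamide resin under 785 nm excitation
(`example_similarity_table()`). On it the defaults select the
8-component model, with PanK assigned at similarity 0.77, and the first
resolution sequence resin (k = 1), glass (k = 2), Bis-Tris (k = 3). One
internal tension is documented rather than hidden: on that grid a
similarity-only rule first resolves PanK at k = 6 (a component scoring
0.73), while the accompanying narrative places first resolution at k = 7
with 0.71 — the difference is attributable to the manual optical
criterion, which this package does not automate. The selected optimal
model is unaffected.

## Preprocessing

Raw Raman maps carry fluorescence baselines far larger than the bands of
interest. The per-pixel chain is:

1. **Asymmetric least-squares baseline estimation** (Eilers–Boelens): the
   baseline `z` minimizes `sum(w_i (y_i - z_i)^2) + lambda * sum((Δ²z)^2)`
   with `w_i = p` above the baseline and `1 - p` below, re-estimated for
   10 rounds. Defaults `lambda = 1e5`, `p = 0.01` are the classic settings
   for Raman-scale baselines over a few hundred channels. The
   second-difference penalty vanishes on constants and straight lines, so
   those are reproduced exactly (a property the tests exploit).
2. **Savitzky–Golay smoothing**, window 11, polynomial order 3 — exact on
   polynomials up to the filter order.
3. **Clipping** of negative residuals to zero, which guarantees the
   non-negativity NMF requires.

Min–max normalization is *not* part of this chain: it belongs to
similarity scoring, where both spectra of a pair are normalized
immediately before the cosine. Normalizing before factorization would
destroy the linear mixing structure NMF exploits. Reference spectra pass
through the same baseline/smoothing chain by default (configurable), so
resolved and reference spectra are compared on an equal footing.

## Numerical choices

- **Initialization** is NNDSVD-a (non-negative double SVD, zeros replaced
  by the data mean) — deterministic, so ladders are exactly reproducible;
  seeded random initialization is available.
- **Convergence**: the objective decrease over a 10-iteration window,
  relative to the initial objective, must fall below `tol`. The default is
  `tol = 1e-7` with `max_iter = 5000`. This is deliberately tighter than
  the few-hundred-iteration defaults common in NMF libraries: on scenes
  with strongly overlapped species the component *spectra* converge early,
  but the concentration *maps* of the overlapped species keep improving
  for thousands of iterations; a loose tolerance leaves them visibly
  under-converged while looking fine spectrally.
- **Component order** is fixed by descending total concentration
  `colSums(W)`, so "component 1" is stable across runs and models.
- **Degenerate inputs** fail loudly: constant spectra cannot be min–max
  normalized (no shape to compare), zero matrices cannot be factorized,
  and `RRE` is undefined for `||A||_F = 0`.
- **Ties** in assignment are broken toward the lower component index;
  reference order never affects the outcome (a tested invariance).

## The synthetic scene generator

Raw hyperspectral maps of immobilized-enzyme systems are rarely
available alongside their similarity tables, so validation rests on a
ground-truthed generator (`default_scene()` /
`render_cube()`) that emulates its qualitative structure on a pixel grid
(default 32 x 32, ~600 channels from 600 to 1798 cm^-1):

- **Resin beads** as disks with a mild radial profile; the **glass
  substrate** is exactly the complement of the bead field (its broad band
  near 1400 cm^-1 matches 785 nm behaviour).
- **Enzyme** in ~70% of beads, as an egg-shell ring near the bead surface
  — the classic profile of diffusion-limited immobilization — spilling
  slightly past the rim, where partial-volume pixels carry enzyme coat
  without resin. Its preset spectrum has the 1003 cm^-1 phenylalanine
  marker plus the shared 1454/1662 cm^-1 bands.
- **Wash residue** (Bis-Tris-like bands in the 800–900, 1000–1100 and
  1400–1500 cm^-1 regions) as patches inside beads, strongest in beads
  with little enzyme — enzyme and wash loadings anti-correlate across
  beads — plus dried spots on the glass.
- A smooth cubic **baseline** with per-pixel jittered coefficients
  (amplitude 4 x the unit peak height, so raw spectra are
  baseline-dominated and unmixing succeeds only after preprocessing) and
  **noise** with a Gaussian floor (sd 0.05, roughly 20:1 peak
  signal-to-noise) plus a shot-like term scaling with the square root of
  the signal.

The forward model is exactly the bilinear mixing NMF assumes, which is
what makes parameter recovery a meaningful test: with the defaults the
full pipeline re-identifies all four species with cosine similarity and
abundance-map Pearson correlation above 0.9 in at least four of five
seeds (32 x 32 grid, k = 1..10).

Two caveats delimit what those tests show about real data. First, the
generator's species have NMF-identifiable supports — each species
dominates some pixels. Real immobilized-enzyme maps need not be so
obliging (an enzyme that never dominates any pixel is recoverable only up
to a resin admixture, which is precisely why the real system's enzyme
similarity plateaus near 0.8 rather than 1). Second, the generator omits
cosmic-ray spikes, detector etaloning, wavenumber miscalibration and
focus drift; the preprocessing module intentionally does not address
those (despiking and calibration are out of scope).

## Problem sizes and costs

Default scene conditions — 32 x 32 pixels, 600 channels, ladder to
k = 10 — run in roughly two minutes on one CPU core: the sparse-Cholesky
AsLS solve (the symbolic factorization is computed once and reused across
all pixels and reweighting rounds) takes ~25 s, the ladder the remainder.
Smaller grids (16 x 16, 24 x 24) are used throughout the unit tests to
keep the suite fast; they exercise identical code paths.

## Known limitations

- The multiplicative-update engine is plain Frobenius NMF; sparsity- or
  orthogonality-regularized variants and MCR-ALS are out of scope.
- Model selection assumes the reference library is complete. A species
  present in the sample but absent from the library is silently absorbed
  into other components or left as an unassigned component.
- The optical-agreement criterion is manual by design.
- Similarity tables are rounded to two decimals for display (an unrounded
  machine copy is always written alongside); selection on a re-read table
  therefore operates on rounded scores, exactly as when working from a
  published table.
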