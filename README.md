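# ramanmf

Unmixing of Raman hyperspectral images of immobilized enzymes by
non-negative matrix factorization (NMF), with data-driven selection of the
number of components.

## The problem

Immobilizing an enzyme on porous resin beads is a standard way to make a
biocatalyst stable and reusable. Judging whether the immobilization worked
requires knowing *where* each chemical species sits: the enzyme, the
carrier resin, residue of the final wash buffer (Bis-Tris), and the glass
slide underneath. Raman hyperspectral imaging measures a full vibrational
spectrum at every pixel of a map, but the species' Raman bands overlap
heavily (enzyme and resin share C–H deformation at 1454 cm⁻¹ and amide I
intensity at 1662 cm⁻¹), so no single band isolates any species.

`ramanmf` factorizes the preprocessed data matrix *A* (pixels ×
wavenumbers) as *A ≈ W·S* with non-negative concentrations *W* and
component spectra *S*, fitted by Lee–Seung multiplicative updates under
the Frobenius norm. Instead of picking the number of components *k* from
the elbow of the relative reconstruction error
RRE = ‖A − WS‖_F / ‖A‖_F — which on these systems flattens at 2–3
components and misses the enzyme entirely — the package fits a ladder of
independent models (k = 1…10), scores every resolved spectrum against a
reference library by cosine similarity on min–max-normalized vectors, and
selects the smallest model that (1) resolves **all** species above a
threshold (τ = 0.5), (2) maximizes the worst assigned similarity, within
(3) a parsimony tolerance (ε = 0.05). The selected model's concentration
columns are reshaped into per-species chemical images.

The package also contains the full preprocessing chain for Raman maps
(asymmetric least-squares baseline removal, Savitzky–Golay smoothing,
non-negativity clipping), a ground-truthed synthetic scene generator for
validation, long-format map/reference text I/O, and a small CLI
(`inst/scripts/ramanmf.R`) with `simulate`, `select` and `run`
subcommands.

## Worked example

The package bundles the similarity grid of a real measurement — an
immobilized pantothenate kinase (PanK) on acrylamide resin, mapped under
785 nm excitation, ten NMF models scored against four references:

```r
library(ramanmf)
grid <- read_similarity_table(example_similarity_table())
grid
#> <similarity_grid> models k = 1..10; 4 references (glass, resin, PanK, Bis-Tris); 220 scores
report <- select_optimal(grid)
report
#> <selection_report> optimal model: k* = 8
#>   glass        component 2, similarity 0.97
#>   resin        component 1, similarity 0.98
#>   PanK         component 7, similarity 0.77
#>   Bis-Tris     component 3, similarity 0.84
#>   first resolved at k: glass=2, resin=1, PanK=6, Bis-Tris=3
```

Reading: the resin is already resolved by a 1-component model (similarity
0.99) and the glass by 2, but the enzyme only appears once the ladder
reaches 6–7 components — more components than chemical species, because
extra components absorb baseline residue and minor structure. The
8-component model is optimal: it resolves all four species, its worst
assigned similarity (PanK, 0.77) is within ε of the best achievable, and
no smaller model matches that.

A fully synthetic end-to-end run:

```r
truth <- default_scene(32, 32, seed = 1)    # 4-species bead scene + truth
cube  <- render_cube(truth)                  # forward model: W·S + baseline + noise
pre   <- preprocess_cube(cube)               # AsLS -> Savitzky-Golay -> clip
ladder <- fit_ladder(pre, k_max = 10, seed = 1)
lib   <- reference_library(lapply(truth$pure, preprocess_spectrum),
                           axis = cube$axis)
report <- select_optimal(score_ladder(ladder, lib), attr(ladder, "rre"))
```

On this scene the selected model assigns all four species with cosine
similarities 0.94–0.99 and abundance maps correlating with the generator's
ground truth at Pearson r ≥ 0.9.

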