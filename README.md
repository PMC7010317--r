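# blebmorph

Automated single-cell quantification of membrane blebbing and focal
adhesions from three-channel fluorescence micrographs.

## The problem

High-content imaging experiments on adherent fibroblasts stain three
compartments per field of view: the whole cell (e.g. HCS CellMask), DNA
(DAPI), and a focal-adhesion marker (vinculin or FAK immunofluorescence).
Two phenotypes must then be read out over thousands of cells without
manual scoring:

1. **Membrane blebbing** — metabolically stressed cells retract and grow
   bead-like bulging membrane protrusions. A cell is called *blebbing*
   when all three standardized criteria hold:

   * mean boundary curvature `κ̄ > 0.029 px⁻¹`, where the curvature at
     boundary point `Pᵢ` is `κᵢ = 1/rᵢ`, the inverse circumradius of the
     circle through `Pᵢ` and its two neighbours (`r = abc/4A`), computed
     on a Savitzky–Golay-smoothed sub-pixel contour;
   * nuclear/cytoplasmic adhesion-marker intensity ratio `< 1.15`
     (blebbing cells show relatively high cytoplasmic vinculin signal);
   * cell/nucleus area ratio `< 4.5` (blebbing cells are poorly spread).

   Cells with a DNA-positive area `< 1000 px` or a cell area
   `> 150 000 px` are excluded as segmentation outliers.

2. **Focal-adhesion (FA) counts** — puncta are segmented with a phase
   stretch transform (PST), and filtered: outside cells or inside nuclei,
   smaller than 30 px, or dimmer than the parent cell's mean intensity.
   Per-cell counts receive a dataset-wide 99th-percentile upper cutoff
   and a lower cutoff removing cells with ≤ 4 adhesions.

Cell bodies are segmented from the cytoplasm channel by thresholding at
twice the mean of the dimmest 20% of pixels; regions containing several
nuclei are re-thresholded and split by nuclei-seeded region growing.
Nuclei and FAs are segmented with the PST, a frequency-domain operator
that applies the warped phase kernel
`φ(r) ∝ W·r·atan(W·r) − ln(1+(W·r)²)/2` and thresholds the output phase.

Group statistics: pairwise two-sided Fisher's exact tests
(point-probability convention) with Benjamini–Hochberg FDR adjustment for
blebbing frequencies; two-way ANOVA with Tukey HSD on log₁₀ FA counts,
plus a rank-based alternative (pairwise Mann–Whitney + BH).

Because suitable public micrographs do not exist, the package ships a
seeded synthetic-scene generator with complete ground truth (cell,
nucleus and FA masks, blebbing labels), used by the whole test suite.

## Worked example

```r
library(blebmorph)

scene <- generate_scene(scene_params(n_cells = 6, seed = 42))
scene
#> Synthetic scene: 768x768 px, 6 cells (3 blebbing), 54 focal adhesions

q <- quantify_scene(scene)
round(as.data.frame(q$features), 3)
#>   cell_id nucleus_id cell_area nucleus_area mean_curvature intensity_ratio
#> 1       1          1      9477         2672          0.086           0.753
#> 2       2          2      8007         2428          0.059           0.702
#> 3       3          3      9967         2977          0.058           0.729
#> 4       4          4      9690         3146          0.018           1.426
#> 5       5          5      9214         3010          0.018           1.271
#> 6       6          6     11318         3648          0.017           1.332
#>   area_ratio blebbing fa_count
#> 1      3.547        1        8
#> 2      3.298        1       10
#> 3      3.348        1       10
#> 4      3.080        0        6
#> 5      3.061        0       10
#> 6      3.103        0       10

m <- match_cells_to_truth(q, scene$truth)
all(q$features$blebbing == scene$truth$blebbing[m])
#> [1] TRUE
```

The three blebbing cells sit far above the 0.029 px⁻¹ curvature cutoff
(0.058–0.086) with cytoplasm-dominant marker signal (ratio ≈ 0.7), the
three smooth cells far below it (≈ 0.018, ratio ≈ 1.3–1.4); all six
match the generator's ground truth. `fa_count` is the per-cell number of
surviving focal adhesions.

Group-level statistics are one call each: `blebbing_table()` +
`fisher_pairwise_fdr()` for phenotype frequencies, `fa_group_test()` for
the 2×2-factor FA-count comparison, `write_report()` for the CSV/JSON
bundle. A thin command-line front end with `simulate`, `quantify` and
`stats` subcommands lives in `inst/cli/blebmorph.R`.

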