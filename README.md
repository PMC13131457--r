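# evquant

Quantification of extracellular-vesicle (EV) uptake and EV–organelle
apposition in multi-channel fluorescence micrographs.

## The problem

Fluorescently tagged EVs appear as diffraction-limited puncta. Two questions
recur when studying their uptake by target cells:

1. **How many EVs does each cell internalize?** Somata are segmented from a
   marker channel, EV puncta are detected by intensity thresholding with
   size/shape filtering, and each punctum is assigned to the soma containing
   its centroid. Results are reported as particles per cell and particle
   density (particles/µm² soma area), with Pearson correlations of count and
   density against soma area (p from `t = r·√((n−2)/(1−r²))` on n−2 df).

2. **Are internalized EVs targeted to a specific organelle?** EV puncta and
   the mitochondrial network are segmented, and for every punctum the
   pixel-grid **edge-to-edge distance** to the organelle mask is computed
   from the exact Euclidean distance transform: a punctum overlapping or
   8-adjacent to the mask is *in contact* (0 nm); otherwise
   `d_edge = (d_px − 1) · pixel size`, the boundary gap between pixel
   squares. Apposition is summarized as cumulative fractions at contact,
   ≤100, ≤200, ≤500 and ≤1000 nm. Non-random proximity is tested with a
   **Monte Carlo randomization null**: each punctum's segmented pixel shape
   is rigidly re-placed uniformly inside the cellular region of interest
   (organelle geometry fixed), and the one-sided empirical p-value uses the
   add-one convention `p = (1 + #extreme) / (1 + N_iter)` (1,000 iterations
   per image; 10,000 for pooled binned enrichment). Conditions are compared
   by Mann–Whitney U (distances) and Fisher's exact test (contact counts),
   and distance distributions are characterized by **Sarle's bimodality
   coefficient** `BC = (g₁² + 1)/(g₂ + 3(n−1)²/((n−2)(n−3)))` (threshold
   0.555, the uniform benchmark 5/9) and by 1- vs 2-component Gaussian
   mixture selection with `ΔBIC = BIC₂ − BIC₁` (negative favours two
   components).

Because microscopy data of this kind are rarely redistributable, the package
includes a **ground-truthed synthetic micrograph generator** (filamentous
mitochondrial networks from dilated self-avoiding random walks, puncta
placed at exactly planned edge distances, elliptical somata with
zero-inflated punctum counts, Poisson shot noise and Gaussian read noise) so
every stage of the analysis is testable against known truth.

## Worked example

```r
library(evquant)

# simulate a field whose puncta sit at exact background gaps of 1..5 pixels
# from a mitochondrial structure, at 31 nm per pixel
f <- generate_apposition_field(apposition_field_spec(
  n_puncta = 5, punctum_radius_px = 0, pixel_size_nm = 31,
  distance_plan = gap_plan(1:5), seed = 104))
parts <- extract_particles(f$puncta_labels, get_channel(f$image, "ev"))
rec <- edge_to_edge_distances(parts, f$mito_mask)
sort(rec$edge_distance_nm)
#> [1]  31  62  93 124 155
mean(rec$edge_distance_nm)
#> [1] 93
```

The five puncta sit one to five background pixels from the organelle, so the
edge distances are exact multiples of the 31 nm pixel: their mean, 93 nm, is
the kind of tight apposition a neuronal EV-targeting phenotype produces.

The analysis workflow lives under `analysis/` (thin, numbered drivers over
the package functions; tables land in `results/`):

```sh
Rscript analysis/01_simulate_fields.R       # example images + truth tables
Rscript analysis/02_soma_quantification.R   # 500-soma uptake cohort
Rscript analysis/03_apposition_analysis.R   # two-condition apposition + Monte Carlo
Rscript analysis/04_distribution_shape.R    # bimodality + mixture selection
```

Step 2, for instance, recovers the simulated cohort's parameters through the
full detection pipeline (output from a run of this repository):

```
cohort: 500 somata over 50 images
true mean count  4.144 | recovered 4.144 +/- 0.154 (SEM)
true positive %  66.6 | recovered 66.6
```

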