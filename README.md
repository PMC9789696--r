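# jawspace

Quantitative placement of an isolated fossil lower jaw in a chondrichthyan
jaw morphospace, with phylogenetic-signal tests under tree uncertainty.

## The problem

Cartilaginous fish are mostly known from teeth and scales; a lower-jaw
cartilage found with no associated teeth or skeleton cannot be identified by
conventional characters. Its two-dimensional outline, however, can be
compared quantitatively against jaws of known affinity. `jawspace`
implements that comparison as a reusable pipeline:

1. **Elliptic Fourier analysis (EFA)** — each closed outline is expanded in
   per-harmonic coefficient quadruples (a_n, b_n, c_n, d_n) of x and y as
   functions of arc length, normalized by the first-harmonic ellipse so
   size, rotation, and starting point drop out. 25 harmonics (the default)
   retain ≥ 99% of cumulative harmonic power on jaw-like shapes.
2. **PCA morphospace** — covariance PCA of the coefficient matrix; the
   space is invertible, so any coordinate maps back to a jaw outline (the
   background shape grids on morphospace plots). Phenetic distances are
   Euclidean over all PCs.
3. **Placement** — hierarchical clustering plus a k-nearest-neighbour clade
   vote locate the unknown among the comparators.
4. **Phylogenetic signal under uncertainty** — Blomberg's K (permutation
   p), Pagel's λ (maximum likelihood, likelihood-ratio p), and a Mantel
   test of phenetic vs patristic distances, repeated over an ensemble of
   time trees built by random polytomy resolution, stratigraphic tip-age
   randomization, and basic node calibration; everything reported as
   mean ± SD over trees. Strong K and λ with a weak Mantel correlation is
   the signature of convergence (homoplasy) in jaw shape.

A synthetic-data module generates the full study design — 41 comparator
jaws in three groups evolved by Brownian motion on a time tree, one unknown
specimen, a degraded input topology with stratigraphic ranges, and optional
cross-clade convergence — so the entire pipeline is testable without any
fossil data.

## Worked example

```r
library(jawspace)

ds  <- simulate_jaw_dataset(scenario_config(seed = 1))
rep <- run_pipeline(ds$outlines, ds$labels, ds$topology, ds$ranges,
                    run_config(n_trees = 100, n_perm = 200, master_seed = 1))
print(rep)
```

```
Morphospace: PC 1 (88% of variance), PC 2 (11% of variance), PC 3 (0% of variance)
The specimen 'unknown' plots at 0.304/-0.048 (PC1/PC2)
<placement_report> unknown
  closest: t11 (0.09685, clade1), t8 (0.1069, clade1), t15 (0.1184, clade1)
  clade vote (k=5): clade1
  dendrogram sister: t32, t10, t15, t11, t8
Phylogenetic signal over 100 trees (mean ± SD):
  K (equal to 2.255 ± 0.382; p-value = 0.005 ± 0)
  lambda (equal to 0.996 ± 0.013; p-value = 0 ± 0)
  Mantel (R statistic = 0.543 ± 0.05; p-value = 0.005 ± 0)
```

Reading it: PC 1 (a thickness-like axis) carries 88% of shape variance; the
unknown lands at (0.30, −0.05), its five nearest comparators are all from
`clade1` — the clade it was actually generated from — and the dendrogram
agrees. Across 100 replicate trees the shape data show strong phylogenetic
signal (K well above 1, λ ≈ 1, both significant), and here — with no
convergence scenario switched on — phenetic and phylogenetic distances also
correlate (Mantel R ≈ 0.54). `render_figures(rep, "figs")` writes the
morphospace (with reconstructed-shape background grid), the dendrogram, and
the ensemble histograms; `write_report(rep, "out")` writes all tables as
TSV/JSON.

Real data enter through the same call: a TPS outline file, a label TSV
(`taxon_id, clade, mirror, role`), a Newick topology, and a stratigraphic
range TSV (`taxon_id, age_max_ma, age_min_ma`). A thin command-line wrapper
lives at `inst/scripts/jawspace-run.R`.

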