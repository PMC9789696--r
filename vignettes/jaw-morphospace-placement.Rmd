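---
title: "Placing an isolated fossil jaw in outline morphospace: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing an isolated fossil jaw in outline morphospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawspace)
```

## The problem

Chondrichthyan (shark, ratfish, and stem-group) fossils are mostly teeth,
scales, and spines; cartilaginous jaws fossilize rarely and often turn up
isolated, with no associated dentition to anchor an identification. When the
only usable character is the two-dimensional outline of a lower jaw
(Meckel's cartilage), a quantitative placement works in four stages:

1. decompose each closed jaw outline into elliptic Fourier coefficients;
2. build a PCA **morphospace** from the coefficient matrix of a comparator
   sample with known affinities, and locate the unknown in it;
3. read off the unknown's neighbours by hierarchical clustering and a
   k-nearest-neighbour clade vote on phenetic (Euclidean, all-PC) distances;
4. ask whether jaw shape carries phylogenetic information at all — and how
   much convergence blurs it — with Blomberg's K, Pagel's λ, and a Mantel
   test of phenetic against patristic distances, integrated over an ensemble
   of time-calibrated trees that propagates phylogenetic and stratigraphic
   uncertainty.

`jawspace` implements all four stages plus a synthetic-data generator that
reproduces the statistical structure this design assumes, so every stage is
testable end to end without any fossil data.

## Elliptic Fourier decomposition

A closed outline is an ordered polygon without a repeated closing point. The
coordinates, viewed as periodic functions of arc length, are expanded in a
Fourier series; harmonic $n$ contributes the quadruple
$(a_n, b_n, c_n, d_n)$. The discrete formulas are exact for the
piecewise-linear curve through the points, so unevenly spaced input is
handled correctly; outlines are nevertheless resampled to equal arc-length
spacing (default $k = 300$ points) so every specimen is represented at the
same resolution. 300 points resolve the default 25 harmonics with a wide
Nyquist margin (the hard limit is $2N + 1$ points).

**Normalization.** Size, rotation, and starting point are removed with the
standard first-ellipse convention: the starting point is moved to the
semi-major axis of the first-harmonic ellipse, the shape is rotated so that
axis lies along $x$, and all coefficients are divided by the semi-major
length. Afterwards $a_1 = 1$, $b_1 = c_1 = 0$, and $d_1$ is the signed
first-ellipse aspect ratio — for a jaw, essentially its relative thickness.
Two conventions are worth stating explicitly:

* the residual half-turn ambiguity of the starting point is resolved by
  comparing the two candidate coefficient vectors lexicographically, a
  deterministic rule that is itself invariant to the input's starting point;
* mirroring (left vs right jaws drawn from heterogeneous sources) is *not*
  auto-corrected from coefficient signs; it is declared per specimen in the
  label table, because silent auto-mirroring would erase genuine asymmetry.

**Harmonic selection.** Harmonic power $P_n = (a_n^2+b_n^2+c_n^2+d_n^2)/2$
measures retained shape information; `choose_harmonics()` returns the
smallest $n$ whose cumulative share reaches a threshold (default 0.99). The
package defaults to 25 harmonics, and the pipeline reports the cumulative
power actually retained at that order by decomposing at a higher check
order — reporting the share at the working order itself would be trivially 1.

## Morphospace

PCA is computed by singular value decomposition of the centred coefficient
matrix. Defaults and their reasons:

* **covariance PCA** (no column scaling): after normalization all
  coefficients live on one scale, and correlation-scaling would inflate the
  noise-dominated high harmonics. Correlation PCA remains available
  (`pca_scale = TRUE`), since whether the original toolchain standardized
  its preordination data is not determinable.
* **the unknown enters the ordination** by default, matching the joint
  design; `include_unknown = FALSE` gives the statistically cleaner
  passive projection instead, and the placement is reported for both in the
  test suite.
* axis signs are fixed (largest-magnitude loading positive) so repeated
  runs are identical; zero-variance columns ($b_1$, $c_1$) are tolerated.

Phenetic distances are Euclidean over **all** PCs, which is exactly the
Euclidean distance between centred coefficient vectors. Hierarchical
clustering accepts any PC subset because descriptions of such analyses
sometimes say "the first principal components" and sometimes "all PCs";
the default is all PCs and the choice is never silently reconciled —
`hca_pcs` makes it explicit. Default linkage is complete (the common
default of the underlying clustering tools); single, average, and Ward are
exposed. Distance ties break lexicographically and are flagged.

Because the PCA is invertible, any morphospace coordinate maps back to an
outline (`reconstruct_shape()`); the background shape grids on morphospace
plots are drawn this way.

## Phylogenetic signal and convergence

With $C$ the Brownian covariance of a dated tree ($C_{ij}$ = shared
root-to-ancestor path length):

* **Blomberg's K** compares the observed ratio of ordinary to
  phylogenetically corrected mean squared error with its Brownian
  expectation; $K \approx 1$ under Brownian motion, $< 1$ with less signal.
  Its p-value comes from tip permutation (one-tailed, 1000 permutations by
  default, with the $+1$ correction so $p > 0$ always).
* **Pagel's λ** multiplies the off-diagonals of $C$; the profile
  log-likelihood is maximized over $[0, 1]$ — a range where $C(\lambda)$ is
  a convex combination of $C$ and its diagonal and hence always valid — and
  the default p-value is a likelihood-ratio test against $\lambda = 0$ on
  $\chi^2_1$. A tip-permutation p-value for λ is also available
  (`lambda_permutation_p()`) for a literal match to permutation-based
  reporting; both conventions are deliberate, not interchangeable.
* **Mantel test**: Pearson correlation (Spearman optional) between the
  upper triangles of the phenetic and patristic distance matrices, with
  simultaneous row/column permutation of the second matrix, two-tailed by
  default. For $n \le 7$ an exact mode enumerates all $n!$ permutations.
  Low or negative correlation despite significant K and λ indicates
  homoplasy: convergent shapes in distant clades.

The univariate trait for K and λ defaults to PC1 scores — the original
description does not say which morphospace variable was tested, so the
choice is a required, visible configuration (`signal_trait`), with any PC
available.

## The tree-uncertainty ensemble

Input is a possibly non-binary topology plus a stratigraphic range per tip.
Each of `n_trees` (default 1000) replicates:

1. **resolves polytomies uniformly at random** over all rooted binary
   refinements, by sequential attachment (each child joins at one of the
   $2k-1$ positions of the local subtree), a distribution chosen as the
   least-informative reading of "randomly resolved";
2. **draws tip ages** independently and uniformly within each taxon's
   stratigraphic interval;
3. **calibrates** node ages by the basic cascade — each node `min_branch`
   (default 1 Myr) older than its oldest child — which guarantees positive
   branch lengths and a non-singular $C$; `min_branch = 0` is allowed but
   zero-length branches are flagged.

All six statistics (K, its p, λ, its p, Mantel r and p) are summarized as
mean ± SD over replicates. Seeding is deliberately asymmetric: replicate
seeds drive only tree building, while the permutation stream is derived
once from the master seed and reused across replicates. This makes the
degenerate case exact — a binary tree with point ages yields SD = 0 for
*every* statistic, including permutation p-values — and keeps the whole
ensemble bit-reproducible from one master seed.

## What the synthetic generator emulates

`simulate_jaw_dataset()` produces the study design the pipeline assumes:
41 comparator jaws in three groups plus one unknown. Defaults, fixed once:

| knob | default | reason |
|---|---|---|
| tree | birth–death, 41 tips, root age 60 Myr | a Devonian-scale clade age |
| clades | 2 monophyletic subtrees + 1 paraphyletic grade | comparative samples of crown clades plus a stem grade |
| `bm_rate` | 1e-4 per Myr | tip-level SD ≈ 0.08 on unit-scale coefficients: visible, valid shapes |
| shape variance | harmonics 1–6, SD ∝ $n^{-2}$ | real outlines' power decays; makes 25 harmonics retain ≥ 99% power by construction |
| `lambda_true` | 1 | Brownian motion unless a scenario says otherwise |
| `clade_effect_size` | 0.25 | a clear-separation regime: clade membership is recoverable from shape by design, while groups still overlap visibly in morphospace |
| `noise_sd` | 0.005 | digitization jitter well below shape signal |
| `polytomy_fraction` | 0.5 | half the nodes unresolved, a realistically poor fossil topology |
| `range_width_myr` | 10 | age-rank stratigraphic intervals |

Clade offsets act on a thickness-like combination ($d_1$) and curvature-like
harmonic-2/3 combinations, so the synthetic PC1 and PC2 have the same
qualitative reading as in real jaw data (thickness, curvature). Convergence
scenarios overwrite one member of each cross-clade pair with the other's
shape plus small noise. The unknown is an extra draw from a designated
clade's distribution; a difficulty knob scales its offset toward the grand
mean.

**What it does not emulate.** No taphonomic deformation beyond additive
coordinate noise, no allometry, no digitizer-specific artifacts, and no
biomechanics. One genuine non-linearity deserves note: generating an
outline from deviated coefficients implicitly re-parametrizes the curve by
arc length, so at large clade offsets the realized coefficients are a
smooth, deterministic — but not identity — transform of the requested ones
(the thickness coefficient is essentially unaffected; harmonic-2+
coefficients mix). Group structure, phylogenetic signal, and convergence
survive this map, which is why placement and signal-recovery tests pass;
exact coefficient-level recovery is only guaranteed for moderate
deviations, and the test suite checks it there.

Passing tests therefore show that the pipeline recovers structure *of the
kind the generator creates* — clade-structured Brownian shape variation
with known uncertainty — not that any particular fossil identification is
correct.

## Numerical conventions

* resampling: linear interpolation along the polygon, starting point
  preserved; degenerate (zero-perimeter) outlines are errors;
* orientation: shoelace sign, everything re-oriented counter-clockwise;
  collinear/self-crossing outlines with zero signed area are errors;
* all-zero decompositions reconstruct to a flagged degenerate point;
* PCA: deterministic SVD, no randomized solvers;
* λ optimization: golden-section/parabolic search (`optimize`) at
  tolerance 1e-8, with both interval endpoints checked so boundary maxima
  are never missed;
* every permutation or simulation accepts a seed, and identical seeds give
  bit-identical results;
* ensemble replicates that fail (e.g. a singular covariance under
  `min_branch = 0`) are recorded, resampled from a reserved seed pool, and
  counted in the report.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full design at reduced
ensemble sizes — typically `n_trees = 100` and `n_perm = 200`, with 25–100
generator seeds for accuracy estimates — which keeps the whole battery in
the minutes range while leaving every code path identical to a full
1000 × 1000 run; those are simply loop counts.

## Limitations

* Two-dimensional outlines only: no landmarks, no 3D, no internal anatomy.
* The λ search stops at 1 by default; values above 1 (possible on some
  non-ultrametric trees) require raising `lambda_max` explicitly.
* The basic calibration is intentionally simple; rate-based or Bayesian
  tip-dating is out of scope.
* Topology inference is out of scope — the tree is always an input.
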