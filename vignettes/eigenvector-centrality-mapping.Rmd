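---
title: "Eigenvector centrality mapping of resting-state fMRI: methods and design"
author: "ecmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector centrality mapping of resting-state fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmap)
```

## The problem

Deep brain stimulation of the subthalamic nucleus (STN DBS) and oral
levodopa produce comparable motor improvement in advanced Parkinson's
disease, but through different physiological routes. One way to compare
them in vivo is to ask how each treatment reorganizes resting-state
functional connectivity: acquire BOLD fMRI in the same patients before
electrode implantation (with and without levodopa) and shortly after
(with and without unilateral stimulation), and look for voxels whose
*interconnectedness* changes between treatment states.

Eigenvector centrality (EC) is the tool this package is built around. It is
data driven and parameter free: no seed choice, no threshold on the
connectivity graph. A voxel receives high EC when it is strongly correlated
with other voxels that are themselves strongly correlated with well
connected voxels — the same fixed-point idea as PageRank. EC localizes
*where* hubness changes; it does not say which connections drive the
change, which is why a seed-based correlation follow-up from the
significant EC clusters is part of the chain.

## The model

### Similarity matrix and its non-negative variants

Let `X` be the `V × T` matrix of in-mask voxel time courses after
standardization (each row demeaned and scaled to unit L2 norm). Then
`C = X Xᵀ` is the full Pearson correlation matrix. EC requires a
non-negative matrix; three variants are supported:

| variant | map | interpretation |
|---|---|---|
| `add` | `r ↦ r + 1` | shifts all correlations positive; anticorrelation = weakest link |
| `abs` | `r ↦ |r|` | anticorrelation counts as connectivity |
| `pos` | `r ↦ max(r, 0)` | anticorrelation ignored |

The diagonal is the transformed self-correlation `f(1)`. For `add` this
adds the rank-one matrix `11ᵀ` plus identity-like terms: the eigenvector is
unchanged by the constant diagonal shift; for `abs`/`pos` the unit diagonal
adds the identity, which shifts all eigenvalues equally and again leaves
eigenvectors untouched. The choice is therefore cosmetic for the result but
fixed here so that runs are reproducible bit for bit.

For a strictly positive matrix (`add` always; `abs`/`pos` generically) the
Perron–Frobenius theorem guarantees a unique dominant eigenvalue with a
strictly positive eigenvector — EC is well defined. Under `pos` the matrix
can be *reducible* (a voxel non-positively correlated with everything, or
two mutually orthogonal blocks); the dominant eigenspace may then be
degenerate. `ecMap()` detects this by estimating the second eigenvalue on
the deflated operator and reports `uniquePerron = FALSE` with a warning
rather than silently picking one eigenvector.

### Computation

`ecMap()` uses power iteration from a uniform positive start vector,
normalizing every iterate, stopping when successive iterates differ by less
than `tol = 1e-9` in the sup norm (cap `maxIter = 10000`; non-convergence
is flagged, not hidden). Two evaluation paths:

* **`add`, matrix-free:** `f(C) v = X (Xᵀ v) + (Σ v) 1`, cost `O(VT)` per
  iteration and memory `O(VT)` — the `V × V` matrix never exists. Because
  `add` adds the rank-one all-ones matrix, the spectral gap is large and
  convergence takes only a handful of iterations.
* **`abs`/`pos`, chunked:** blocks of `chunkRows` similarity rows are
  formed as `X_I Xᵀ`, transformed, multiplied into `v`, and discarded, so
  peak memory holds at most `chunkRows` rows.

`ecMapDense()` builds `f(C)` explicitly and calls a dense symmetric
eigendecomposition. It is guarded to `V ≤ 2000` and exists as the
independent oracle: the test suite drives both paths over random instances
(`V ≤ 500`, `T ≤ 64`) and requires agreement to `1e-8`.

EC maps are scaled to unit L2 norm. The scaling convention matters because
the downstream GLM is scale sensitive; what is essential is not which
convention is chosen but that the identical convention is applied to every
run, which the implementation guarantees structurally (the eigenvector is
normalized inside `ecMap()` itself).

Voxel order is the column-major (x fastest) order of the mask grid,
applied identically to every run, so that row *i* of every map is the same
voxel.

### Group model

Per-run maps enter a flexible-factorial GLM: for `S` subjects and `K`
conditions the design has one row per map and `K + S` indicator columns
(conditions first). The design is deliberately over-parameterized with rank
`K + S − 1`; coefficients are obtained by Moore–Penrose pseudoinverse, and a
contrast is estimable exactly when its weights are zero on subject columns
and sum to zero over condition columns — which is also how the estimability
check is implemented. For the reference layout (13 subjects, 5 conditions)
the error degrees of freedom are `65 − 17 = 48`.

Voxelwise: `t = cᵀβ̂ / sqrt(σ̂² · cᵀ(XᵀX)⁺c)` with `σ̂² = RSS/df`; one-sided
p from the t distribution (each directed difference and its reverse are
separate contrasts in the battery); `z = Φ⁻¹(1 − p)` computed in log space
so large t convert without saturating; Benjamini–Hochberg FDR across the
in-mask voxels, per contrast. Variance is estimated per voxel with no
pooling and no nonsphericity/REML correction — a deliberate simplification
relative to SPM's machinery, recorded here as a known divergence.

The contrast battery (`contrastBattery()`) contains eleven sum-to-zero
vectors: the two unilateral ON-state differences against levodopa
(`POST_ON_left − PRE_ON`, `POST_ON_right − PRE_ON`), the OFF–OFF
(microlesion) difference, the two unilateral difference-of-difference
interactions, the weighted bilateral contrast
`POST_ON_left + POST_ON_right − 2·PRE_ON` and its interaction
`(POST_ON − PRE_ON) − 2·(POST_OFF − PRE_OFF)`, and four reverse-direction
contrasts testing decreases (`PRE_ON − POST_ON_left/right/weighted`,
`PRE_OFF − POST_OFF`). The interaction is the scientifically load-bearing
one: a PRE→POST change common to OFF and ON states (microlesion, session
effects) cancels exactly, which the suite verifies as an algebraic
identity.

Cluster tables use 18-connected components (faces + edges; configurable to
6 or 26), report cluster size `k`, the peak (maximum t) in mm via the
affine, and up to 3 local maxima greedily selected in descending t subject
to pairwise separation > 8 mm.

### Seed-based follow-up

Seeds are the connected components of strictly sub-threshold FDR q values
(`q < 0.05`) in a chosen EC contrast; each run then yields a seed-to-voxel
Pearson correlation map from the unweighted mean seed time course. Maps are
Fisher z-transformed by default (`atanh` with r clipped to `±(1 − 1e−7)`)
— the transform is monotone, so voxel rankings are unchanged, and it
stabilizes variance before the GLM; the untransformed path remains
available via `fisher = FALSE`. Seed voxels keep their trivial
self-correlations in the maps but are excluded from cluster reporting to
avoid circular peaks.

### Masking, smoothing, motion

The artifact mask mirrors the post-surgery masking problem: electrodes
cause susceptibility dropout, so a voxel survives only if its temporal-mean
intensity reaches 40 % of a robust maximum. "40 % of what" is
under-specified in common usage; here the reference is the 99th percentile
of the temporal-mean image, so single hot voxels cannot inflate it, and
both the fraction and the quantile are arguments. Per-run masks are
combined across subjects with logical AND and intersected with an
anatomical search space when one is supplied.

`gaussianSmooth()` implements separable Gaussian smoothing specified by
FWHM in mm (`σ = FWHM / (2√(2 ln 2))`), kernel width per axis taken from
the affine, truncation at 5σ, mirror boundary handling (which preserves
the spatial sum). The reference pipeline does **not** smooth the synthetic
study: on a 16×16×8 grid an 8 mm kernel spreads the planted effect well
outside the ground-truth voxel set, turning recovery metrics into blur
measurements. Smoothing is validated separately against a dense
convolution oracle and the Gaussian semigroup property.

Framewise displacement is
`FD_t = Σ|Δ translations| + 50 mm · Σ|Δ rotations|` (rotations in radians;
a degrees flag converts), giving `T − 1` values per run, summarized by mean
FD, maximum FD, maximum after discarding the largest 5 % (ceiling of
`0.05·n` values; ties keep earlier frames), and the count of FD > 2 mm. QC
only — no frames are censored.

### Clinical statistics

The 2×2 within-subject ANOVA (treatment method × treatment state) exploits
the two-level structure: each F with df (1, n−1) equals the squared paired
t on the corresponding subject-level composite, which makes the
implementation transparent and exactly testable against `aov()` error
strata. The effect battery reports levodopa (`PRE_OFF − PRE_ON`), DBS
(`POST_OFF − POST_ON`) and baseline-anchored DBS (`PRE_OFF − POST_ON`)
effects as mean ± SD (n−1 denominator) with two-tailed paired t-tests at
the Bonferroni-corrected α = 0.0083 (the conventional printed constant for
this five-test family; 0.05/5 would give 0.01 — the constant is an
argument). Degenerate input is handled by convention: identical score
vectors return t = 0, p = 1; constant non-zero differences are an error
because the statistic is undefined.

## The synthetic study

`syntheticConfig()` defaults define the package's reference study — chosen
once as a realistic miniature of the within-subject DBS/levodopa design,
then frozen:

* **Geometry:** 16 × 16 × 8 voxels at 3 mm isotropic, 200 volumes at
  TR 3 s (matching a typical 10-minute 1.5 T EPI session), 13 subjects,
  five conditions.
* **Network:** disjoint region blocks driven by latent Gaussian signals
  whose correlation is the condition's coupling matrix (Cholesky
  factorization). The "motor" hub is bilateral — two disconnected 4×4×3
  patches sharing one latent signal, mimicking homologous motor cortices
  and providing the two seed components for the follow-up analysis — plus
  thalamus- and cerebellum-like blocks and two background blocks. The hub
  has the largest total base coupling, so it is the planted top-EC region.
* **Treatment effect:** in both unilateral stimulation conditions the
  coupling rises by +0.45 (motor–thalamus, motor–cerebellum) and +0.25
  (thalamus–cerebellum) — a cortico-thalamo-cerebellar connectivity
  increase confined to the ON conditions, so the interaction contrast
  isolates it. Every effective matrix is checked for positive definiteness,
  per condition, at configuration time.
* **Noise:** each voxel is `snr ×` its region's latent signal plus AR(1)
  Gaussian noise (φ = 0.3, unit innovations, stationary start), on a
  baseline intensity of 100; SNR 3. Latent signals are white in time —
  temporal smoothness enters only through the AR(1) noise, the simplest
  structure that still exercises correlation-based EC.
* **Artifacts:** an electrode-like 2×2×2 block attenuated to 0.1 of
  baseline (removed by the 40 % intensity mask), and motion traces as
  smooth 6-parameter random walks with a 3 mm translation step in ~15 % of
  runs.
* **Determinism:** each (subject, condition) run has its own RNG stream
  derived from the master seed by stable hashing, so adding subjects or
  reordering generation never perturbs existing runs.

The effect sizes were calibrated once, before freezing, so that the planted
modulation is decisively recoverable — the synthetic analogue of the
robustly significant clusters this analysis is designed around. At 120
volumes the interaction sat at the detection boundary (coverage fluctuated
seed to seed); at the acquisition-realistic 200 volumes, with the couplings
above, the interaction contrast recovers the full modulated voxel set with
off-target rejections at or below the nominal FDR level across seeds.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: hemodynamic convolution and its temporal
autocorrelation structure, physiological (cardiac/respiratory) noise,
scanner drift, realistic anatomy and atlas geometry, between-subject
anatomical variability, and motion-correlated signal artifacts. Recovery
results certify the *statistical machinery*, not robustness to fMRI
physics.

## Numerical choices

* Power iteration: sup-norm tolerance 1e-9, cap 10 000 iterations,
  uniform start (valid because the target eigenvector is positive).
* Second-eigenvalue probe: 30 deflated iterations from a deterministic
  generic start; degeneracy flagged when `λ₂/λ₁ > 1 − 1e-6`.
* Exact-fit GLM voxels (residual sum of squares below `1e-20 ×` the data
  scale) get σ̂² = 0 and t = 0 rather than 0/0 noise.
* Gaussian kernels truncated at 5σ and renormalized (tail mass < 3e-7);
  mirror reflection applied repeatedly for kernels wider than an axis.
* Fisher transform clips r at `±(1 − 1e-7)` so seed self-correlations stay
  finite.
* Cluster peak ties break toward the first voxel in linear order; trimmed
  FD maxima keep earlier frames on ties.
* `q < threshold` is strict for seed definition (a voxel at exactly the
  threshold is excluded); the BH rejection set itself uses `q ≤ level`,
  the standard step-up convention.

## Problem sizes used in the checks

The acceptance checks run the clinical battery on the bundled 13-subject
table; EC oracle agreement on 50 random instances per variant (`V ≤ 500`,
`T ≤ 64`); hub recovery over 100 single-run replicates of the reference
study; interaction coverage on one full 13 × 5 study (2040 in-mask voxels);
FDR calibration on replicate null-configuration studies; and the FD
arithmetic on 200-volume traces. These sizes keep a full run in the
low minutes on a single core while leaving each check statistically
meaningful.

## Known limitations

* No realignment, slice-timing correction or spatial normalization —
  inputs are assumed co-registered on a common grid.
* No temporal filtering or global-signal regression anywhere (none is part
  of this analysis chain).
* Voxelwise OLS variance without nonsphericity correction; with 4–5
  correlated within-subject conditions this is anticonservative in
  principle, and the null-calibration test is the empirical guard.
* The `pos` variant on reducible similarity matrices reports a flagged,
  possibly non-unique eigenvector rather than a canonical choice.
* Dense oracle guarded to `V ≤ 2000`; the chunked `abs`/`pos` paths scale
  as `O(V²T)` per iteration and are meant for moderate V.
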