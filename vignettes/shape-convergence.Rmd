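---
title: "Cranial shape, prey size, and tests of phenotypic convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cranial shape, prey size, and tests of phenotypic convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoconv)
```

## The analysis this package implements

morphoconv carries a landmark-based comparative study of cranial shape from
raw specimen coordinates to a decision about phenotypic convergence. The
motivating problem is the classic one of identifying the closest ecological
analogues of an extinct predator (such as the thylacine) among living
faunivorous mammals: given 3D cranial landmarks for many specimens, a
time-scaled phylogeny, and a table of each species' body mass, mean prey
mass, pack size, and diet composition, the pipeline asks (i) how cranial
shape covaries with size, diet, and relative prey size once phylogeny is
accounted for, (ii) which prey-size class the focal species' cranium
belongs to, and (iii) which species are *maximally convergent* with the
focal species under two complementary tests of convergent evolution.

The stages, in order:

1. **Generalized Procrustes alignment** (`gpa_align()`) removes
   translation, scale, and rotation from each configuration, yielding
   Procrustes shape coordinates and centroid sizes.
2. **Subset extraction** (`subset_shapes()`) carves the configuration into
   a facial and a neurocranial patch, each re-superimposed as its own
   dataset, alongside the total configuration.
3. **Ordination** (`pca()`) gives PC scores at the specimen and
   species-mean level; `select_pcs()` applies the 1% and 5% variance
   retention rules.
4. **Phylogenetically informed statistics**: multivariate phylogenetic
   signal (`k_mult()`) and distance-based PGLS with residual-randomization
   inference (`pgls_fit()`).
5. **Prey-size discrimination** (`cva_discriminate()`): two-group canonical
   variates on the retained PCs, leave-one-out jackknife validation, and
   assignment of the focal species (held out as an unknown) with posterior
   probabilities; plus nonparametric per-PC screens
   (`pc_ecology_screen()`).
6. **Convergence testing**: UPGMA candidate selection
   (`upgma_candidates()`), the distance-based C1–C4 metrics against a
   Brownian-motion simulation null (`c_metrics()`, `c_significance()`), the
   phenotypic vector-angle test against a tip-shuffling null
   (`theta_convergence()`), Benjamini–Hochberg FDR control (`bh_fdr()`),
   and the maximal-convergence decision rule
   (`maximal_convergence_call()`).

## Models and statistics

### Brownian motion as the null process

All phylogenetic machinery assumes multivariate Brownian motion (BM): trait
change along a branch of length $t$ is Gaussian with covariance $tR$, where
$R$ is the $p \times p$ evolutionary rate matrix. Under BM the tip data
have covariance $C \otimes R$, with $C$ the matrix of shared root-to-MRCA
path lengths (`phylo_covariance()`). Ancestral states
(`ancestral_states()`) are the maximum-likelihood (GLS) reconstruction,
equivalent to branch-length-weighted squared-change parsimony; $R$ is
estimated as the mean outer product of the phylogenetically independent
contrasts (`estimate_bm_rate()`), and `simulate_bm()` draws replicate tip
datasets by accumulating per-branch increments. Polytomies are handled
natively; zero-length branches are nudged to $10^{-8}$ of tree depth with a
warning.

### Phylogenetic signal

`k_mult()` generalizes Blomberg's $K$ to multivariate data:

$$K_{\mathrm{mult}} =
  \frac{\;\lVert Y - \bar a \rVert^2 \,/\, (Y-\bar a)^\top C^{-1} (Y-\bar a)\;}
       {\;[\mathrm{tr}(C) - n/\mathbf{1}^\top C^{-1}\mathbf{1}]/(n-1)\;}$$

with $\bar a$ the GLS (phylogenetically weighted) mean. It equals 1 in
expectation under BM on the given tree, reduces exactly to Blomberg's $K$
for $p = 1$ (the unit test asserts this against a literal transcription of
the univariate formula), and is tested by permuting tip rows.

### Distance-based PGLS with residual randomization

`pgls_fit()` whitens response and design by $C^{-1/2}$ and decomposes sums
of squares in the whitened space, so $R^2$ and a pseudo-$F$ remain defined
when trait dimension far exceeds the number of species (Procrustes
coordinates routinely have hundreds of columns). Significance comes from
permuting reduced-model residuals in the whitened space; the effect size
$Z$ standardizes the observed $F$ against that null. With an identity
covariance the whole construction collapses to ordinary least squares,
which is the test suite's oracle. Degrees of freedom follow the usual
convention (model terms, then $n - k - 1$ residual). A focal species of
unknown ecology is excluded from ecological fits via the `exclude`
argument.

### The two convergence tests

The **distance-based metrics** compare the realized tip divergence of a
species pair with the largest divergence their lineages ever reached.
Writing $D_{\mathrm{tip}}$ for the Euclidean distance between the two tip
phenotypes and $D_{\max}$ for the maximum distance over all node pairs
drawn one from each lineage path (MRCA to tip, ancestors and tips
included):

* $C1 = 1 - D_{\mathrm{tip}}/D_{\max}$ — the proportion of the maximal
  divergence closed by evolution (0 = as different as they ever were,
  1 = complete convergence);
* $C2 = D_{\max} - D_{\mathrm{tip}}$ — the same quantity unscaled;
* $C3 = C2 / L_{\mathrm{tot.lineage}}$ — scaled by the summed phenotypic
  change along both lineage paths;
* $C4 = C2 / L_{\mathrm{tot.clade}}$ — scaled by the summed change over
  every branch of the clade descending from the MRCA.

Ancestral phenotypes inside the metric are BM-ML reconstructions; an
injection hook (`node_states`) lets tests and worked examples supply exact
node values. The null distribution is generated by re-simulating BM on the
same tree with the rate matrix estimated from the data, and p-values are
+1-corrected exceedance fractions. Because the rate is estimated from data
that may themselves contain convergence, the null is slightly inflated,
which makes the test conservative rather than anticonservative.

The **phenotypic vector-angle test** measures, for each species of a pair,
the vector from the reconstructed MRCA phenotype to the tip phenotype, and
computes the angle $\theta$ between the two vectors (0° = evolving toward
the same phenotype, ~90° = unrelated directions). $\theta_{\mathrm{time}}$
divides the angle by the patristic distance between the species through
their MRCA, expressing convergence per unit time. Significance is
one-sided: the observed angle is compared against angles for random tip
pairs obtained by shuffling the convergent "state" across the tree's tips,
since convergence predicts a *smaller* angle than expected given elapsed
time. Note that when a tree genuinely contains several convergent tips,
random reassignment occasionally lands on a truly convergent pair, so the
attainable p-value saturates slightly above $1/(n_{\mathrm{shuffles}}+1)$;
this is a property of the published null construction, not an
implementation artifact.

### Decision rule and multiplicity

Within each analysis family — one family per dataset (total, facial,
neurocranial) and method (C1, $\theta$) — p-values are BH-adjusted at
$\alpha = 0.10$. A candidate is **maximally convergent** when it is
significant under *both* methods in the total dataset *and* under both
methods in at least one patch dataset. The per-(dataset × method) family
composition mirrors the per-table adjustment of the original analyses;
other groupings can be assembled by calling `bh_fdr()` directly. The rule
is monotone: lowering any p-value can only grow the maximal set (a
property test asserts this).

### Candidate selection

Candidates are screened by average-linkage (UPGMA) clustering of
species-mean PC scores retaining axes above 1% variance. The candidate set
is the focal species' largest phenogram cluster that still excludes the
majority of species: following the focal species up the merge sequence,
the cluster after its last merge containing at most half of all species.
The rationale: the screen exists to restrict expensive pairwise convergence
testing to species that are superficially similar to the focal species,
and a "cluster" that has absorbed most of the tree screens nothing — in
the degenerate limit it only dilutes the subsequent FDR families with
known-irrelevant pairs. With a tight focal cluster inside a diffuse cloud
of species, the simpler alternative (the cluster one merge below the
dendrogram root) returns nearly all species, which is why it was not
adopted. A fixed `cut_height` overrides the default rule.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `pc_variance_pct` | 1 (%) | pipeline, CVA, UPGMA, convergence | PC retention for multivariate tests |
| `pc_screen_pct` | 5 (%) | ecology screens | PC retention for per-axis rank tests |
| `prey_ratio_cut` | 0.45 | `PREY_RATIO_CUT` | per-capita prey/predator mass ratio separating small- from large-prey predators (energetic-constraint optimum) |
| `alpha` | 0.10 | BH | false discovery rate |
| `n_perm`, `n_sims`, `n_shuffles` | 1000 | all resampling tests | null sizes; the +1-corrected p floor is $1/(n+1)$ |
| `tol`, `max_iter` | 1e-8, 100 | GPA | consensus-change convergence tolerance |

The prey/predator ratio divides mean prey mass by average pack size before
dividing by predator mass, so cooperative hunters are scored by per-capita
prey intake; ratios are natural-log transformed for all continuous
analyses.

## The synthetic-data generator

No specimen data ship with the package; `simulate_study()` generates
complete fake studies instead. Its defaults emulate the structure of a
specimen-level cranial dataset: 57 species with four specimens each (two
per sex), a 381-point template with 46 fixed landmarks, 191 curve and 144
patch semilandmarks, and 72-point facial and neurocranial patches; species
means evolve by multivariate BM on a unit-depth pure-birth tree; an
optional convergent regime blends each focal species' latent mean toward a
shared target with weight $w$ (so $w = 0$ is exactly the BM null and
$w = 1$ is identical tips); centroid size carries an allometric factor
$\exp(b \cdot \mathrm{latent}_1)$ that Procrustes alignment must undo; and
the log prey/predator ratio is a noisy linear function of the first latent
axis, centred so the 45% class boundary falls at latent 0.

Two generator scales were chosen once and are used throughout:

* **Signal-to-noise.** Latent traits displace landmarks through a seeded
  orthonormal basis scaled to 5% of centroid size per unit latent, with
  per-coordinate specimen noise of 0.1% of centroid size. This puts
  between-species shape variance well above within-species digitizing
  noise — the regime in which landmark studies operate (species means
  resolvable from a handful of specimens, discrimination rates near the
  80–90% range) — while keeping the species means estimated from four
  specimens meaningfully noisy.
* **Ecology effect.** Unit slope of log ratio on latent 1 with noise SD
  0.3, giving prey-ratio–shape associations of moderate strength
  ($R^2 \approx 0.1$–0.3 at the species level).

What the generator does *not* emulate: anatomically structured covariance
(the template is an ellipsoid, the deformation basis is random
orthonormal), sexual dimorphism, measurement error that correlates along
curves, missing landmarks, and non-BM evolutionary processes (e.g.
Ornstein–Uhlenbeck attraction; convergence is implemented as tip blending
because the convergence tests are defined on realized phenotypes and
blending gives direct control over $D_{\mathrm{tip}}$). Passing tests on
synthetic data therefore demonstrate the statistical machinery and its
calibration, not the biological realism of any particular dataset.

## Numerical choices

* **Rotations** in GPA use the determinant-corrected orthogonal (SVD)
  solution, excluding reflections: a biological shape must not mirror.
* **Semilandmark sliding** is off by default. When enabled, curve and
  patch semilandmarks slide within tangent planes estimated from each
  point's nearest neighbours on the consensus, minimizing thin-plate-spline
  bending energy (3D kernel $-r$) against the consensus before each
  rotation round. Whether the original digitizing protocols slid
  semilandmarks is generally protocol-specific, hence the flag.
* **Patch datasets are re-superimposed** independently by default: each
  patch is analysed as its own shape space with its own ordination, which
  is how separate functional modules are usually interrogated.
  `realign = FALSE` carries the parent alignment instead.
* **Species means** are plain coordinate-wise means of aligned
  coordinates, not re-superimposed.
* **PCA signs** are fixed (largest-magnitude loading positive) so scores
  reproduce across platforms; axes below $10^{-12}$ relative eigenvalue
  are dropped.
* **Equal priors** in CVA assignment: group sizes reflect study design,
  not prevalence.
* **Permutation p-values** are +1-corrected everywhere, so p is never 0
  and never below $1/(n+1)$.
* **Rank tests** use exact enumeration for $n \le 20$ and the
  tie-corrected normal approximation otherwise; Spearman p-values use the
  large-sample approximation.
* **Residual randomization** (not full randomization) is the PGLS
  permutation scheme: reduced-model residuals are permuted in the whitened
  space, which keeps the permuted datasets exchangeable under the null
  while preserving the estimated mean structure.

## Problem sizes used by the test suite

The calibration and power properties are exercised at sizes chosen to make
the suite informative yet quick: null calibration of the three tests uses
200 replicate BM datasets on a 16-tip tree (100-draw inner nulls);
the Kmult calibration averages 100 BM simulations on a 50-tip tree;
power and recovery use 100 replicate studies at generator defaults with
$w = 0.9$ (200-draw inner nulls) and 50 full pipeline runs (1000-draw
nulls, the pipeline default). The acceptance script derives the analytic
C1 bound checks on a fixed 6-tip tree with injected node states.

## Known limitations

* The $\theta$ null saturates when several genuinely convergent tips share
  a tree (see above); with small candidate families this can leave a truly
  convergent pair marginally non-significant after FDR adjustment.
* `estimate_bm_rate()` resolves polytomies internally for contrast
  computation; with many zero-length resolutions the rate estimate
  degrades gracefully but is not exact ML.
* The bending-energy sliding approximates curve tangents by local
  neighbour planes; it does not use digitizing-protocol curve adjacency,
  which files in the wild rarely carry.
* Jackknife CVA refits the discriminant per held-out specimen; for very
  large specimen sets this is the dominant CVA cost.
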