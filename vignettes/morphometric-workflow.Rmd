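---
title: "Landmark-based discrimination of taxa and classification of unknown specimens"
author: "diplomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based discrimination of taxa and classification of unknown specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplomorph)
```

## The problem

Isolated skeletal elements — here, gecko maxillae recovered from Holocene
cave and midden deposits — often cannot be assigned to a species or genus
by eye, and size alone is a poor guide because size distributions of
related taxa overlap and subfossil populations may have been larger than
their extant relatives. Landmark-based geometric morphometrics offers a
principled alternative: quantify the *shape* of the element in a modern
reference sample of known taxa, show that taxa are discriminable in shape
space, and then place unknown specimens into that space and ask, for each
reference group, both *how well* the unknown fits the group (typicality)
and *which* group fits best (posterior probability).

`diplomorph` implements that chain end to end for 3D landmark
configurations with sliding semilandmarks and paired bilateral elements,
together with a synthetic-data generator that reproduces the statistical
structure of such a study, so every stage of the pipeline can be exercised
and validated without any specimen data.

## The model and its assumptions

**Shape.** A specimen is a configuration of $K$ landmarks in
$\mathbb{R}^3$ ($K = 55$ in the default scheme: 15 fixed anatomical
landmarks plus 40 semilandmarks on four curves). Shape is what remains
after removing position, orientation and scale: generalized Procrustes
analysis (GPA) centres each configuration, scales it to unit centroid size
$CS = \sqrt{\sum_k \lVert x_k - \bar{x} \rVert^2}$, and iteratively
rotates it to the evolving consensus until the consensus is stable
(RMS change $< 10^{-10}$, at most 100 iterations). Size is retained
separately as $CS$.

**Semilandmarks.** Curve points carry no point-to-point homology, so each
is allowed to slide along its local curve tangent — estimated by central
finite differences on its curve neighbours — by the step that minimizes
the Procrustes distance of the specimen to the consensus (the
minimized-distance criterion, not minimum bending energy). The step has
the closed form $s = t^\top (y - x)$ for unit tangent $t$ and is clipped
at half the distance to the nearest neighbour so points can never
leapfrog; sliding alternates with GPA re-alignment for up to 5 cycles
(tolerance $10^{-6}$ on the summed Procrustes distance). Each cycle is
non-increasing in the total distance to the consensus, which the test
suite asserts.

**Bilateral symmetry.** Left elements are mirrored (negating $x$; the
landmark scheme is treated as side-symmetric, so no relabelling is
needed) and each individual's mirrored-left and right aligned shapes are
averaged into their symmetric component ("matching symmetry"), with the
individual's $CS$ taken as the mean of the side sizes. Unpaired
individuals pass through flagged. All downstream analyses run on one
symmetric shape per individual. Sliding precedes symmetrization; the
alternative order changes results only at the sliding tolerance, and
the chosen order lets unpaired (fossil) elements reuse the identical
slide-against-consensus path.

**Morphospace.** PCA of the vectorized Procrustes coordinates (covariance
with divisor $N-1$; eigenvector signs fixed so the largest-magnitude
loading is positive) gives scores, eigenvalues and variance fractions;
the eigenvalue sum equals the total Procrustes variance. Unknowns are
never allowed to reshape the reference space: they are superimposed and
slid against the *fixed* training consensus and projected by matrix
multiplication with the stored eigenvectors. Note that an artificial
shape constructed as mean $+ c\,v_1$ projects back to exactly $(c, 0,
\dots)$ only if it is fed in already in the training frame
(`align = FALSE`); re-normalizing to unit centroid size perturbs the
score at order $c \cdot \lambda$, which is invisible in practice but
matters for exact tests.

**Hypothesis tests.** Shape is regressed on genus, $\log CS$ and their
interaction with sequential (type-I) sums of squares computed as summed
squared residual distances; significance is by residual randomization
(RRPP): for each term the reduced-model residuals are permuted, added
back to the reduced fit, and the term's $F$ recomputed, with
$p = (\#\{F^\ast \ge F\} + 1)/(n_{perm} + 1)$. $\log CS$ is the
allometry covariate (the field-standard choice; raw $CS$ is a flag away).
Term order is genus, size, genus×size. With this sequential arrangement
all three term $F$ statistics share one residual (interaction-model)
denominator with $df = N - 2G$; published analyses sometimes report
per-term denominators from different model arrangements (e.g. a size
main effect tested against $df = N - 2$), which changes the printed
degrees of freedom but not the variance decomposition. Centroid size
itself is tested by classical one-way ANOVA with Tukey HSD. Pairwise
genus shape differences use the Procrustes distance between group mean
shapes with label-permutation p-values, uncorrected.

**Phylogenetic signal.** For species-mean shapes $Y$ on a tree with
covariance $C$,
$$K_{mult} = \frac{\mathrm{tr}\,E^\top E \,/\, \mathrm{tr}\,E^\top C^{-1} E}
{\left(\mathrm{tr}\,C - n/\mathbf{1}^\top C^{-1}\mathbf{1}\right)/(n-1)},
\qquad E = Y - \mathbf{1}a,$$
with $a$ the phylogenetically weighted mean. $K_{mult}$ has expectation 1
under Brownian motion, reduces exactly to Blomberg's $K$ for one trait
(asserted against an independent univariate implementation), and is
invariant to rescaling all branch lengths. Significance is by permuting
data across tips, observed value included. Phylomorphospaces use
maximum-likelihood Brownian ancestral states.

**Classification.** A "reduced set of PC scores" feeds the CVA: by
default the smallest $k$ leading axes reaching 90% cumulative variance,
capped at $N - G - 1$ so the pooled within-group covariance $W$ stays
invertible. The CVA solves the generalized eigenproblem of the
between-group covariance against $W$; the transform whitens $W$, so
squared Euclidean distance across the full transformed space equals
Mahalanobis $D^2 = (x-\mu_g)^\top W^{-1} (x-\mu_g)$ in PC space (the
suite checks the two routes against each other at $10^{-8}$). Typicality
is the upper-tail probability $P(\chi^2_k \ge D^2)$ — an *absolute*
membership test that can reject all groups; the posterior
$\propto \exp(-D^2_g/2)$ under equal priors is *relative* and always
sums to one. A typicality call requires the best typicality to exceed
0.20; a small-sample F-form of typicality
($((m-k+1)n_g / (k\,m\,(n_g+1)))\,D^2 \sim F_{k,\,m-k+1}$, $m$ the
pooled df) is available as an option. Accuracy of discrimination is
summarized by leave-one-out cross-validation, re-estimating means and
$W$ without each specimen in turn.

### Typicality degrees of freedom

The chi-square df is the dimension in which $D^2$ is measured. Because
$D^2$ is taken across the *full* whitened space (all $k$ retained PCs,
not only the $G-1$ canonical axes with positive among-group eigenvalue),
df $= k$. Using $G-1$ would make training-member typicalities
systematically non-uniform; the suite's calibration test (uniformity of
typicality under multivariate normality, Kolmogorov–Smirnov) pins this
choice down.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the package targets, and
its defaults are the study conditions, not tuning knobs:

* 13 species in 5 genera on a fixed ultrametric tree (root depth 15),
  43 modern individuals with both sides (86 configurations), 11 unpaired
  subfossils;
* genus/species divergence: Brownian motion on the tree,
  `bm_rate = 4e-4` per coordinate per unit branch length — chosen so the
  genus term explains roughly half of symmetric shape variance, the
  regime a discriminable-genera study presupposes;
* within-species isotropic landmark noise `within_sd = 0.05` (about the
  template's curve spacing divided by ten), left–right asymmetry
  `asymmetry_sd = 0.02`;
* allometry: displacement along one fixed direction (dorsoventral
  deepening, orthogonalized against uniform scaling) proportional to the
  deviation of $\log CS$ from the genus mean; the default coefficient
  2.05 makes allometry about 7% of symmetric shape variance, the weak
  allometric signal characteristic of this kind of cranial element;
* genus centroid sizes: normal with means/sds 1690±228.1, 968±100.9,
  1198±142.9, 1241±115.6, 1093±104.0 (CT units); fossils drawn from the
  largest-bodied genus with a larger size distribution (1900±200);
* every element is emitted at its drawn $CS$ in a random rigid frame, so
  the reader/aligner is genuinely exercised.

What it does **not** emulate: spatially correlated digitization error
(optional along-tangent semilandmark jitter exists, default off),
missing landmarks, curved-surface (two-tangent) semilandmarks,
measurement error correlated between sides, or non-Brownian evolution.
Passing tests therefore demonstrate correctness of the machinery under
the stated generative model, not robustness to every pathology of real
micro-CT data.

## Numerical choices

* GPA convergence $10^{-10}$ (consensus RMS change), max 100 iterations;
  non-convergence is an error, not a warning.
* Sliding: 5 cycles, tolerance $10^{-6}$, step bound half the
  inter-neighbour distance; one-sided tangents at curve ends.
* PCA keeps eigenvalues above $10^{-12}$ of the leading one; scores of
  degenerate axes are dropped rather than reported as noise.
* CVA refuses $k > N - G$ (singular $W$) rather than regularizing.
* TPS uses the 3D kernel $U(r) = r$ with an affine part, solved with one
  step of iterative refinement; query-to-landmark distances are computed
  dimension-wise to avoid cancellation at coincident points. Singular
  systems (degenerate landmark geometry) raise an error suggesting
  jitter.
* Posteriors use max-subtraction before exponentiation.
* Permutation p-values always include the observed statistic, so they
  are bounded below by $1/(n_{perm}+1)$ and can never be zero.

## Worked sizes and runtime

The default emulation (86 + 11 configurations, 55 landmarks) runs the
complete chain — alignment, sliding, symmetrization, PCA, ANOVA with 999
RRPP permutations, $K_{mult}$ with 999 permutations, CVA, LOO and fossil
classification — in a couple of seconds on one CPU; the validation suite's
heavier blocks (100-replicate allometry recovery, 500-replicate
$K_{mult}$ and RRPP calibration) complete in about a minute. These sizes
were chosen to match the emulated study design (43 + 11 specimens), which
is small by construction.

```{r, eval = FALSE}
sim <- simulate_dataset(simulation_config(seed = 42))
res <- run_study(sim$modern, sim$fossils, tree = sim$config$tree,
                 scheme = sim$config$scheme, n_perm = 999, seed = 42)
print(res)
plot(res$pca, unknowns = predict(res$pca, sim$fossils))
```

## Known limitations

* Sliding is along curve tangents only; surface semilandmarks (sliding
  in a tangent plane) are out of scope.
* No missing-landmark estimation: configurations must be complete.
* The pairwise genus test uses the plain distance between mean shapes;
  standardized-distance variants would weight directions by within-group
  covariance and can disagree near the significance boundary.
* Group tests are not phylogenetically corrected; $K_{mult}$ quantifies,
  but does not remove, phylogenetic non-independence.
* Typicality assumes multivariate normality within groups on the
  retained PCs; with very small reference groups the F-variant is the
  safer choice.
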