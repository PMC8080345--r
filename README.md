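# diplomorph

Geometric-morphometric discrimination of taxa from 3D landmark data, and
classification of specimens of unknown affinity — built for the situation
where a modern skeletal reference collection (e.g. gecko maxillae from a
handful of genera, landmarked on micro-CT surface models) must be used to
identify isolated subfossil elements that size comparisons alone cannot
place.

## What it does

The package implements the complete landmark-based workflow as composable
fitting functions returning classed objects with `print`/`summary`/
`predict`/`plot` methods:

* **Superimposition** — generalized Procrustes analysis (`gpa()`) of
  configurations of fixed landmarks and sliding semilandmarks, with
  mirroring of left-side elements, semilandmark sliding by the minimized
  Procrustes-distance criterion (`slide_semilandmarks()`), and bilateral
  symmetrization of paired elements (`symmetrize_pairs()`). Size is kept
  as centroid size $CS = \sqrt{\sum_k \lVert x_k - \bar x\rVert^2}$.
* **Morphospace** — PCA of Procrustes coordinates (`shape_pca()`),
  projection of unknowns into the *fixed* reference space
  (`predict.shape_pca()`), shapes along axes (`shape_at_score()`),
  thin-plate-spline warps (`tps_warp()`), Brownian-motion ancestral
  states for phylomorphospaces (`ancestral_states()`).
* **Hypothesis tests** — Procrustes ANOVA of shape on genus × log(CS)
  with residual-randomization permutations (`procrustes_anova()`),
  pairwise mean-shape tests (`pairwise_group_tests()`), one-way
  centroid-size ANOVA with Tukey HSD (`size_anova_tukey()`), and
  multivariate phylogenetic signal
  $K_{mult} = \dfrac{\mathrm{tr}\,E^\top E / \mathrm{tr}\,E^\top C^{-1}E}
  {(\mathrm{tr}\,C - n/\mathbf 1^\top C^{-1}\mathbf 1)/(n-1)}$
  with tip permutation (`kmult()`), which reduces to Blomberg's K for a
  single trait.
* **Classification** — CVA on a reduced set of PC scores (`cva_fit()`),
  leave-one-out cross-validation (`loo_crossvalidate()`), and assignment
  of unknowns by Mahalanobis $D^2 = (x-\mu_g)^\top W^{-1}(x-\mu_g)$ with
  chi-square **typicality** (absolute membership: can reject every
  group) and softmax **posterior** probabilities (relative membership:
  always sums to 1) via `predict.cva_fit()`.
* **I/O** — TPS and long-format CSV/TSV landmark carriers, JSON landmark
  schemes, Newick trees (`read_tps()`, `read_landmark_table()`,
  `read_newick()`), TSV exports of every result surface.
* **Synthetic data** — `simulate_dataset()` generates a full bilateral
  study (Brownian shape evolution of 13 species in 5 genera on a tree,
  43 paired modern individuals, 11 unpaired fossils, weak allometry,
  left–right asymmetry, random rigid frames) so the entire chain runs
  and is testable with no downloads.
* **Orchestration** — `run_study()` executes read → GPA → slide →
  symmetrize → PCA → tests → CVA/LOO → classification and writes TSV
  tables plus a JSON run manifest.

## Worked example

```r
library(diplomorph)
sim <- simulate_dataset(simulation_config(seed = 42))
res <- run_study(sim$modern, sim$fossils, tree = sim$config$tree,
                 scheme = sim$config$scheme, n_perm = 999, seed = 42)
```

```
Generalized Procrustes fit: 86 configurations, 55 landmarks (3D)
  converged in 4 iteration(s); semilandmarks slid (5 cycle(s)); per-element shapes
Shape PCA: 43 specimens, 42 non-degenerate axes
  variance fractions: PC1 22.6%, PC2 12.5%, PC3 9.4%, PC4 8.3% (first 4: 52.8%)
Procrustes ANOVA (sequential SS, 999 RRPP permutations)
       term df      SS       MS       F     Rsq     p
      group  4 0.12400 0.031000 10.6700 0.50630 0.001
       size  1 0.01359 0.013590  4.6790 0.05550 0.001
 group:size  4 0.01145 0.002862  0.9851 0.04674 0.544
   residual 33 0.09587 0.002905      NA 0.39140    NA
      total 42 0.24490       NA      NA 1.00000    NA
Multivariate phylogenetic signal: K_mult = 0.665, p = 0.001001 (999 permutations)
Canonical variate analysis: 43 specimens, 5 groups, 24 retained PCs, 4 CV axes
Leave-one-out cross-validation accuracy: 100.0%
```

Reading this: the 86 simulated maxilla-like elements collapse to 43
symmetric shapes; genus membership explains 50.6% of shape variance
(highly significant under RRPP), log centroid size a further 5.6% (the
weak allometric component the generator builds in), and their
interaction is indistinguishable from noise. Species resemble each other
less than Brownian motion on the tree would predict
(K<sub>mult</sub> &lt; 1) because within-species noise dilutes the
phylogenetic signal of the species means. The five genera are perfectly
separable in cross-validation.

The classification report for the 11 unknowns mirrors a
typicality/posterior table, one row per specimen:

```
 specimen_id typ_Hoplodactylus ... typicality_call posterior_call
     fossilA             0.081              none    Hoplodactylus
     fossilB             0.999     Hoplodactylus    Hoplodactylus
     fossilC             0.555     Hoplodactylus    Hoplodactylus
     ...
     fossilK             0.025              none    Hoplodactylus
```

All fossils were generated from the Hoplodactylus shape distribution:
the posterior criterion recovers that for every specimen, while the
absolute typicality criterion (call requires p &gt; 0.20) flags the
specimens whose large size pushed their allometric shape beyond the
modern reference range — exactly the "no clear affinity" behaviour such
a table is designed to expose.

## Further reading

The methods vignette (`vignettes/morphometric-workflow.Rmd`) documents
the model and its assumptions, every tolerance and default, what the
synthetic generator does and does not emulate, and known limitations.
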