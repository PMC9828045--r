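# morphomod

Testing hypotheses of **evolutionary modularity and integration** in 3D
landmark shape data across a time-calibrated phylogeny, and characterizing
the tempo and mode of evolution of the modules found.

Flowers (and skulls, wings, shells, ...) are built from parts. When suites
of landmarks covary strongly with each other but only weakly with the rest
of the configuration, they form *modules*; whether a flower's sepals,
lateral petals, labellum and column evolve as such semi-independent units —
and whether the boundaries follow development, pollination function or
something else — is a question asked with a ledger of competing landmark
partitions evaluated against interspecific shape data. `morphomod`
implements that complete workflow for researchers in geometric
morphometrics and phylogenetic comparative methods:

1. **Alignment** — Generalized Procrustes superimposition (`gpa()`), the
   object-symmetry decomposition that isolates the symmetric shape
   component (`symmetry_decompose()`), and a phylogenetic regression of
   shape on log centroid size with randomized-residual permutation to
   decide whether a size correction is warranted
   (`phylo_allometry_test()`).
2. **Modularity tests** — the covariance ratio
   `CR = sqrt(||S12||² / sqrt(||S11°||² ||S22°||²))` with a
   landmark-reassignment permutation null, p-values and effect sizes `Z_CR`
   (`cr_permutation_test()`, `compare_cr()`), in raw and phylogenetically
   corrected (evolutionary covariance / independent contrasts) form.
3. **Likelihood model selection** — a landmark congruence correlation
   matrix (`landmark_correlations()`) fitted under every parameterization
   scheme of every hypothesis (shared or separate within- and
   between-module correlations ρ; `enumerate_schemes()`, `emmli_fit()`),
   compared by `AICc = −2·MaxL + 2K + 2K(K+1)/(n−K−1)` over the
   `n = P(P−1)/2` landmark pairs, with Akaike weights and per-module
   integration estimates (`integration_report()`).
4. **Tempo and mode** — penalized-likelihood fits of multivariate Brownian
   motion, single-optimum Ornstein–Uhlenbeck and early-burst models
   directly on a module's 3D coordinates (`fit_trait_model()`), compared by
   GIC over a set of candidate trees (`model_support_over_trees()`);
   phylogenetic half-lives `t½ = ln 2 / α` (`phylo_half_life()`);
   multivariate net evolutionary rates σ²_mult with simulation-based tests
   (`multi_module_rates()`); and per-landmark-standardized Procrustes
   variance with Tukey-HSD contrasts (`module_disparity()`).

A synthetic-data module (`make_template()`, `simulate_tree()`,
`simulate_modular_dataset()`) generates bilaterally symmetric flower-like
landmark configurations with block-structured trait correlations evolved on
ultrametric trees, so the entire pipeline is testable end to end without
any external data. `run_study()` chains all stages from one set of inputs
and writes TSV tables plus a JSON report.

## Worked example

Simulate a study-scale dataset (38 species, 52 landmarks, tree height
11.5 Myr) under the four-module hypothesis H6* and analyse it:

```r
library(morphomod)

template <- make_template()                       # 52-landmark flower
ledger   <- builtin_ledger(template$organs)       # H1 ... H6*
tree     <- simulate_tree(n_tips = 38, height = 11.5, seed = 1)
flowers  <- simulate_modular_dataset(
  simulation_spec(ledger[["H6*"]], seed = 7), tree, template)

shapes <- symmetry_decompose(gpa(flowers), template$pairing)
phylo_allometry_test(shapes, tree, n_perm = 999, seed = 2)
#> phylogenetic allometry: 6.0% of shape variance explained by log size,
#>   p = 0.002 (999 permutations)

cr_permutation_test(shapes, ledger[["H6*"]], n_perm = 999, seed = 3)
#> CR test [H6*]: CR = 0.786, p = 0.001, Z_CR = -11.65 (999 perms)

fits <- emmli_fit(landmark_correlations(shapes), enumerate_schemes(ledger))
fits
#> modularity model selection: 33 schemes, best = H6*-d
#>  scheme hypothesis letter n_modules    MaxL  K     AICc    dAICc      weight
#>   H6*-d        H6*      d         4 694.879 11 -1367.56   0.0000 9.99450e-01
#>    H6-d         H6      d         4 687.374 11 -1352.55  15.0088 5.50347e-04
#>    H6-b         H6      b         4 672.974  6 -1333.89  33.6710 4.87754e-08
#>   H6*-b        H6*      b         4 671.098  6 -1330.13  37.4229 7.47262e-09
#>   H2*-d        H2*      d         3 569.303  7 -1124.52 243.0355 1.67988e-53
```

The generating hypothesis wins decisively (Akaike weight ≈ 0.999), with
its nearest competitor the same four-module structure differing only in
the two column-foot landmarks. The CR value of 0.786 is significantly
below its permutation null (the smallest attainable p at 999 permutations
is 0.001), and the permutation-standardized effect size `Z_CR = −11.65`
quantifies the strength of the modular signal. `integration_report(fits)`
then tabulates within-module ρ̂ (here 0.20–0.58) against the uniformly
lower between-module values, and a per-module trait-model fit such as

```r
m3 <- shape_matrix(shapes)[, rep(partition_assignment(ledger[["H6*"]],
        shapes$landmarks), each = 3) == "M3"]
fit_trait_model(m3, tree, "OU")
#> OU fit (N = 38, q = 30), alpha = 0.171 (t1/2 = 46.62 Myr):
#>   logLik = 6155.57, gamma = 0.01, GIC = -11327.84
```

reports the adaptation rate α per unit tree height — here small, with a
half-life well beyond the tree height, correctly indicating that this
BM-simulated module carries no appreciable OU-like constraint.

The ten shipped hypotheses and the symmetry pairing of the default
template are also available as editable YAML fixtures under
`inst/extdata/` (`default_ledger.yaml`, `default_pairing.yaml`), together
with a small example dataset; any user-supplied ledger in the same format
replaces the built-in one.

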