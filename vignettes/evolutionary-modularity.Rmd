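---
title: "Evolutionary modularity of 3D landmark shape data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary modularity of 3D landmark shape data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomod)
```

This vignette is the package's account of the statistical machinery: the
models fitted, the assumptions they make, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where more than one defensible option
existed.

## The data and the question

The unit of data is a configuration of `P` homologous 3D landmarks
digitized on one flower per species, for `S` species related by a rooted,
time-calibrated ultrametric phylogeny (branch lengths in Myr). The
scientific question is which a-priori partition of the landmarks into
organ-level modules best describes their *evolutionary* covariation — the
covariation of species mean shapes across the phylogeny — and how the
resulting modules evolved (mode, rate, disparity).

Competing partitions are supplied as a hypothesis ledger. The built-in
ledger (`builtin_ledger()`) encodes ten hypotheses for a zygomorphic
orchid-like flower, organized in three families: *efficiency* (organs
interacting mechanically with the pollinator form a unit), *attraction*
(advertising organs vs. strictly reproductive ones), and *development*
(units follow developmental-genetic control, up to the four-module split
sepals / lateral petals / labellum / column). Four hypotheses additionally
exist in a starred variant that moves the two column-foot landmarks (the
ligament attachment point and the internal rim of the foot) from the
column module to the labellum module, encoding the hypothesis that the
hinged, motile labellum and the foot it articulates with evolve together.
Starred variants are generated programmatically from their base
hypothesis, so the two-landmark difference has a single source of truth.

The exact landmark-to-organ assignment of any real dataset is the user's
responsibility (the ledger and pairing are plain YAML files); the organ
map shipped with the package belongs to its synthetic template and is a
stand-in, not a published digitization protocol.

## Stage 1: alignment and symmetry

`gpa()` implements Generalized Procrustes Analysis: each configuration is
centred, scaled to unit centroid size, and rotated onto the iteratively
re-estimated mean shape. Only proper rotations (determinant +1) are ever
fitted, so reflections cannot be absorbed silently. Convergence is
declared when the mean shape moves less than `tol = 1e-10` (root sum of
squares) between rounds, with `max_iter = 100`; non-convergence is an
error, not a warning. Because Procrustes alignment leaves a global
rotation undetermined, the final mean is oriented onto its principal axes
with a deterministic sign convention (third moment along each axis), which
makes the output invariant — to machine precision — under arbitrary
rotation, translation and scaling of the inputs. Degenerate
(all-coincident or rank < 2) configurations are rejected by name.

`symmetry_decompose()` applies the standard object-symmetry protocol: for
each specimen a reflected copy is built by negating the left–right axis
(`axis = 2`, i.e. the configuration's midsagittal plane is x–z; both the
axis and the pairing are user-configurable) and swapping paired left/right
landmark labels, a joint GPA is run over all `2S` configurations, and the
symmetric component of a specimen is the average of its two aligned
copies. The asymmetric component is the exact remainder, so the
decomposition reconstructs each aligned configuration to within the GPA
tolerance and the symmetric/asymmetric sums of squares partition the total
(an identity the test suite checks per specimen pair). All downstream
analyses consume the symmetric component; one structural consequence worth
knowing is that the mirrored coordinate of every midline landmark is
identically zero there.

`phylo_allometry_test()` regresses the `S x 3P` shape matrix on log
centroid size by GLS under a Brownian-motion species covariance, with
significance from randomized residual permutation (RRPP; the reduced model
is the phylogenetic intercept). The permutation scheme is a design choice
— the procedure's family is standard but the literature rarely states the
reduced model — and is documented here once: residuals of the reduced
model are permuted across species and added back to the reduced fit.
P-values include the observed statistic in the null set, so the floor is
`1/(n_perm + 1)`; `n_perm = 999` by default. The pipeline applies no size
correction unless the user opts in *and* the test is significant, because
the expected finding for flower-scale data of this kind is a
non-significant allometric effect.

## Stage 2: covariance-ratio tests

For two modules the covariance ratio is
`CR = sqrt(||S12||_F^2 / sqrt(||S11o||_F^2 ||S22o||_F^2))`, where `S12`
collects the between-module covariances and `S11o`, `S22o` are the
within-module blocks with their diagonals zeroed; with more than two
modules the statistic is the mean of all pairwise CRs. The permutation
null reassigns whole landmarks (their three coordinates together — a
landmark is one biological unit) to modules, preserving module sizes; 999
permutations by default. Because low CR indicates modularity, the p-value
is the lower tail, observed value included. The effect size
`Z_CR = (CR_obs − mean(null)) / sd(null)` is computed on the untransformed
permutation distribution; log- and Box–Cox-normalized variants were
evaluated during development and did not change the behavior described
below, so the simplest definition was kept. In study reports, `Z_CR` is
shown only for hypotheses whose CR test is significant at 0.05, mirroring
the usual presentation convention.

The phylogenetically corrected variant replaces the sample covariance by
the evolutionary covariance `(X − 1a')' C^{-1} (X − 1a') / (N − 1)`, with
`C` the BM species covariance and `a` the GLS root state.

**A caution on ranking hypotheses by `Z_CR`.** The spread of the CR
permutation null shrinks as modules get larger and fewer, so standardized
effect sizes are not perfectly comparable across hypotheses with different
module counts. In the package's own simulations at study scale (38
species, 52 landmarks), where between-module noise in the sample
covariance is substantial, coarse two-module hypotheses frequently attain
more negative `Z_CR` than the finer generating partition even though the
likelihood-based model selection identifies the generating partition
reliably. `compare_cr()` is therefore best read together with the
model-selection table rather than as a standalone arbiter; the pairwise
difference test it reports (normal comparison of two standardized
deviates, difference variance 2) is likewise a documented approximation.

## Stage 3: likelihood-based model selection

`landmark_correlations()` summarizes pairwise landmark association with an
absolute vector-congruence coefficient: for landmarks `l`, `m` with
per-specimen 3D deviation vectors from the mean shape,
`r_lm = |Σ_s d_ls · d_ms| / sqrt(Σ_s ||d_ls||² Σ_s ||d_ms||²)`. The
centering convention (deviations from the mean shape; absolute value taken
because the sign of a displacement correlation is arbitrary under
rotation) is a documented choice. With a tree, the rows are phylogenetic
independent contrasts of the coordinate columns — the exchangeable
observations after correction — and the effective row count is `N − 1`.

`emmli_fit()` compares parameterization schemes that assign shared or
separate correlation parameters ρ within and between modules: scheme `a`
(one within-ρ, one between-ρ), `b` (separate within, shared between), `c`
(shared within, separate between-pair), `d` (fully separate); two-module
hypotheses admit only `a` and `b` since `c` and `d` duplicate them, and a
null scheme pools all pairs. Pair correlations are Fisher-z transformed
with sampling standard deviation `1/sqrt(n_eff − 3)`; within each ρ-set
the maximum-likelihood estimate is the z-space mean (the per-set normal
likelihood is maximized exactly there, so no grid search is needed — the
grid alternative would only discretize the same optimum). The
log-likelihood sums the normal densities of the pair z-values around
their set means, `K` is the number of ρ-sets plus one, and models are
compared by `AICc = −2 MaxL + 2K + 2K(K+1)/(n − K − 1)` with `n` the
number of unordered landmark pairs (`P(P−1)/2`), not the specimen count —
the pairs are the observations entering the likelihood, and this
convention reproduces the published arithmetic of the worked examples in
the test suite. Akaike weights over the compared set give model posterior
probabilities. The ten-hypothesis ledger yields 32 schemes plus the null;
the fully separate scheme of a four-module hypothesis has
`K = 4 + 6 + 1 = 11`.

## Stage 4: tempo and mode of module evolution

`fit_trait_model()` fits multivariate BM, single-optimum OU (fixed root at
the optimum) and early-burst models directly to a module's `N x q`
coordinates, with `q` typically exceeding `N`. The species covariances
are, for shared time `t_ij` and patristic distance `d_ij`: BM `t_ij`; OU
`exp(−α d_ij)(1 − exp(−2α t_ij))/(2α)`; EB `(exp(r t_ij) − 1)/r` with the
analytic `r → 0` limit below `|r| = 1e-8`. The fixed-root OU form is the
default (a `stationary` flag provides the alternative), matching common
penalized-likelihood practice. The root state is profiled out by GLS, and
the trait covariance `R` is estimated by linear shrinkage of the whitened
sample covariance toward its diagonal, `R(γ) = (1−γ)S + γ diag(S)`.

Model parameter θ (α or r) and shrinkage γ are chosen jointly to maximize
the leave-one-species-out *conditional* predictive log-density: species
`i` is predicted from all others through the Gaussian conditional implied
by `C(θ)` (precision-matrix identities give the conditional mean and
variance in closed form), with `R` estimated from the remaining species.
The conditional form matters: a naive LOO score on whitened rows ignores
the cross-species dependence a misspecified θ induces and, combined with
shrinkage, systematically rewards spurious θ — a failure mode we measured
(BM-simulated data preferred OU/EB almost always) and eliminated by the
conditional design (BM-simulated data now prefer BM in essentially all
replicates).

θ is parameterized per unit tree height internally (the tree is rescaled
to height 1) and converted through the height for reporting, which makes
the half-life arithmetic `t½ = (ln 2 / α) · height` exact as printed. The
default OU grid is 16 log-spaced points on `[0.01, 50]` (per unit
height); a fit selecting a grid endpoint is flagged `boundary`. The EB
grid runs to `−10` on the decelerating side but is capped at `+2` on the
accelerating side: on an ultrametric tree the accelerating-rates
covariance with `r = 2α` is *identical* (up to a scale absorbed by `R`)
to the fixed-root OU covariance, so an unbounded positive grid would
duplicate OU and turn model selection between them into a coin flip. The
cap retains the mildly positive estimates real fits report while keeping
the two families distinguishable; a user who wants the unconstrained
model passes `theta_grid` explicitly. Structurally constant columns
(e.g. midline-landmark mirrored coordinates of a symmetric component) are
dropped before fitting, with the count recorded.

Fits are compared by `GIC = −2 logLik + 2 df`, where `df` counts the
evolutionary parameter (0 or 1), the `q` root states, and effective
covariance degrees of freedom interpolated by the shrinkage intensity,
`(1−γ) q(q+1)/2 + γ q`. This linear surrogate for the effective df of a
shrunken covariance is a deliberate, self-contained choice; its absolute
values are not comparable with other implementations, and the package's
claims about it are calibration claims (the right model attains the
lowest GIC on data simulated under it), which the test suite measures.
`model_support_over_trees()` repeats the fits over a set of candidate
trees (e.g. a posterior sample) and reports the GIC mean ± 2 SD and the
percentage of trees preferring each model, ties resolved toward the
simpler model in the fixed order BM, EB, OU.

`multi_module_rates()` computes per-module net rates
`σ²_mult,m = Σ_i ||ỹ_i,m||² / (N p_m)` from BM-whitened, root-centred
coordinates, standardized by landmark count `p_m` so modules of different
size are comparable (the same standardization the disparity measure
states explicitly; it is configurable in the sense that the unstandardized
quantity is `rate * p_m`). The max/min rate ratio is tested against BM
simulations under a common-rate covariance constructed from the estimated
evolutionary correlations with every coordinate variance set to the pooled
mean — equal rates by construction, correlation structure preserved.
`module_disparity()` divides each module's Procrustes variance by its
landmark count and compares modules with Tukey's HSD over per-species
standardized squared deviations.

## The synthetic-data generator

The generator exists so that every stage is testable at the study's actual
scale without any external data. Its defaults are fixed once:

* 38 tips on a pure-birth tree rescaled to exactly 11.5 Myr height — the
  clade size and crown age of the motivating system;
* 52 landmarks in organ clusters (18 sepal, 10 lateral petal, 10
  labellum, 12 column, 2 column-foot), bilaterally symmetric about the
  x–z plane, with midline counts fixed per organ and paired landmarks
  exact mirror images;
* block-structured landmark correlations `Ω ⊗ I₃` with within-module
  ρ = 0.5 and between-module ρ = 0.15 — a clearly modular preset lying
  inside the empirically reported ranges (within ≈ 0.28–0.53, between
  ≈ 0.12–0.27); per-module values can be set individually;
* Brownian motion per module at a per-coordinate rate of `1e-4 /Myr`
  (shape deviations of a few percent of centroid size over the tree), and
  i.i.d. asymmetric jitter of sd 0.005 so the symmetry decomposition has
  something to remove.

Species deviations are matrix-normal draws with row covariance from the
per-module evolutionary model and column covariance `Ω ⊗ I₃` scaled by
the rates; when modules carry different models, each module's block is
propagated under its own tree transform while cross-module correlation is
applied to the shared innovations — exact under a common model, an
approximation under mixed models. Datasets are bit-reproducible from the
seed.

What the generator does **not** emulate: digitization error models,
within-species sampling, allometric signal (size and shape are generated
independently), topological tree uncertainty (`simulate_tree_set()`
perturbs node ages only), and the geometry-induced correlation structure
of real organs. One known interaction deserves emphasis: because the
generator draws free (asymmetric) deviations, the symmetrized component
couples mirror pairs, so realized congruence correlations in the
symmetric component are a monotone transform of the generating ρ (about
`4ρ/(3+ρ)` for cross-landmark pairs, higher for exact mirror pairs)
rather than ρ itself. Recovery tests of the *estimator* therefore use
unsymmetrized deviations, while pipeline-level tests assert ranking
behavior, not equality of ρ̂ with the generating value. Passing tests
show the machinery recovers the structures it assumes, at the stated
sizes; they do not validate the biological realism of any particular
dataset.

## Problem sizes and runtime choices

The test suite runs recovery at the full study scale (38 × 52, 20
replicates, 999 permutations) for the modularity stages, parameter
recovery for the trait models at `q = 30` coordinates, and null
calibration with 99–199 resamples; the complete suite takes under a
minute on one core. The pipeline's defaults (999 permutations, 100 trees)
are the analysis-grade settings; tests and examples scale these down
explicitly, never silently.

## Known limitations

* `Z_CR` comparability across hypotheses with different module counts is
  imperfect (see the caution above); the likelihood route is the more
  reliable arbiter at these sample sizes.
* The congruence correlation discards the sign of landmark co-movement,
  and the Fisher-z likelihood treats pairs as independent observations —
  both standard, both approximations.
* Multi-optimum OU models and data-driven module discovery are out of
  scope: the ledger is an a-priori instrument.
* The GIC degrees-of-freedom surrogate is internally consistent but not
  exchangeable with other software's absolute GIC values.
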