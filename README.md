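# nectarevo

Comparative analysis of floral nectar-trait evolution across pollination
syndromes on time-calibrated phylogenies.

Floral nectar is the main reward plants offer their pollinators, and its
volume and chemistry are expected to track the pollinator community: birds
favour large volumes of dilute, sucrose-rich nectar; flies tolerate tiny
volumes; bees and butterflies sit in between. `nectarevo` implements the
full analytical pipeline for testing this idea on a clade (the motivating
system is *Impatiens*, Balsaminaceae): reconstruct pollination syndromes on
the tree, compare trait-evolution models with and without
syndrome-specific selection, estimate per-syndrome evolutionary optima
with uncertainty, and relate multivariate nectar composition to syndrome.

## The models

For a trait `y` (log- or logit-transformed) on an ultrametric tree of `n`
species, six nested/non-nested evolutionary models are compared:

| model   | process | free parameters |
|---------|---------|-----------------|
| `WN`      | white noise (star phylogeny), iid N(μ, s²) | 2 |
| `BM.s`    | Brownian motion, covariance σ²·C | 2 |
| `Lambda`  | BM with Pagel's λ scaling off-diagonal covariance | 3 |
| `BM.rate` | BM with one rate σ²ᵣ per selective regime | 1 + R |
| `OU.s`    | Ornstein–Uhlenbeck toward a single optimum θ | 3 |
| `OU.poll` | OU with one optimum θᵣ per pollination syndrome | 2 + R |

The OU mean follows the Hansen construction: tip *i* expects
`Σᵣ W(i,r)·θᵣ`, where `W` integrates `α·e^{−α(T−t)}` over the regime
history of lineage *i* (plus root weight `e^{−αT}`), and the covariance on
an ultrametric tree is
`V_ij = σ²/(2α) · e^{−α d_ij}(1 − e^{−2α s_ij})`.
Models are ranked by the small-sample AICc and Akaike weights
`w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2)`; the strength of selection is
summarized by the phylogenetic half-life `t½ = ln 2 / α`.

Regimes come from a maximum-likelihood ancestral-state reconstruction of
the five syndromes (bird, fly, butterfly, bee, bee-and-butterfly) under an
equal-rates Mk model (Felsenstein pruning, uniform root prior), each node
assigned its most probable state and each branch the state of its tipward
node. Phylogenetic regressions (e.g. log volume ~ syndrome + log spur
length) use generalized least squares with jointly ML-estimated Pagel's λ.
The multivariate stage standardizes the nectar variables, clusters species
by UPGMA, tests the syndrome association with a Mantel permutation test on
a hand-built syndrome distance (0.5 between bee or butterfly and the mixed
bee-and-butterfly class, 1 otherwise), and measures the λ signal of
syndrome on the nectar dendrogram against a star-tree reference.

A synthetic-data generator (`generate_study_like_dataset()`) produces Yule
chronograms, Mk regime histories and traits under any of the six models,
so the entire pipeline is testable without the original measurements.

## Worked example

```r
library(nectarevo)

b <- generate_study_like_dataset(seed = 42)    # 57 species, 22 Ma crown age
painting <- reconstruct_regimes(b$tree, b$syndromes)

y <- transform_trait(setNames(b$traits$volume_ul, b$traits$species), "log")
cm <- compare_models(b$tree, y, painting = painting)
cm
#> Model comparison (best: OU.poll )
#> # A tibble: 6 x 5
#>   model   loglik     k  aicc   weight
#>   <chr>    <dbl> <int> <dbl>    <dbl>
#> 1 OU.poll  -31.2     7  78.7 1   e+ 0
#> 2 OU.s     -92.4     3 191.  3.61e-25
#> 3 BM.rate  -92.0     6 198.  1.40e-26
#> 4 Lambda   -99.6     3 206.  2.56e-28
#> 5 WN      -102.      2 207.  1.09e-28
#> 6 BM.s    -104.      2 212.  1.05e-29
```

The Akaike weight of ~1.00 says the per-syndrome OU model decisively beats
the alternatives for nectar volume. The fitted optima, back-transformed to
microlitres with Hessian-based 95% intervals:

```r
fit <- cm$fits$OU.poll
estimate_theta_uncertainty(fit, b$tree, y, painting = painting,
                           transform = "log")
#>              regime  theta     se theta_natural ci_lower ci_upper
#> 1              bird  3.192 0.1581        24.334   17.851    33.17
#> 2         butterfly  1.366 0.1479         3.919    2.933     5.24
#> 3               bee  1.552 0.1322         4.719    3.641     6.11
#> 4               fly -0.726 0.0836         0.484    0.411     0.57
#> 5 bee_and_butterfly  1.341 0.1581         3.825    2.806     5.21
```

Bird-pollinated lineages evolve toward ~24 μL optima, flies toward ~0.5
μL, with the insect syndromes in between; the fitted
`phylogenetic_half_life(fit$params$alpha)` of ~0.015 Ma is a tiny fraction
of the 22 Ma tree height, i.e. adaptation to a new syndrome is fast
relative to the clade's age. The one-call pipeline

```r
res <- run_full_analysis(list(simulation = list(seed = 42), seed = 1,
                              out_dir = "run"))
```

writes six reports (model comparison, OU parameters, optima, PGLS tables,
multivariate/Mantel summary, machine-readable run log).

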