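---
title: "Modelling nectar-trait evolution across pollination syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nectar-trait evolution across pollination syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nectarevo` asks whether floral nectar — its volume, sugar concentration,
sucrose proportion and amino-acid content — evolves toward different
optima in lineages serving different pollinators. This vignette explains
the models the package fits, the choices behind their implementation, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## Data model and transforms

Inputs are a rooted, time-calibrated (ultrametric) phylogeny with branch
lengths in Ma, and a species-by-trait table with a five-level pollination
syndrome per species (`bird`, `fly`, `butterfly`, `bee`,
`bee_and_butterfly`). Replicate nectar samples per species are averaged on
the raw scale before transformation; the replicate-to-replicate
differences in this kind of data are small relative to between-species
variation, so the choice of aggregation has little leverage.

Volume (μL) and amino-acid concentration (mM) are log-transformed;
concentration-like percentages (sugar % w/w, sucrose proportion,
amino-acid fractions) are logit-transformed. Two conventions are fixed
deliberately:

* percentages are divided by 100 first, so logit offsets act on the
  proportion scale — `logit(x + 0.001)` for main percentage traits that
  contain zeros, `logit(x + 0.01)` always for the 22 amino-acid fractions
  (many of which are structurally zero);
* all reported optima and intervals are back-transformed to natural units,
  which makes confidence intervals asymmetric on the natural scale.

Ultrametricity is checked as a maximum relative root-to-tip deviation
(default tolerance `1e-3`); OU fits refuse trees beyond tolerance rather
than silently proceeding, because the OU covariance used here assumes
contemporaneous tips. Species missing a particular trait are dropped from
that trait's analyses only (morphological traits typically cover a subset
of species).

## Regimes from ancestral-state reconstruction

Selective regimes are the pollination syndromes extended over the tree. We
fit a one-parameter equal-rates (ER) Mk model to the tip syndromes by
maximum likelihood (Felsenstein pruning with per-node rescaling, uniform
root prior) and compute marginal ancestral-state probabilities with the
standard up-down algorithm. ER with a uniform prior is the only
defensible parameterization at five states and a few dozen species; richer
Mk variants would be unidentifiable. Each internal node takes its
most-probable state, with ties broken deterministically toward the lowest
index in the canonical syndrome order (and logged). Branches then inherit
the state of their tipward endpoint — a convention, not a theorem: the
reconstruction yields node states, and some rule must extend them to
branches. The tipward rule keeps exactly one regime per branch (what the
OU machinery needs) and errs toward placing transitions early on a branch.
The painting stage is deliberately separate from the fitting stage, so a
painting from any other source (e.g. a known true history in simulations)
can be substituted.

## The six-model comparison

Each transformed trait is fitted under six Gaussian models on the tree,
all evaluated as exact multivariate-normal likelihoods:

* **WN** — star phylogeny, iid `N(mu, s2)`: no phylogenetic structure.
* **BM.s** — Brownian motion, covariance `sigma2 * C`, `C_ij` the shared
  root-to-MRCA path length.
* **Lambda** — BM with Pagel's λ multiplying the off-diagonal of `C`;
  λ is estimated in `[0, 1]`.
* **BM.rate** — BM with a separate rate per regime; the covariance is
  `sum_r sigma2_r * C_r`, `C_r` accumulating only shared path length spent
  in regime `r`.
* **OU.s** — single-optimum Ornstein–Uhlenbeck.
* **OU.poll** — OU with an optimum per syndrome. Expected values follow
  the Hansen weight matrix: lineage `i`'s weight on optimum `theta_r` is
  the integral of `alpha * exp(-alpha (T - t))` over the segments of its
  root-to-tip path painted `r`, with the root weight `exp(-alpha T)`
  assigned to the root regime, so rows sum to one. The covariance is
  `V_ij = sigma2/(2 alpha) * exp(-alpha d_ij) (1 - exp(-2 alpha s_ij))`.

Root handling for the OU models follows the "optimum-pinned" convention:
no separately estimated ancestral state, the root weight goes to the root
regime's optimum. This keeps the parameter counts at `k = 3` (OU.s) and
`k = 2 + R` (OU.poll) and matches reporting a single `sigma2`/`alpha` with
per-syndrome optima only. Parameter counts for the others: WN and BM.s 2,
Lambda 3, BM.rate `1 + R` (means and variances count as parameters).

Fitting profiles everything linear analytically: given `alpha` (or λ, or
the per-regime rates), the optima/means are generalized-least-squares
solutions and the overall scale `sigma2` has a closed-form ML estimate, so
the numerical search is 1-dimensional for OU.s/OU.poll/Lambda (bounded;
`alpha` on the log scale over `[1e-9/T, 1e3/T]` with three deterministic
starts at half-lives of `2T`, `0.1T` and `0.001T`) and R-dimensional on
log rates for BM.rate. Convergence is to `1e-8`-scale likelihood
tolerance; all starts are fixed, so fits are deterministic. Degenerate
inputs (constant traits, too few species for the AICc denominator) are
refused with explicit errors.

Models are compared by `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)` and
Akaike weights. A model that fails to fit is recorded with its error and
weight 0 rather than aborting the comparison. Selection strength is
reported as the phylogenetic half-life `t1/2 = ln 2 / alpha` — the time
for the expected trait to move halfway to a new optimum; values much
smaller than the tree height mean history barely constrains the present.

Optimum uncertainty uses the inverse numerical Hessian of the negative
log-likelihood at the ML point (variance and rate parameters on the log
scale, optima on the analysis scale); intervals are `theta +- 1.96 se` on
the analysis scale and then back-transformed. A singular Hessian triggers
a seeded parametric bootstrap (199 refits on data simulated from the
fitted model), flagged in the output. For the λ model a profile-likelihood
interval for λ is reported; the point estimate is constrained to `[0, 1]`
but the interval is computed on the unconstrained profile surface, so its
upper bound may exceed 1 — this matches how λ intervals wider than the
unit interval arise in practice.

## Phylogenetic regression

`pgls_fit()` estimates regression coefficients and Pagel's λ
simultaneously: for a given λ the GLS solution under `sigma2 * C_lambda`
is exact, and λ is maximized over `[0, 1]` by bounded search (endpoints
checked explicitly, since profile surfaces are often maximized at 0 or 1).
Categorical predictors use treatment coding with `bird` as the reference
level in the fixed order bird/butterfly/bee/fly/bee-and-butterfly, so
syndrome contrasts read as "tested against bird-pollinated flowers".
Standard errors use the unbiased residual variance and t tests with
`n - p` degrees of freedom; model comparison across fixed-effect
structures uses AICc with ML likelihoods, counting λ as a parameter when
it is estimated (a convention that must be fixed one way or the other; it
is stated in the output). No multiple-testing correction is applied. A
perfectly collinear response yields a capped t statistic rather than an
error.

## The multivariate nectar-syndrome stage

Seven variables describe overall nectar composition: transformed volume,
sucrose proportion, sugar concentration and amino-acid concentration, plus
the first three axes of a PCA of the 22 logit-transformed amino-acid
fractions. All are z-scored ("scaled to unit variance") before Euclidean
distances are computed. PCA uses the correlation matrix with a
deterministic sign convention (the dominant loading of each axis is made
positive) so scores are reproducible across platforms; constant columns
(amino acids absent from every species) are dropped by the pipeline before
a correlation PCA, since they carry no compositional information.

Clustering is UPGMA (average linkage); the dendrogram is returned as an
ultrametric tree whose cophenetic distances reproduce the merge levels
(heights are half the merge distances). Ties in merge order follow the
deterministic behaviour of the agglomeration over a fixed input order.

The syndrome association is tested two ways:

* a **Mantel test** (default `n = 9999` permutations, seeded) between the
  nectar distance matrix and a hand-built syndrome distance: 0 within a
  syndrome, 0.5 between the mixed bee-and-butterfly class and either bee
  or butterfly, 1 otherwise. The test is one-sided (greater), since the
  hypothesis is positive association; `p = (1 + #{r_perm >= r_obs}) /
  (1 + n_perm)`.
* a **λ signal of syndrome on the dendrogram**: internal dendrogram
  branches are scaled by λ with tip depths preserved (the discrete-trait
  analog of the continuous λ transform), an ER Mk model is fitted on the
  transformed tree, λ is maximized in `[0, 1]`, and a 1-d.f. likelihood
  ratio test compares the optimum against λ = 0, which is exactly the
  star-tree (white noise) reference. How to operationalize "λ of a
  discrete trait on a cluster dendrogram" is genuinely open; this
  construction is one defensible reading and is labelled as such. A
  caveat discovered while validating it: the *point estimate* of λ is
  weakly identified when the trait occupies only a small part of a larger
  assumed state space (the profile is nearly flat and the argmax can sit
  at 1 under the null), whereas the likelihood-ratio statistic remains
  well calibrated when the state space matches the observed states — so
  inference should lean on the LRT, not on λ̂ alone.

## The synthetic-data generator

`generate_study_like_dataset()` emulates the study design so that every
stage has realistic, fully-known input: 57 species, crown age 22 Ma (an
alternative 23.7 Ma total height can be requested), five syndromes, traits
at the published magnitudes.

* **Tree**: Yule process conditioned on the tip count — `n - 1`
  exponential inter-speciation waits with rate `k` at `k` lineages,
  uniform choice of the splitting lineage, one final wait, then node
  depths rescaled to the requested crown age. The unscaled waits are kept
  as attributes so the Yule branching law (`k x wait` standard
  exponential) stays testable after rescaling. Trees are exactly
  ultrametric by construction.
* **Regimes**: an ER Mk history (rate 0.03 per Ma per pair by default, a
  moderate value giving a handful of syndrome shifts over 22 Ma) simulated
  with within-branch change points retained; the exported painting
  collapses each branch to the state of its tipward node, matching the
  convention of the reconstruction stage. The history is conditioned
  (bounded deterministic retries) on all five syndromes being present at
  the tips.
* **Traits**: volume, sugar concentration and sucrose proportion evolve
  under the per-syndrome OU model and amino-acid concentration under
  single-optimum OU, with the process parameters at the reported
  magnitudes (e.g. volume: `sigma2 = 5.42`, `alpha = 14.9`, bird optimum
  37.1 μL, fly optimum 0.5 μL on the log scale) and the remaining insect
  optima set to mid-range values consistent with the reported optimum
  ordering. Tip values are drawn from the OU transition law *truncated*
  to the published trait envelope (volume 0.06–72.16 μL, sugar
  0.73–76.9%, sucrose proportion 25.2–99.8%, amino acids 0.20–69.70 mM);
  internal nodes follow the exact law. Truncation, rather than
  whole-dataset rejection, is the honest way to condition on a published
  min–max: the envelope is the realized range of one 57-species dataset,
  and under the reported stationary spread the probability that *all*
  tips of a fresh realization stay inside it is far too small to reject
  against (for sucrose proportion, essentially zero).
* **Composition and morphology**: 22 amino-acid fractions are generated
  from log-normal abundance draws normalized to 100%, with fractions
  below 0.3% zeroed and renormalized — producing the structural zeros
  (rare amino acids such as methionine) that exercise the logit-offset
  path. Spur length is allometric in volume
  (`log total spur = 0.4 + 0.6 log volume + N(0, 0.3)`) with nine species
  left unmeasured, emulating a 48-of-57 morphology subset. These two
  pieces are plausibility scaffolding, not calibrated models.

Everything is a pure function of the seed (sub-seeds are derived
deterministically), so two runs with the same seed are byte-identical on
disk.

What the generator does *not* emulate: phylogenetic signal in amino-acid
composition (fractions are iid across species), measurement error,
correlated evolution among traits beyond the spur–volume link, extinction
(no birth–death trees), and any irregularity of a real calibrated
chronogram. Passing tests on synthetic data therefore demonstrate that
the estimators recover known generating processes at realistic sizes — not
that any particular empirical dataset satisfies those processes.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the study's own
scale (57 tips) with replicate counts chosen to estimate the monitored
proportions stably: 200 replicates for parameter recovery, 100 for
model-selection power, 500 for null-calibration checks, permutation counts
of 199–9999 depending on context. Likelihood equality checks against
dense-matrix oracles use `1e-8` tolerances; transform round-trips `1e-10`;
ultrametricity of constructed trees `1e-9` relative.

Tie-breaking is deterministic everywhere randomness is not explicit:
argmax ties in ancestral states go to the lowest-index state, PCA signs
follow the dominant loading, UPGMA follows the fixed input order. All
stochastic stages (simulation, permutation, bootstrap) take explicit
seeds and restore the RNG state afterwards.

## Known limitations

* One `alpha` and one `sigma2` are shared across regimes in OU.poll;
  per-regime rate/selection variants and multivariate OU are out of scope.
* AICc parameter counts are a convention (means and variances counted);
  published AICc values from other software may differ by a constant per
  model family, which cancels in weights computed within one convention
  but not across conventions.
* The branch-painting rule (tipward endpoint) is one of several
  reasonable conventions and can matter when regimes change on long
  branches.
* Marginal (not joint) ancestral reconstruction is used; argmax
  assignment discards reconstruction uncertainty in downstream OU fits.
* The dendrogram λ construction is a defensible but non-unique reading of
  "phylogenetic signal on a cluster dendrogram" (see above); its λ̂ should
  be interpreted through the LRT.
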