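Package: nectarevo
Title: Evolution of Floral Nectar Traits Across Pollination Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of nectar-trait evolution on time-calibrated
    phylogenies. Fits and compares six trait-evolution models (white noise,
    Brownian motion with one or several rates, Pagel's lambda, and
    Ornstein-Uhlenbeck processes with a single optimum or per-pollination-
    syndrome optima) by small-sample AIC and Akaike weights, reconstructs
    ancestral pollination syndromes under an equal-rates Mk model and paints
    selective regimes onto branches, estimates phylogenetic half-lives and
    optimum uncertainty, runs phylogenetic generalized least squares with
    jointly estimated Pagel's lambda, and relates multivariate nectar
    composition to pollination syndrome through PCA, UPGMA clustering and a
    Mantel test. Includes a synthetic-data generator producing Yule trees,
    Mk regime histories and trait data with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    expm,
    nlme,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
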