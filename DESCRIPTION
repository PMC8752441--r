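Package: traitscape
Title: Global Trait-Environment Analysis with Gap-Filling, Trait Axes and
    Climate-Soil Variance Partitioning
Version: 0.1.0
Authors@R:
    person("Trait", "Scape", email = "maintainer@traitscape.org", role = c("aut", "cre"))
Description: Pipeline for ecoregion-scale analysis of plant functional trait
    spectra. Imputes missing trait observations by hierarchical probabilistic
    matrix factorization over the taxonomy (Gibbs sampling with per-value
    uncertainty), applies z-score quality control, aggregates observations to
    species medians per ecoregion and to ecoregion medians, decomposes the
    trait correlation structure into size and economics axes (complete-linkage
    clustering, PCA, latitudinal-gradient regression), partitions the variance
    of each trait into joint and independent climate and soil effects via
    ridge regression with nested cross-validation and hierarchical
    partitioning, and relates trait axes to environmental gradients by
    redundancy analysis with variance-inflation pruning. A synthetic-world
    generator with known latent structure (a latitude-linked climate factor
    and a latitude-independent soil-fertility factor) makes every stage
    verifiable against ground truth without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
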