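Package: paleoASR
Title: Ancestral State and Biogeographic Reconstruction on Time-Scaled
    Phylogenies with Fossil Tips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for Bayesian tip-dating studies of clades
    with rich fossil records. Provides time-trees with absolute node ages on
    top of the 'ape' phylo container; preparation of morphological
    supermatrices (concatenation with duplication balancing, invariant-column
    removal, ordered longitudinal-zone coding, multi-locality OTU splitting
    with uniform tip-age priors); marginal ancestral state reconstruction for
    ordered and unordered discrete characters under the Mk model; a two-pass
    ancestral geocoordinates reconstruction under bivariate Brownian motion
    with confidence ellipses, including distance-to-time scaling of
    multi-locality tips via neighbor joining, nonparametric rate smoothing and
    subtree grafting; time-slice lineage-through-time tables with geographic
    zone subsetting; posterior tip-age summaries (median and highest density
    intervals), clock-rate prior derivation with BIC model selection, and ln
    Bayes factor comparison. A synthetic-data module simulates
    fossilized-birth-death trees, Mk characters, Brownian geocoordinates and
    multi-locality occurrence tables so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    geosphere,
    fitdistrplus,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
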