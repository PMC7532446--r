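Package: druminfo
Title: Species-Identity Information in Woodpecker Drumming Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the species-identity information carried by woodpecker
    drumming displays and its evolution along a phylogeny. Provides a synthetic
    generator for pulse-train drums, species, trees, discrete/continuous trait
    histories and geographic ranges; extraction of 22 temporal/amplitude
    acoustic features with z-scoring and principal component reduction;
    Ward.D2 clustering of species acoustic profiles into drumming types with
    majority-rule selection of the number of clusters; leave-one-out
    discriminant classification with a permutation null, confusion-matrix
    mutual information (local and overall, in bits), the ceiling-normalized
    information and the pairwise Classification Index; continuous-time Markov
    (Mk-type) ancestral state reconstruction under six rate parameterizations
    with AICc model averaging and tip priors; Brownian-motion ancestral states
    and Pagel's lambda; information-through-time bootstrap trajectories;
    analytic diversifying-selection scenarios; and community-level analyses of
    sympatry, virtual-community discriminability and character displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    MASS,
    Matrix,
    phytools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
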