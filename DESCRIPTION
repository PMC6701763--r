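Package: mothwaves
Title: Haplotype Diversity and Travelling Outbreak Waves in Forest Pest Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tidy tools for two complementary analyses of outbreaking forest
    insect populations. The population-genetics arm collapses aligned mtDNA
    (COI) sequences into haplotype tables and computes diversity and
    neutrality statistics (segregating sites, haplotype and nucleotide
    diversity, Tajima's D, Fu's Fs via the Ewens sampling formula) together
    with Hudson-type pairwise Fst and statistical-parsimony (TCS-style)
    haplotype networks. The time-series arm implements an outbreak
    travelling-wave detector for annual defoliation records: log(x+1)
    transform, three-point Hunn smoothing, stationarization, smoothed
    periodogram cyclicity estimates, and lagged cross-correlation with
    t-based significance. Seeded synthetic-data generators for star-like
    haplotype genealogies and zero-inflated cyclic outbreak panels make
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
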