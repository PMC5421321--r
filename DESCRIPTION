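Package: fluxome
Title: Compartmentalized 13C Metabolic Flux Analysis and Fermentation
    Analytics for Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents the compartmentalized central-carbon metabolic
    network of the oleaginous yeast Yarrowia lipolytica, simulates GC-MS
    mass distribution vectors of proteinogenic amino-acid fragments with
    the elementary metabolite unit (EMU) framework, and estimates
    intracellular fluxes from parallel isotope labeling experiments by
    variance-weighted nonlinear least squares.  Also provides fermentation
    time-course analytics (specific growth rates, substrate consumption
    rates, citrate yields, nutrient-limitation onsets), FPKM computation
    and two-fold expression-change classification for two-phase RNA-seq
    count tables, and fully seeded synthetic-data generators so every
    analysis stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
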