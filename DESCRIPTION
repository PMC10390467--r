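Package: tRNAcad
Title: Computer-Aided Design of tRNA Abundance Distributions for
    Translation-Rate Engineering
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for engineering the speed of protein synthesis in
    bottom-up synthetic cellular systems by tuning relative tRNA
    abundances. Implements a post-hoc Monte-Carlo estimator that maps a
    tRNA abundance distribution, a codon-cognate map and a weighted
    transcriptome to expected translation-elongation latencies; a Markov
    surrogate kernel (closed form and Monte-Carlo) for single-codon
    latencies plus a pre-computed component-latency table backend;
    rational distribution generators (uniform, stepwise, codon-weighted,
    bounded random, pairwise perturbations); RED20-style transcriptome
    recoding and tRNA-set reduction; a genetic algorithm (CD-CAD) that
    evolves distributions toward faster or slower elongation under
    abundance bounds; a TINA mixing-recipe calculator for assembling
    specified distributions from synthetic tRNA stocks; and a
    fluorescence-kinetics pipeline (Gaussian smoothing, background
    subtraction, maximal-rate extraction, batch normalization,
    Kolmogorov-Smirnov comparisons) for validating designs in vitro.
    Synthetic-data generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, Translation, SyntheticBiology
RoxygenNote: 7.3.3
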