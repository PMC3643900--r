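Package: bonemeta
Title: Microbial Metagenome Profiling and Ancient-DNA Damage Analysis for
    Bone Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microbial DNA in ancient-bone shotgun
    metagenomes sequenced on 454-style platforms. Implements duplicate-read
    clustering (strict per-emulsion single linkage and greedy identity
    clustering), end-adaptor detection and trimming, mean-quality filtering,
    curated rRNA reference handling with an abundance-based majority
    lowest-common-ancestor taxonomic classifier, taxon-binned reference-guided
    consensus building, a read-versus-consensus substitution-spectrum
    statistic that separates cytosine-deamination damage from sequencing
    error, in silico restriction digestion with IUPAC motifs, and a
    precision/recall benchmark for rRNA read detection. A synthetic-data
    generator with full ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ggplot2,
    rlang,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
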