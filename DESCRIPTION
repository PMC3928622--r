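Package: rrbskit
Title: Reduced-Representation Bisulfite Sequencing Simulation, Alignment
    and Differential Methylation
Version: 0.1.0
Authors@R:
    person("Maya", "Calder", email = "maya.calder@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for reduced-representation bisulfite
    sequencing (RRBS) methylome analysis built around MspI/TaqI libraries:
    in-silico sequential restriction digest and size selection, a
    C-to-T-converted fragment-end reference database, three-letter
    bisulfite-aware read alignment with an exhaustive-search uniqueness
    filter, per-cytosine methylation calling in CpG/CHG/CHH contexts,
    per-site Fisher exact / Welch t differential-methylation testing with
    genomic feature annotation, CpG-island detection, a Pfaffl-method
    qRT-PCR expression utility, and a ground-truth bisulfite read
    simulator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
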