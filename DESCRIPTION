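Package: ystrkit
Title: Forensic Y-STR Haplotype Analysis and Population Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic analysis of Y-chromosomal short tandem repeat
    (Y-STR) haplotype panels such as Yfiler (17 slots) and Yfiler Plus (27
    slots): parsing and quality control of haplotype tables (null alleles,
    copy-number variants, microvariant census), direct-counting allele and
    haplotype frequencies, gene diversity, haplotype diversity, discrimination
    capacity and random match probability, pairwise Rst by two-level analysis
    of molecular variance (AMOVA) with permutation p-values and Bonferroni
    correction, classical multidimensional scaling of distance matrices,
    neighbor-joining trees with Newick output, and a stepwise-mutation-model
    simulator of diverging male populations for calibration studies.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
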