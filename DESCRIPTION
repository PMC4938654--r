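Package: bsamap
Title: Bulked Segregant Analysis Mapping of Recessive Mutants with the
    CAAFD Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Map-based cloning toolkit for recessive mutants in F2
    populations using bulked segregant analysis by sequencing (BSA-seq).
    Implements marker selection from pooled allele counts, the cubic
    average allele frequency difference (CAAFD) sliding-window scan with
    peak-region calling, selected-recessive fine mapping (recombination
    fractions, LOD scores, Kosambi map distances, interval delimitation),
    a presence-pattern candidate-variant filter with a cosegregation
    test, and classical segregation statistics.  A forward simulator of
    F2 populations, DNA bulks and pooled sequencing allele counts makes
    the whole pipeline runnable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
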