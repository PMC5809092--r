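Package: introscan
Title: Ancestry Painting and Introgression Analysis for Bacterial
    Evolve-and-Resequence Experiments with Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing genomes from bacterial evolution experiments
    with Hfr-conjugation-mediated horizontal gene transfer. Classifies every
    variant in a recombinant genome by provenance (recipient-evolved, donor
    K-12, new, replaced, or donor-specific) via set algebra over donor,
    recipient, and recombinant call sets; paints chromosomes into alternating
    donor/recipient ancestry segments from differentiating markers; computes
    genome-binned introgression and divergence statistics with natural cubic
    spline smoothing; performs locus-level allelic-state classification,
    gene-conversion detection, and recombination-versus-mutation accounting;
    analyzes two-timepoint allele-frequency dynamics including last-common-
    ancestor fixed haplotypes and coverage-based plasmid frequencies; and
    ships a forward simulator of Hfr conjugation with distance-decaying
    unidirectional transfer, auxotrophy selection, and hitchhiking sweeps so
    the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
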