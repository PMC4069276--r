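Package: halfsibs
Title: Phasing, Pedigree Reconstruction and Recombination Detection in
    Half-Sib Families
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-array genotype data on paternal half-sib
    family groups, common in livestock genomics. Counts opposing
    homozygotes between all pairs of individuals, reconstructs half-sib
    pedigrees by recursive hierarchical clustering with four separation
    criteria, assigns parentage, builds paternal-origin block structures,
    detects and counts recombination events, flags putative map errors,
    infers (phases) the haplotypes of an un-genotyped sire from its
    offspring, phases the offspring, and imputes offspring paternal
    haplotypes from low- to high-density panels. Includes a
    gamete-dropping simulator with full truth records so every stage can
    be validated without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
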