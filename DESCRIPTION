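Package: evoscreen
Title: Expression Screening and Molecular-Evolutionary Analysis of Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A candidate-gene triage and molecular-evolution toolkit. Screens
    differential-expression result tables by inverse-normal Z-score with
    Benjamini-Hochberg correction and cross-dataset overlap; performs
    McDonald-Kreitman tests from Nei-Gojobori style synonymous/nonsynonymous
    counts with an exact two-sided Fisher test and neutrality index; fits
    Goldman-Yang codon site models (M0, M1a, M2a, M3, M7, M8) with F3x4
    frequencies on a fixed tree by maximum likelihood, with likelihood-ratio
    tests and naive empirical Bayes identification of positively selected
    sites; computes running dN/dS tracks along a protein with peptide-region
    summaries and variant overlays; consolidates SIFT and PolyPhen-2 calls
    into tolerance summaries; and generates fully synthetic study inputs
    (codon alignments evolved under site-class omega, polymorphism/divergence
    count tables, SNP tables, expression tables) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
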