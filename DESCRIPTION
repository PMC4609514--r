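Package: tbpaffinity
Title: TATA-Binding Protein Promoter Affinity and Regulatory SNP Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the equilibrium binding affinity, -ln(KD), of the
    TATA-binding protein (TBP) for core-promoter DNA via a three-step
    thermodynamic approximation (nonspecific sliding along DNA, stopping at a
    TATA-box scored by a position-weight matrix, and DNA-helix bending),
    scans promoter windows centered at positions -70 to -20 relative to the
    transcription start site, attaches a perturbation-based uncertainty from
    all 78 single-base substitutions of the best window, and compares
    ancestral versus minor promoter alleles with a Z-statistic to call a
    predicted expression excess, deficiency, or no change for regulatory
    SNPs. Includes FASTA and variant-table input, batch analysis, synthetic
    promoter fixtures, and independent brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
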