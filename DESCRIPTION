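Package: sorfpep
Title: Proteogenomic Database Construction, PSM Rescoring and
    sORF-Encoded Peptide Discovery for Endogenous Peptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for enzyme-free (endogenous) peptidomics with a
    proteogenomics search space. Builds concatenated target-decoy search
    databases from a reference proteome, predicted small open reading
    frame (sORF) sets and contaminants, with per-stop-codon selection,
    exon-overlap filtering, deduplication and Venn-cell composition
    reporting. Computes peptidoform monoisotopic masses and b/y fragment
    ions with the common endogenous-peptide modifications (C-terminal
    amidation, methionine oxidation, pyro-glutamate), matches peaks at a
    fixed tolerance, and derives predicted-versus-observed spectral
    correlation and retention-time features. Rescored peptide-spectrum
    matches are validated by target-decoy q-values and a semi-supervised
    cross-validated linear rescorer, then summarised into peptide groups,
    annotated against a neuropeptide reference, and screened for
    non-coding sORF-encoded peptide candidates with uniqueness and
    coverage checks. A seed-deterministic simulator generates synthetic
    proteomes, spectra and PSM score mixtures with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
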