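Package: mhctyper
Title: Multilocus MHC Genotyping from Tagged Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genotyping complex multilocus MHC class I
    systems from tagged 454-style amplicon reads. Provides a synthetic read
    simulator with known ground truth (diploid multilocus genotypes, PCR point
    mutations, PCR chimeras, pyrosequencing errors), dual-MID demultiplexing
    with degenerate-primer matching, a five-step artefact-removal procedure
    based on per-amplicon variant frequencies and chimera/single-mutation
    explainability, an exact equiprobable-multinomial model of the minimum
    read depth needed for reliable genotyping, functional annotation of
    validated alleles (stop codons, pseudogene assignment, nucleotide
    diversity), Nei-Gojobari dN/dS with Jukes-Cantor correction and a
    codon-based Z-test of selection over site masks, physicochemical
    supertype clustering of binding-site residues (z-descriptor encoding,
    K-means with BIC model selection, DAPC), and duplicate-based
    repeatability and minimum-locus-number summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    MASS,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
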