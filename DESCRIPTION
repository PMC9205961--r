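Package: vetkey
Title: Genetically Vetted Hybrid Identification and Plumage Keys for
    Mallard-Like Ducks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to disentangle shared ancestry from recent hybridization
    in incipient mallard-like duck taxa (Mexican duck vs. wild and domestic
    mallards) from reduced-representation SNP panels and mtDNA control-region
    sequences. Implements the PLINK-style SNP filtering chain (minor-allele
    frequency, per-SNP missingness, pairwise linkage-disequilibrium pruning),
    principal components analysis, maximum-likelihood admixture-proportion
    estimation with bootstrap standard errors and cross-validated selection of
    the number of clusters, a rarity-weighted co-ancestry matrix with
    sibling-group detection, two rule-based hybrid callers (assignment
    threshold and co-ancestry) with a concordance report, nucleotide diversity
    and Hudson-form PhiST per genomic partition, mtDNA haplotype collapsing
    and haplogroup assignment, and construction, application and evaluation of
    genetically vetted ordinal plumage-score keys per sex-age cohort. A
    synthetic-data generator emulating the study design (drifted populations,
    F1/backcross hybrids, sibling groups, two mtDNA haplogroups, and
    cohort-conditional plumage-trait distributions) makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
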