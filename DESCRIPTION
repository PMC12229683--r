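Package: ysnpdb
Title: Phylogeny-Aware Harmonization and Analysis of Y-SNP Haplogroup Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing Y-chromosomal SNP haplogroup data of
    heterogeneous resolution against a reference haplogroup tree. Loads and
    validates haplogroup trees with SNP synonyms and equivalence classes,
    ingests per-sample genotype records from tab-separated caller output or
    manual submission tables, answers haplogroup and paraphyletic exclusion
    queries, computes per-region haplogroup frequencies with phylogenetic
    membership inference, interpolates frequencies for regions without data
    by inverse-distance weighting over great-circle border distances, and
    runs a comparative population pipeline: reduced SNP panel construction,
    Nei gene diversity, pairwise FST by analysis of molecular variance on
    lineage frequencies, and classical multidimensional scaling. Includes a
    deterministic synthetic-data generator emulating mixed genotyping panels
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
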