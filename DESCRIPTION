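Package: quadbind
Title: Amino-Acid Composition and RG-Rich Motif Analysis of
    G-Quadruplex Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Composition profiling and motif analysis of G-quadruplex
    binding protein sets. Computes amino-acid and k-mer composition
    matrices with boxplot statistics and relative enrichment against
    reference proteome frequencies; tests per-residue enrichment versus
    background protein sets with a bootstrap resampling test and
    Bonferroni correction; attaches multiscale-bootstrap approximately
    unbiased (AU) and plain bootstrap (BP) support values to
    average-linkage dendrograms of protein composition; scans protein
    sets with peptide-derived position weight matrices using exact
    p-values from dynamic programming and Benjamini-Hochberg q-values;
    discovers shared ungapped motifs with a ZOOPS Gibbs site sampler;
    and ranks candidate quadruplex binders by motif match. Includes a
    synthetic-data generator (background sequences from residue
    frequency vectors, composition-shifted groups, planted motifs at
    controlled substitution rates) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
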