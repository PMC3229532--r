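Package: dupModes
Title: Classification of Gene Duplication Modes and Divergence Analysis of
    Duplicate Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies duplicate gene pairs into six mechanistic modes
    (whole-genome, tandem, proximal, retrotransposed, DNA-based transposed
    and dispersed duplication) from genome annotation, protein homology
    hits and syntenic anchor pairs. Quantifies expression divergence
    between paralogs within a species and expression conservation of
    orthologs across species via comparison of co-expression patterns.
    Estimates coding sequence divergence (Ka, Ks) by the Nei-Gojobori
    pathway method on codon alignments and noncoding divergence by
    Jukes-Cantor distances, extracts promoter regions, calls promoter
    methylation from probe tracks, and provides the enrichment, power and
    regression machinery used to relate duplication mode to expression and
    sequence divergence. Includes a synthetic-corpus generator that plants
    duplications of every mode with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, GeneExpression, Phylogenetics, Annotation, Software
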