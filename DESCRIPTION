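Package: pbmscan
Title: Transcription Factor Binding Affinity Models from Protein Binding
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives quantitative k-mer binding affinity models for
    transcription factors from protein binding microarray (PBM) probe
    intensities: spatial detrending, seed-and-wobble position weight
    matrix estimation, per-7-mer z-score tables and energy-normalized
    logo matrices. Predicts per-base binding affinity across strand-aware
    promoter windows, writes genome browser tracks (bedGraph), designs
    composition-preserving scrambled-site promoter variants and re-scores
    them, and compares predictions against ChIP-seq coverage with a
    circular-shift permutation test. Also provides the companion
    transcriptomic post-processing: threshold filtering of differential
    expression tables, Ward hierarchical clustering with per-cluster
    summary statistics, and three-way Venn set analysis. Includes seeded
    synthetic-data generators with known ground truth for every input.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
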