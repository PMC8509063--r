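Package: memtol
Title: Mutational Tolerance and Packing Analysis of Transmembrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled saturation-mutagenesis screens of
    membrane peptides and the structural context of the mutated residues.
    Implements degenerate-codon library bookkeeping (SNS-style schemes),
    variant calling from pooled amplicon reads, the pooled-count enrichment
    statistic F with incorrect sequence-phenotype assignment (ISPA)
    filtering, per-position tolerance and criticality summaries, and
    compensatory-mutation detection.  Companion sequence and structure
    analyses cover reference-based conservation and correlated-mutation
    indices over family alignments, residue contact graphs at a distance
    cutoff with maximal-clique packing profiles and size-versus-order
    fits, and Hausdorff-distance comparison of hydrophobic contact
    geometries minimised by simulated annealing.  Seeded synthetic-data
    generators (read pools with planted deleterious and compensatory
    substitutions, alignments with planted correlated pairs, ideal helices
    and compact globular decoys) provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
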