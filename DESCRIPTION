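Package: giga
Title: Gene Tree Inference in the Genomic Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agglomerative inference of gene family trees from a raw pairwise
    sequence-distance matrix under hard constraints from a known species tree
    and genome gene content. Gene trees are assembled from orthologous
    subtrees (groups of genes related only by speciation) joined by founding
    copy events (gene duplications) that are dated relative to speciation
    events by deletion parsimony, with significance-tested revision of
    duplication dates, on-the-fly quarantine and later re-insertion of
    sequence fragments, approximate ancestral sequence reconstruction,
    Jukes-Cantor corrected branch lengths, and evaluation metrics (normalized
    Robinson-Foulds distance and ortholog-pair difference). Includes a gene
    family simulator with known event histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
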