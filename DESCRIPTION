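Package: spliceCBE
Title: Design and Analysis of Cytosine Base Editor Knockout Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing single-guide RNAs that knock out genes with
    cytosine base editors (CBEs), either by disrupting canonical splice donor
    (GT) and acceptor (AG) dinucleotides or by installing premature stop
    codons, together with the quantitative machinery used to evaluate
    multiplex editing experiments. Guide discovery scans the antisense strand
    around every splice junction of a transcript model for protospacers whose
    editing window covers the splice-critical cytosine, enumerates and
    classifies every joint C-to-T/A/G conversion outcome, and scores and
    ranks candidates. Companion functions enumerate directed translocation
    junctions for multiplex panels, decompose per-cell knockout calls into
    combination fractions, estimate translocation frequencies from droplet
    digital PCR counts under the Poisson partition model, normalize PD-1 flow
    cytometry fractions, and rank RNA off-target candidates by expression. A
    deterministic synthetic-locus generator provides fully annotated test
    loci with planted splice sites and editable codons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, Sequencing, FunctionalGenomics, GuideDesign
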