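Package: endocut
Title: Endoribonuclease Cleavage-Site Mapping from 5'-End RNA-Seq and
    Codon-Based Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps toxin endoribonuclease (tRNase) cleavage sites from 5'-end
    RNA-seq alignments using a local peak score and a toxin/control cleavage
    ratio with a fixed calling threshold, derives degenerate cleavage-site
    consensus motifs and scans tRNA/mRNA sequences for them (including
    anticodon-loop localisation from dot-bracket structures), and predicts
    translation-level targets of tRNA-Ser loss from serine-codon composition
    of zone-specific transcripts (threshold gene lists, Venn intersections,
    replicon bias).  Ships a synthetic-data generator (genomes, annotations,
    aligned reads with planted cleavage signatures, zone-expression tables
    with known ground truth) so the whole pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
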