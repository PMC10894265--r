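Package: casTandem
Title: Design and Analysis of Overlapping Cas9/Cas12a Target Sites
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing Cas9 and Cas12a mutagenesis at shared
    genomic loci. Finds sites where a Cas12a target (5' TTTV PAM, 23-nt
    spacer) and a Cas9 target (3' NGG PAM, 20-nt spacer) overlap within
    coding sequences, enumerates candidate off-target sites genome-wide
    with bounded mismatches and at most a one-nucleotide DNA or RNA bulge,
    quantifies editing outcomes from paired-end amplicon sequencing reads
    with a control-aware indel caller, computes indel size spectra,
    frameshift fractions and off-target adjudication statistics, designs
    Golden-Gate spacer oligonucleotides, and simulates every input with
    known ground truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
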