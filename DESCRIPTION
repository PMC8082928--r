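Package: svlr
Title: Structural Variant Discovery from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls germline and somatic structural variants (deletions,
    insertions, inversions, tandem duplications, translocations and virus
    integrations) from long-read alignments by clustering CIGAR and
    split-read signatures, builds majority-vote consensus sequences at
    breakpoints, classifies inserted sequences by repeat content, infers
    breakpoint repair mechanisms (NAHR, alt-EJ, NHEJ, FoSTeS/MMBIR) and
    ancestral insertion/deletion events from cross-species breakpoint
    distances, and benchmarks callsets by breakpoint distance. Ships a
    self-contained long-read simulator (repeat-bearing references, spiked
    SVs, Nanopore-like error profiles, truth alignments) for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
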