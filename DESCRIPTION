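Package: uorfscan
Title: Detection, Classification, and Translation-Probability Analysis of
    Upstream Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of upstream open reading frames (uORFs) in
    annotated transcripts of GC-rich genomes. Parses genome FASTA plus GFF3
    annotation into spliced transcript models, detects and classifies uORFs
    (in-frame extensions, out-of-frame overlappers, and 5'UTR-contained ORFs)
    and 3'UTR dORFs, builds randomized and mutagenized control sequence sets,
    derives a Kozak-style position-information matrix from reference initiator
    contexts, decomposes score and length distributions by least-squares
    mixture projection, tests ortholog-proteome conservation of N-terminal
    extensions with scrambled controls, and assigns each in-frame uORF a
    Bayesian translation probability from its Kozak score and length, with ROC
    evaluation. Includes a synthetic genome generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    rtracklayer,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
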