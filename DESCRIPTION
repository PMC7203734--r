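Package: nascentTx
Title: Primary Transcript Annotation from Nascent Run-On Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers data-driven transcription start sites (TSS) and
    transcription termination sites (TTS) of primary transcripts from
    strand-specific nascent run-on sequencing coverage (PRO-seq/GRO-seq),
    annotates de novo transcription units with gene identifiers by interval
    overlap, and quantifies genes (read counts, promoter-proximal pause
    indices) under the refined coordinates. TSSs are chosen among annotated
    first-exon 5' ends by downstream read density; TTSs are located by
    binning a 3' search region, fitting a smoothing spline to binned counts,
    finding the terminal read-density peak and the point where the curve
    decays toward zero. Includes a synthetic PRO-seq coverage generator with
    ground-truth TSS/TTS/TU structure for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
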