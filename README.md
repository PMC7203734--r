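# nascentTx

Data-driven primary transcript annotation from nascent run-on sequencing
(PRO-seq / GRO-seq) coverage.

## The problem

Run-on assays report where RNA polymerase sits, at base resolution and
strand-specifically. Conventional mRNA annotations describe the *mature*
transcript, not the *primary* one: the dominant initiation site frequently is
not the most upstream annotated start, and polymerase keeps transcribing for
kilobases beyond the polyadenylation and cleavage site before it terminates.
Quantifying run-on data against mRNA coordinates therefore mis-assigns reads,
dilutes differential-expression signal, and corrupts promoter-proximal pause
statistics. nascentTx infers transcription start sites (TSS) and
transcription termination sites (TTS) of primary transcripts directly from
the coverage, uses them to annotate *de novo* transcription units (TUs, e.g.
groHMM calls) with gene identifiers, and quantifies genes (counts, pause
indices) under the refined coordinates. It is aimed at anyone analysing
PRO-seq/GRO-seq libraries with standard bedGraph/bigWig coverage tracks and
BED annotations.

## The method

For a gene with candidate first-exon 5' ends `t1 … tk` (one per isoform,
deduplicated), the inferred TSS is

    TSS = argmax_i  reads[t_i, t_i + W)        (strand-aware, W = 500 b)

— the candidate whose downstream window captures the promoter-proximal pause
peak. For the TTS, a search region spanning the 3'-most fraction (default
0.2) of the gene plus a fixed extension (default 10 kb) past the annotated
end is cut into `B`-base bins (default 200 b), a cubic smoothing spline
`f(x)` is fitted to the binned counts, the terminal peak `p = argmax f` is
located, and the TTS is the 5' edge of the first bin `j > p` with

    f(j) <= tau * f(p)                          (tau = 0.1)

— the point where polymerase density has decayed toward zero. TUs are then
assigned gene names by overlap with the inferred coordinates (a TU spanning
`k` genes is split at midpoints between gene boundaries into `k` tiling
segments; TUs overlapping nothing are `UNANNOTATED`). The pause index of a
gene is `density[TSS, TSS+50) / density[TSS+50, TTS)`.

A synthetic PRO-seq generator (`synthetic_gene_specs()`,
`generate_coverage()`) plants pause peaks, Poisson gene bodies, readthrough,
termination peaks and decay with a full ground-truth table, so every claim
the package makes is testable without external data.

## Worked example

```r
library(nascentTx)

specs <- synthetic_gene_specs(4, noise_rate = 0.01)   # 4 genes, 1% background
gen   <- generate_coverage(specs, seed = 42)

genes <- largest_interval(gen$isoforms)       # conventional envelope coords
cands <- collect_first_exons(gen$isoforms)    # candidate TSSs per gene
tss   <- infer_tss(cands, gen$track, W = 500)
tts   <- infer_tts(genes, gen$track, downstream_extension = 5000)
inferred <- inferred_coordinates(tss, tts)
inferred[, c("gene_id", "start", "end", "strand", "tss", "tts", "tts_status")]
#>    gene_id start    end strand    tss   tts  tts_status
#> 1 gene_001 14700  26760      +  14700 26760 decay_found
#> 2 gene_002 40640  52700      -  52699 40640 decay_found
#> 3 gene_003 68099  80159      +  68099 80159 decay_found
#> 4 gene_004 94039 106099      - 106098 94039 decay_found
```

Each planted TSS is recovered exactly (`gen$truth$true_tss` is 14700, 52699,
68099, 106098) and every TTS lands within a bin of the planted termination
point (e.g. 26760 inferred vs 26700 true for `gene_001`) — well beyond the
annotated 3' end at 24700: the readthrough the method is built to capture.
Refined coordinates sharpen pausing quantification:

```r
compare_pause_indices(inferred, genes, gen$track)
#>    gene_id pause_index_a pause_index_b log2_ratio improved
#> 1 gene_001          5.67          0.00        Inf     TRUE
#> 2 gene_002          5.22          0.02       7.97     TRUE
#> ...
```

Under the largest-interval coordinates the pause window sits ~700 b upstream
of the real initiation site and sees background only (index ~0); under the
inferred TSS it captures the pause peak (index ~5).

The same steps run from a shell via the thin wrapper
`inst/cli/pta` (`pta synth`, `pta tss`, `pta tts`, `pta annotate-tus`,
`pta counts`, `pta pause`, `pta pipeline`), and `run_pipeline()` executes
prep → TSS → TTS → TU annotation → quantification in one call, writing
BED/TSV artifacts with provenance headers.

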