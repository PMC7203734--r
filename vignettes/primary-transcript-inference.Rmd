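---
title: "Inferring primary transcript coordinates from run-on coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring primary transcript coordinates from run-on coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentTx)
```

## Motivation and model

Nascent run-on sequencing (PRO-seq, GRO-seq) measures engaged RNA polymerase
at base resolution, strand-specifically. Two well-described features of that
signal make conventional mRNA annotations a poor quantification frame:

* **Promoter-proximal pausing.** Polymerase accumulates a few tens of bases
  downstream of the *active* initiation site, producing the sharpest peak in
  the coverage. Genes typically have several annotated isoform starts; only
  one (or a few) is engaged in a given condition.
* **Readthrough termination.** Polymerase transcribes kilobases past the
  polyadenylation and cleavage site; density stays near body level, often
  rises where transcription rates attenuate near the end of the transcription
  unit, and then decays toward background.

nascentTx treats both features as *signals to fit* rather than nuisances.
The package does not discover novel TSSs — initiation sites not present in
the curated annotation are the province of dedicated 5' assays (PRO-cap,
Start-seq, 5' GRO-seq). It chooses among annotated candidates, and infers the
termination point de novo because annotations carry no usable TTS at all.

### TSS selection

All first exons of a gene's isoforms are collapsed to their distinct 5' ends
(`collect_first_exons()`). Each candidate `t` is scored by the read count in
the downstream window `[t, t + W)` (strand-aware; the window includes the
candidate base). The candidate with the maximal count wins. Since `W` is
constant within a gene, the raw count ranks candidates exactly as a density
would; counts keep the contract integer-valued. Ties break toward the most
5' candidate — the conservative choice, keeping the transcript long — and a
gene whose candidates all score zero is reported with its most 5' candidate
and a `zero_signal` flag rather than dropped, so the caller decides.

`W` defaults to 500 b. That is the scale at which pause peaks sit (tens of
bases downstream of initiation) with margin for dispersed pausing; it is also
the radius used by `distance_to_peak()`, the diagnostic that measures how
far a coordinate sits from the nearest local coverage maximum.

### TTS inference

The search region spans the 3'-most `gene_fraction` of the gene (default
0.2) plus `downstream_extension` bases (default 10,000) past the most distal
annotated end — mammalian readthrough is routinely several kb. The region is
tiled with `floor(len/B)` whole bins from its 5' end (`B` = 200 b default;
the trailing partial bin is discarded rather than scored on a different
denominator). A cubic smoothing spline is fitted to the per-bin counts and
evaluated at the bins; the terminal peak is the *global* maximum of the
curve, and the TTS is the 5' edge of the first downstream bin whose fitted
value drops to `tau` (default 0.1) of the peak height.

Numerical choices worth stating:

* **Smoothness.** `knots_per_kb` (default 1) sets the knot grid;
  the penalty is chosen by generalized cross-validation unless `spar` is
  given. GCV behaves well when bins carry Poisson-scale noise around a
  smooth trend — the situation the region is designed to contain. On
  degenerate profiles (a single spiked bin among zeros) GCV can oversmooth;
  for constructed or very sparse signals pass `spar` explicitly (near 0 for
  a near-interpolating fit). Constant and linear profiles are reproduced
  exactly for any penalty (they lie in the spline's null space), which pins
  the fit's behavior in tests.
* **Background floor.** A peak is only called if the curve's maximum exceeds
  `0.5 * max(1, mean of the 5'-most three bin counts)` — the leading bins
  sit inside the gene body, so this floor suppresses "peaks" in regions that
  are silent relative to the gene itself. No peak ⇒ the annotated end is
  returned (`no_peak_gene_end`).
* **Relative decay threshold.** "Decays toward zero" cannot be an absolute
  test: noisy counts never reach zero, and scaling the library must not move
  the call. `tau * f(peak)` is scale-free. If the curve never crosses the
  threshold before the region ends, the region end is returned
  (`no_decay_region_end`) — the honest statement that termination lies
  beyond the searched window. Decreasing `tau` can only move the TTS 3'-ward
  on a fixed curve (tested as a monotonicity property).
* **Bin-edge convention.** The TTS is reported at the *5' edge* of the decay
  bin: within the bin's ±`B` ambiguity this is the conservative (shortest
  transcript) choice, and it makes the plus/minus conventions exact mirror
  images. All tie-breaks in the package (argmax ties, midpoint rounding in
  TU splitting) are written strand-aware for the same reason; mirroring
  every input mirrors every output bit-for-bit.
* **Neighbour contamination.** A downstream same-strand gene inside the
  extension window contributes signal that can postpone the decay crossing.
  `truncate_at_next_gene = TRUE` clips the search region at the next gene's
  start; it is off by default because truncation also hides genuine long
  readthrough into a neighbour.

### TU annotation

Unsupervised TU callers (groHMM and kin) find transcribed blocks without
names; merged neighbours are their classic failure mode. `annotate_tus()`
assigns gene identifiers by overlap with the inferred coordinates. A gene
qualifies when the TU covers at least `min_frac` (default 0.5) *of the
gene* — fraction-of-gene, not fraction-of-TU, so a long TU spanning a short
gene still inherits its name. A TU spanning several qualifying genes is cut
at the midpoints between consecutive genes' facing boundaries (rounded
toward the TU's 5' end, keeping the rule strand-symmetric); the segments
tile the parent exactly, by construction and by test. TUs overlapping no
qualifying gene stay intact as `UNANNOTATED`. Where inferred genes
themselves overlap, the midpoint cut splits the contested span; should finer
arbitration matter, the per-gene overlap fractions are in the output for the
caller to re-cut.

### Quantification

`count_matrix()` counts reads per gene per sample under any coordinate set —
largest-interval, inferred, or annotated-TU — producing the plain table that
external differential-expression machinery consumes; no test statistic is
computed here. `pause_index()` is density in `[TSS, TSS + pause_len)` over
density in the remaining body (defaults `pause_len` = 50 b, `body_gap` = 0;
both explicit parameters, since pause-window conventions vary across labs).
A zero-read body yields an *undefined* index, flagged, never `Inf`. The
directional claim — refined coordinates sharpen pausing quantification — is
exactly what `compare_pause_indices()` measures.

## What the synthetic generator emulates

`synthetic_gene_specs()` + `generate_coverage()` render, per gene: a
deterministic pause peak (default 200 reads over 5 b, 40 b downstream of the
true TSS), a Poisson gene body (mean 1 read/base), body-level readthrough
(500 b) past the annotated end, a termination peak (100 reads over 50 b),
a linear decay of the Poisson mean to zero over 1,500 b (the decay end *is*
the true TTS — linearity makes the truth well defined), and optional uniform
Poisson background. Candidate TSSs flank the true one at 700 b spacing
(beyond the scoring window), upstream ones in silent DNA, downstream ones
inside the body, so exactly one candidate window contains the pause peak.
Genes alternate strands with 14 kb gaps, so a 10 kb search extension never
touches a same-strand neighbour.

These values are the regime the method targets — mammalian-scale genes,
pausing an order of magnitude above body density, termination zones of one
to a few kb — and the generator's contract is the stated means plus
determinism under a seed, not a particular noise family. What it does *not*
emulate: mappability gaps, GC bias, bidirectionally transcribed enhancers
near 3' ends, overlapping same-strand genes, intronic dropout. Passing
recovery tests here therefore demonstrates the estimator's correctness and
calibration on clean signal, not robustness to every artifact of real
libraries; on real data the fallback statuses and the rejection report are
the instruments for spotting where the model assumptions fail.

Test and validation problem sizes (100 genes per recovery experiment, 50
seeds for the TU partition property, 5 kb extensions on ~10 kb genes) were
chosen so the full suite exercises every code path on a laptop in about a
minute; recovery rates are flat in these sizes.

## Degenerate inputs and edge behavior

* Regions shorter than four bins cannot support a spline: the gene is
  reported `unprocessable` with the annotated end, never silently dropped.
* All-zero regions short-circuit to `no_peak_gene_end` (a constant is its
  own smoother; no peak above floor).
* Chromosomes present in the annotation but absent from the track count as
  zero with one warning — scaffold mismatches are routine.
* Minus-strand bedGraph values may arrive negative (the browser convention);
  magnitudes are taken on read, and `write_coverage()` re-emits them
  negative.
* Isoforms of one gene on different chromosomes or strands make the gene's
  identity ambiguous; it is dropped with a warning rather than repaired.

## Known limitations

* The TTS search takes the global fitted maximum; closely spaced multiple
  termination peaks are summarized by the tallest one. Multi-peak selection
  would be a natural extension.
* Window counts are not normalized by first-exon length; candidates are
  compared on fixed `W` regardless of exon size.
* Convergent gene pairs whose readthrough zones overlap on opposite strands
  are handled correctly (strand separation), but tandem same-strand pairs
  closer than the extension require `truncate_at_next_gene` or a smaller
  extension.
* The expression filter defaults (25 reads, 1 read/kb) are deliberately
  permissive knobs, not calibrated thresholds; set them per library depth.
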