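# Shared helpers: a brute-force dense-array coverage oracle, random step
# fixtures, and coordinate-mirroring utilities for strand-symmetry checks.

# Random disjoint step intervals on one chromosome: breakpoints are drawn,
# every other segment carries a positive value.
rand_steps <- function(L, n, max_val = 10) {
  bp <- sort(sample.int(L - 1, min(2 * n, L - 2)))
  start <- bp[c(TRUE, FALSE)]
  end <- bp[c(FALSE, TRUE)]
  keep <- end > start
  data.frame(start = start[keep], end = end[keep],
             value = sample.int(max_val, sum(keep), replace = TRUE))
}

# Dense per-base array from step intervals (0-based half-open in, 1-based
# dense vector out).
dense_from_steps <- function(steps, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(steps)))
    v[(steps$start[i] + 1):steps$end[i]] <- v[(steps$start[i] + 1):steps$end[i]] + steps$value[i]
  v
}

dense_sum <- function(dense, start, end) {
  s1 <- max(start + 1, 1); e1 <- min(end, length(dense))
  if (s1 > e1) 0 else sum(dense[s1:e1])
}

# CoverageTrack from explicit dense vectors (named lists per strand).
track_from_dense <- function(plus = list(), minus = list()) {
  coverage_track(lapply(plus, S4Vectors::Rle), lapply(minus, S4Vectors::Rle))
}

# Write step intervals as a bedGraph file; sign applies to the values.
write_steps_bg <- function(steps, chrom, path, sign = 1) {
  writeLines(sprintf("%s\t%d\t%d\t%d", chrom, steps$start, steps$end,
                     sign * steps$value), path)
  path
}

# --- mirroring utilities (reflection p -> L - p on boundaries, strand swap) ---

mirror_track <- function(track, L) {
  flip <- function(rle) {
    pad <- L - length(rle)
    if (pad > 0) rle <- c(rle, S4Vectors::Rle(0, pad))
    rev(rle)
  }
  coverage_track(lapply(track$cov[["-"]], flip), lapply(track$cov[["+"]], flip))
}

mirror_intervals <- function(df, L) {
  out <- df
  out$start <- L - df$end
  out$end <- L - df$start
  out$strand <- ifelse(df$strand == "+", "-", "+")
  out
}

mirror_pos <- function(p, L) L - 1 - p  # base positions (not boundaries)

# Standard synthetic scene used by several tests: specs + coverage + truth
# aligned by gene_id.
synth_scene <- function(n_genes, noise_rate = 0, seed = 1, ...) {
  specs <- synthetic_gene_specs(n_genes, noise_rate = noise_rate, ...)
  gen <- generate_coverage(specs, seed = seed)
  gen$truth <- gen$truth[order(gen$truth$gene_id), ]
  gen$genes <- largest_interval(gen$isoforms)
  gen$candidates <- collect_first_exons(gen$isoforms)
  gen
}
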