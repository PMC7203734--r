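# TSS inference. The dominant TSS of a gene is the candidate first-exon 5'
# end whose downstream window carries maximal read density; the window is
# meant to capture the promoter-proximal pause peak, the sharpest feature of
# run-on coverage. With a fixed-length window the raw count ranks candidates
# identically to density, so counts are compared directly.

#' Reads in the downstream window of a candidate TSS
#'
#' Counts reads in the `W`-base window beginning at the candidate initiating
#' base and extending downstream: `[tss, tss + W)` on plus, `(tss - W, tss]`
#' on minus (both include the candidate base itself).
#'
#' @param track A [coverage_track()].
#' @param chrom,tss,strand Candidate position(s); vectors are recycled.
#' @param W Window length in bases (> 0), default 500.
#' @return Numeric vector of read counts.
#' @export
candidate_window_count <- function(track, chrom, tss, strand, W = 500) {
  stopifnot(W > 0)
  tss <- as.numeric(tss)
  start <- ifelse(strand == "+", tss, pmax(tss - W + 1, 0))
  end <- ifelse(strand == "+", tss + W, tss + 1)
  region_counts(track, chrom, start, end, strand)
}

#' Infer the dominant TSS of each gene
#'
#' For every gene, scores each candidate first-exon 5' end by
#' [candidate_window_count()] and returns the candidate with the maximal
#' count. Ties are broken toward the most 5' candidate (conservative toward
#' longer transcripts); if no candidate window contains any signal the most
#' 5' candidate is returned with `zero_signal = TRUE`.
#'
#' @param candidates Candidate table from [collect_first_exons()] (rows in
#'   5'-to-3' order within gene; any order is accepted, the result is
#'   order-invariant).
#' @param track A [coverage_track()].
#' @param W Downstream window length in bases, default 500.
#' @return data.frame with one row per gene: `gene_id, chrom, strand, tss,
#'   window_count, n_candidates, tie_broken, zero_signal`.
#' @export
infer_tss <- function(candidates, track, W = 500) {
  if (!nrow(candidates)) stop("empty candidate set")
  stopifnot(W > 0)
  cnt <- candidate_window_count(track, candidates$chrom, candidates$tss,
                                candidates$strand, W)
  sp <- split(seq_len(nrow(candidates)), candidates$gene_id)
  rows <- lapply(names(sp), function(g) {
    i <- sp[[g]]
    # 5'->3' order within the gene, independent of input order
    key <- if (candidates$strand[i[1]] == "+") candidates$tss[i] else -candidates$tss[i]
    i <- i[order(key)]
    ci <- cnt[i]
    best <- which.max(ci)  # first index among ties = most 5'
    data.frame(gene_id = g, chrom = candidates$chrom[i[1]],
               strand = candidates$strand[i[1]], tss = candidates$tss[i][best],
               window_count = ci[best], n_candidates = length(i),
               tie_broken = sum(ci == ci[best]) > 1L,
               zero_signal = all(ci == 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Signed distance from a TSS to the nearest read peak
#'
#' Scans `max_dist` bases on either side of the position for local coverage
#' maxima (a base whose count is positive and at least its two neighbours) and
#' returns the signed strand-aware distance to the nearest one (downstream
#' positive). Used to evaluate how tightly inferred TSSs sit against the
#' promoter-proximal pause peak compared with conventional annotations.
#'
#' @param track A [coverage_track()].
#' @param chrom,tss,strand Position(s); vectors recycled.
#' @param max_dist Scan radius in bases, default 500.
#' @return Numeric vector of signed distances; ties by smallest absolute
#'   distance, then downstream; `NA` where no peak exists within the window.
#' @export
distance_to_peak <- function(track, chrom, tss, strand, max_dist = 500) {
  stopifnot(max_dist > 0)
  n <- max(length(chrom), length(tss), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  tss <- rep_len(as.numeric(tss), n)
  strand <- rep_len(as.character(strand), n)
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    rle <- track$cov[[strand[k]]][[chrom[k]]]
    if (is.null(rle)) next
    lo <- tss[k] - max_dist
    hi <- tss[k] + max_dist
    # per-base counts over [lo, hi], padded with zeros beyond track bounds
    v <- numeric(hi - lo + 1)
    s1 <- max(lo + 1, 1); e1 <- min(hi + 1, length(rle))
    if (s1 <= e1)
      v[(s1 - lo):(e1 - lo)] <- as.numeric(IRanges::Views(rle, s1, e1)[[1]])
    if (all(v == 0)) next
    left <- c(0, v[-length(v)]); right <- c(v[-1], 0)
    peaks <- which(v > 0 & v >= left & v >= right)
    if (!length(peaks)) next
    pos <- lo + peaks - 1
    d <- if (strand[k] == "+") pos - tss[k] else tss[k] - pos  # downstream positive
    ord <- order(abs(d), -sign(d))  # nearest, ties downstream first
    out[k] <- d[ord[1]]
  }
  out
}
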