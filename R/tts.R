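# TTS inference. Polymerase density rises near gene ends (transcription rates
# attenuate there) and run-on signal extends past the polyadenylation site.
# The TTS is found by: (1) defining a search region from a 3' fraction of the
# gene to a fixed extension past the annotated end; (2) binning the region and
# counting reads per bin; (3) fitting a cubic smoothing spline to the binned
# counts; (4) taking the terminal peak of the fitted curve; (5) walking 3'
# from the peak to the first bin where the curve has decayed to a fraction
# tau of the peak height. The decay bin's 5' edge is reported as the TTS
# (conservative within the bin's +/- B ambiguity).

#' Define the 3' search region of a gene
#'
#' The region spans the 3'-most `gene_fraction` of the gene plus
#' `downstream_extension` bases past the annotated 3' end (strand-aware),
#' optionally clipped at chromosome bounds.
#'
#' @param genes Largest-interval table (`gene_id, chrom, start, end, strand`).
#' @param gene_fraction Fraction of gene length included upstream of the gene
#'   end, in (0, 1]; default 0.2.
#' @param downstream_extension Bases beyond the most distal annotated end;
#'   default 10000.
#' @param chrom_lens Optional named vector of chromosome lengths for clipping.
#' @return data.frame `gene_id, chrom, start, end, strand, gene_end` where
#'   `[start, end)` is the search region and `gene_end` the annotated 3' end
#'   coordinate (the `end` of plus-strand genes, the `start` of minus-strand
#'   genes).
#' @export
define_search_region <- function(genes, gene_fraction = 0.2,
                                 downstream_extension = 10000,
                                 chrom_lens = NULL) {
  stopifnot(gene_fraction > 0, gene_fraction <= 1, downstream_extension >= 0)
  len <- genes$end - genes$start
  flen <- round(gene_fraction * len)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$end - flen, genes$start - downstream_extension)
  end <- ifelse(plus, genes$end + downstream_extension, genes$start + flen)
  start <- pmax(start, 0)
  if (!is.null(chrom_lens)) {
    cl <- chrom_lens[genes$chrom]
    end <- ifelse(is.na(cl), end, pmin(end, cl))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = end, strand = genes$strand,
             gene_end = ifelse(plus, genes$end, genes$start),
             stringsAsFactors = FALSE)
}

#' Bin the search region and count reads
#'
#' Tiles `floor(length / B)` whole bins of width `B` from the region's 5' end
#' (the trailing partial bin is discarded) and counts reads per bin.
#'
#' @param region One row of [define_search_region()] output (or an equivalent
#'   one-row data.frame with `chrom, start, end, strand`).
#' @param track A [coverage_track()].
#' @param B Bin width in bases (>= 1), default 200.
#' @return An object of class `binned_signal`: a list with `gene_id, chrom,
#'   strand, B`, `bin_start` (genomic left edges, in 5'-to-3' order),
#'   `counts`, and `fitted`/`peak_index`/`decay_index` slots filled by the
#'   later steps. `NULL` (with attribute-free) is never returned; fewer than 4
#'   whole bins is an error condition flagged via class `unprocessable_region`
#'   in [infer_tts()] — calling `bin_signal()` directly then stops.
#' @export
bin_signal <- function(region, track, B = 200) {
  stopifnot(B >= 1, nrow(region) == 1L)
  n <- floor((region$end - region$start) / B)
  if (n < 4) stop("search region shorter than 4 bins; gene unprocessable at B = ", B)
  if (region$strand == "+") {
    left <- region$start + (seq_len(n) - 1) * B  # 5'->3' left to right
  } else {
    left <- region$end - seq_len(n) * B          # 5'->3' right to left
  }
  counts <- region_counts(track, region$chrom, left, left + B, region$strand)
  structure(list(gene_id = region$gene_id %||% NA_character_, chrom = region$chrom,
                 strand = region$strand, B = B, bin_start = left, counts = counts,
                 fitted = NULL, peak_index = NULL, decay_index = NULL),
            class = "binned_signal")
}

#' Fit a smoothing spline to binned counts
#'
#' Fits a cubic smoothing spline (penalized least squares) to the per-bin
#' counts and evaluates it at the bin centers. Smoothness is controlled by the
#' knot density; with enough knots and a vanishing penalty the fit approaches
#' the counts themselves. Constant and linear profiles are reproduced exactly
#' (they are in the spline's null space).
#'
#' @param binned A `binned_signal` from [bin_signal()].
#' @param knots_per_kb Knot density along the region, default 1 knot per kb.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; when `NULL` (default) the smoothing level is
#'   chosen by generalized cross-validation.
#' @return The `binned_signal` with `fitted` filled in (all zeros if the
#'   counts are all zero).
#' @export
fit_smooth_curve <- function(binned, knots_per_kb = 1, spar = NULL) {
  stopifnot(inherits(binned, "binned_signal"))
  y <- binned$counts
  n <- length(y)
  if (n < 4) stop("need at least 4 bins to fit a spline")
  if (all(y == y[1])) {  # constant (incl. all-zero): its own smoother
    binned$fitted <- y
    return(binned)
  }
  nknots <- max(4L, min(n, as.integer(round(n * binned$B / 1000 * knots_per_kb))))
  x <- seq_len(n)
  fit <- if (is.null(spar)) {
    stats::smooth.spline(x, y, nknots = nknots, cv = FALSE)
  } else {
    stats::smooth.spline(x, y, nknots = nknots, spar = spar)
  }
  binned$fitted <- stats::predict(fit, x)$y
  binned
}

#' Locate the terminal read-density peak
#'
#' The peak is the global maximum of the fitted curve, provided it clears a
#' background floor of `0.5 * max(1, mean of the 5'-most 3 bin counts)`; the
#' floor prevents calling peaks in silent regions. Ties go to the most 5' bin.
#'
#' @param binned A `binned_signal` with `fitted` present.
#' @return The `binned_signal` with `peak_index` set (integer, 5'-to-3' bin
#'   index) or left `NULL` when no peak clears the floor.
#' @export
locate_peak <- function(binned) {
  stopifnot(inherits(binned, "binned_signal"), !is.null(binned$fitted))
  floor_ <- 0.5 * max(1, mean(utils::head(binned$counts, 3)))
  m <- max(binned$fitted)
  binned$peak_index <- if (m > floor_) which.max(binned$fitted) else NULL
  binned
}

#' Locate the decay point 3' of the peak
#'
#' Walks 3' from the peak and returns the first bin whose fitted value has
#' fallen to at most `tau` times the peak height — the point where the curve
#' has decayed "toward zero". A relative threshold is used because noisy
#' counts never reach exactly zero.
#'
#' @param binned A `binned_signal` with `peak_index` set.
#' @param tau Decay fraction in (0, 1), default 0.1.
#' @return The `binned_signal` with `decay_index` set, or left `NULL` when
#'   the curve never decays below the threshold before the region end.
#' @export
locate_decay <- function(binned, tau = 0.1) {
  stopifnot(inherits(binned, "binned_signal"), !is.null(binned$peak_index),
            tau > 0, tau < 1)
  p <- binned$peak_index
  thr <- tau * binned$fitted[p]
  j <- which(binned$fitted <= thr & seq_along(binned$fitted) > p)
  binned$decay_index <- if (length(j)) min(j) else NULL
  binned
}

#' Infer transcription termination sites
#'
#' Composes [define_search_region()], [bin_signal()], [fit_smooth_curve()],
#' [locate_peak()] and [locate_decay()] for every gene and maps the decay bin
#' back to genomic coordinates.
#'
#' @param genes Largest-interval table (typically the expressed subset).
#' @param track A [coverage_track()].
#' @param gene_fraction,downstream_extension See [define_search_region()].
#' @param B Bin width in bases, default 200.
#' @param tau Decay fraction, default 0.1.
#' @param knots_per_kb,spar See [fit_smooth_curve()].
#' @param chrom_lens Optional chromosome lengths for clipping.
#' @param truncate_at_next_gene When `TRUE`, each gene's search region is
#'   clipped at the start of the nearest same-strand downstream gene, limiting
#'   contamination by a neighbour's signal. Off by default.
#' @return data.frame with one row per gene: `gene_id, chrom, strand, tts,
#'   status, peak_coord, n_bins`. `tts` is a boundary coordinate: the inferred
#'   primary transcript is `[tss, tts)` on plus and `[tts, tss + 1)` on minus.
#'   `status` is one of `decay_found` (peak and decay located),
#'   `no_decay_region_end` (peak but no decay before the region end; `tts` =
#'   region 3' end), `no_peak_gene_end` (no peak above background; `tts` =
#'   annotated gene end) or `unprocessable` (region shorter than 4 bins;
#'   `tts` = annotated gene end).
#' @export
infer_tts <- function(genes, track, gene_fraction = 0.2,
                      downstream_extension = 10000, B = 200, tau = 0.1,
                      knots_per_kb = 1, spar = NULL, chrom_lens = NULL,
                      truncate_at_next_gene = FALSE) {
  regions <- define_search_region(genes, gene_fraction, downstream_extension,
                                  chrom_lens)
  if (truncate_at_next_gene) regions <- .truncate_regions(regions, genes)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, , drop = FALSE]
    plus <- r$strand == "+"
    fallback <- function(tts, status, peak_coord = NA_real_, n_bins = NA_integer_)
      data.frame(gene_id = r$gene_id, chrom = r$chrom, strand = r$strand,
                 tts = tts, status = status, peak_coord = peak_coord,
                 n_bins = n_bins, stringsAsFactors = FALSE)
    if (floor((r$end - r$start) / B) < 4)
      return(fallback(r$gene_end, "unprocessable"))
    bs <- bin_signal(r, track, B)
    bs <- locate_peak(fit_smooth_curve(bs, knots_per_kb, spar))
    if (is.null(bs$peak_index))
      return(fallback(r$gene_end, "no_peak_gene_end", n_bins = length(bs$counts)))
    peak_coord <- bs$bin_start[bs$peak_index] + if (plus) 0 else bs$B  # 5' edge of peak bin
    bs <- locate_decay(bs, tau)
    if (is.null(bs$decay_index))
      return(fallback(if (plus) r$end else r$start, "no_decay_region_end",
                      peak_coord, length(bs$counts)))
    # TTS = 5' edge of the decay bin (conservative within +/- B)
    tts <- bs$bin_start[bs$decay_index] + if (plus) 0 else bs$B
    fallback(tts, "decay_found", peak_coord, length(bs$counts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Clip each search region at the nearest same-strand downstream gene start.
.truncate_regions <- function(regions, genes) {
  for (i in seq_len(nrow(regions))) {
    same <- genes$chrom == regions$chrom[i] & genes$strand == regions$strand[i] &
      genes$gene_id != regions$gene_id[i]
    if (!any(same)) next
    if (regions$strand[i] == "+") {
      nxt <- genes$start[same][genes$start[same] >= regions$gene_end[i]]
      if (length(nxt)) regions$end[i] <- min(regions$end[i], min(nxt))
    } else {
      nxt <- genes$end[same][genes$end[same] <= regions$gene_end[i]]
      if (length(nxt)) regions$start[i] <- max(regions$start[i], max(nxt))
    }
  }
  regions
}

#' Assemble inferred primary-transcript coordinates
#'
#' Joins [infer_tss()] and [infer_tts()] results into a BED-ready gene table:
#' `[tss, tts)` on plus, `[tts, tss + 1)` on minus.
#'
#' @param tss_calls Output of [infer_tss()].
#' @param tts_calls Output of [infer_tts()].
#' @param keep_fallbacks Keep genes whose TTS came from a fallback status
#'   (default `TRUE`); when `FALSE` only `decay_found` genes are returned.
#' @return data.frame `gene_id, chrom, start, end, strand, tss, tts,
#'   tss_zero_signal, tts_status`.
#' @export
inferred_coordinates <- function(tss_calls, tts_calls, keep_fallbacks = TRUE) {
  m <- merge(tss_calls[c("gene_id", "chrom", "strand", "tss", "zero_signal")],
             tts_calls[c("gene_id", "tts", "status")], by = "gene_id")
  plus <- m$strand == "+"
  out <- data.frame(gene_id = m$gene_id, chrom = m$chrom,
                    start = ifelse(plus, m$tss, m$tts),
                    end = ifelse(plus, m$tts, m$tss + 1),
                    strand = m$strand, tss = m$tss, tts = m$tts,
                    tss_zero_signal = m$zero_signal, tts_status = m$status,
                    stringsAsFactors = FALSE)
  if (!keep_fallbacks) out <- out[out$tts_status == "decay_found", , drop = FALSE]
  bad <- out$end <= out$start
  if (any(bad)) {
    warning("dropped gene(s) whose inferred TTS precedes the TSS: ",
            paste(out$gene_id[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
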