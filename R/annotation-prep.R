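# Collapse isoform-level annotations into per-gene structures: the "largest
# interval" envelope (most upstream start to most downstream end across
# isoforms) and the set of candidate first-exon 5' ends used for TSS
# inference.

#' Per-gene largest interval
#'
#' Collapses isoforms to one envelope interval per gene: the most upstream
#' start coordinate to the most downstream end coordinate across all isoforms
#' of the gene. This is the conventional annotation the data-driven
#' coordinates are compared against, and the region used for expression
#' filtering and TTS search.
#'
#' @param isoforms Isoform table as returned by [read_bed()] with an isoform
#'   dialect: columns `chrom, start, end, strand, gene_id` (and usually
#'   `transcript_id, fe_start, fe_end`).
#' @return data.frame with one row per gene: `gene_id, chrom, start, end,
#'   strand`, ordered by `gene_id`. Genes whose isoforms disagree on
#'   chromosome or strand are dropped with a warning (ambiguous identity).
#' @export
largest_interval <- function(isoforms) {
  sp <- split(seq_len(nrow(isoforms)), isoforms$gene_id)
  rows <- lapply(names(sp), function(g) {
    i <- sp[[g]]
    if (length(unique(isoforms$chrom[i])) > 1L || length(unique(isoforms$strand[i])) > 1L)
      return(NULL)
    data.frame(gene_id = g, chrom = isoforms$chrom[i[1]],
               start = min(isoforms$start[i]), end = max(isoforms$end[i]),
               strand = isoforms$strand[i[1]], stringsAsFactors = FALSE)
  })
  dropped <- names(sp)[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("dropped gene(s) with isoforms on multiple chromosomes/strands: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(), start = numeric(),
                      end = numeric(), strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Candidate TSS set: first exons of every isoform
#'
#' Collects each gene's first exons, deduplicated by 5'-end coordinate and
#' sorted 5' to 3' (strand-aware). Each distinct 5' end is a candidate TSS for
#' [infer_tss()].
#'
#' @inheritParams largest_interval
#' @return data.frame of candidates: `gene_id, chrom, strand, fe_start,
#'   fe_end, tss` where `tss` is the 0-based coordinate of the initiating base
#'   (`fe_start` on plus, `fe_end - 1` on minus). Within each gene rows are in
#'   5'-to-3' order.
#' @export
collect_first_exons <- function(isoforms) {
  df <- data.frame(gene_id = isoforms$gene_id, chrom = isoforms$chrom,
                   strand = isoforms$strand, fe_start = isoforms$fe_start,
                   fe_end = isoforms$fe_end, stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$fe_start, df$fe_end - 1)
  df <- df[!duplicated(df[c("gene_id", "tss")]), , drop = FALSE]
  # 5'->3': ascending tss on plus, descending on minus
  key <- ifelse(df$strand == "+", df$tss, -df$tss)
  df <- df[order(df$gene_id, key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter genes by expression level
#'
#' TSS/TTS inference is meaningless on unexpressed genes: without signal, the
#' window argmax and the binned spline see only noise. Genes are retained when
#' their largest interval carries at least `min_count` reads and at least
#' `min_density` reads per kilobase.
#'
#' @param genes Largest-interval table from [largest_interval()].
#' @param track A [coverage_track()].
#' @param min_count Minimum reads in the gene interval (default 25).
#' @param min_density Minimum reads per kb (default 1).
#' @return List with `genes` (retained rows, plus `count` and `density`
#'   columns) and `rejected` (the complement, same columns, with a `reason`).
#' @export
filter_expressed <- function(genes, track, min_count = 25, min_density = 1) {
  stopifnot(min_count >= 0, min_density >= 0)
  cnt <- region_counts(track, genes$chrom, genes$start, genes$end, genes$strand)
  dens <- cnt / ((genes$end - genes$start) / 1000)
  genes$count <- cnt
  genes$density <- dens
  keep <- cnt >= min_count & dens >= min_density
  rejected <- genes[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(rejected$count < min_count, "low_count", "low_density")
  } else rejected$reason <- character(0)
  list(genes = genes[keep, , drop = FALSE], rejected = rejected)
}
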