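# Assignment of gene identifiers to de novo transcription units (TUs), e.g.
# groHMM calls. A TU overlapping one gene inherits its name; a TU spanning
# several genes is split at the midpoints between consecutive gene boundaries
# so that the segments tile the parent exactly; a TU overlapping no gene is
# marked unannotated. Qualification uses the fraction of the *gene* covered,
# so a long TU spanning a short gene still inherits the gene's name.

#' Constant used as the gene identifier of intergenic TUs
#' @export
UNANNOTATED <- "UNANNOTATED"

#' Reciprocal overlap fractions of two intervals
#'
#' @param tu,gene data.frames (recycled row-wise) with columns
#'   `chrom, start, end, strand`.
#' @return data.frame with `frac_tu` (fraction of the TU covered by the gene)
#'   and `frac_gene` (fraction of the gene covered by the TU); both 0 when the
#'   intervals are on different chromosomes or strands, or disjoint.
#' @export
overlap_fraction <- function(tu, gene) {
  n <- max(nrow(tu), nrow(gene))
  ix <- function(df) df[rep_len(seq_len(nrow(df)), n), , drop = FALSE]
  tu <- ix(tu); gene <- ix(gene)
  inter <- pmax(0, pmin(tu$end, gene$end) - pmax(tu$start, gene$start))
  inter[tu$chrom != gene$chrom | tu$strand != gene$strand] <- 0
  data.frame(frac_tu = inter / (tu$end - tu$start),
             frac_gene = inter / (gene$end - gene$start))
}

#' Annotate de novo transcription units with gene identifiers
#'
#' Assigns each TU the identifier(s) of the gene(s) it overlaps:
#' \itemize{
#'   \item one qualifying gene: the whole TU carries that `gene_id`
#'     (`origin = "whole_tu"`);
#'   \item `k >= 2` qualifying genes: the TU is split into `k` segments at the
#'     midpoints between consecutive genes' facing boundaries
#'     (`origin = "split_segment"`); the midpoint is rounded toward the TU's
#'     5' end so the rule is strand-symmetric;
#'   \item no qualifying gene: the TU is kept intact with
#'     `gene_id = UNANNOTATED` (`origin = "intergenic"`).
#' }
#' A gene qualifies when the TU covers at least `min_frac` of the gene's
#' length. When a gene is covered by several TUs, each carrying record gets a
#' distinct `name` (`gene_id` suffixed with the segment ordinal in 5'-to-3'
#' order); `gene_id` itself stays unsuffixed.
#'
#' @param tus data.frame of TU calls: `chrom, start, end, strand` and an `id`
#'   (or `name`) column with the caller's identifier.
#' @param genes data.frame of (inferred) gene coordinates:
#'   `gene_id, chrom, start, end, strand`.
#' @param min_frac Qualification threshold on the fraction of the gene
#'   covered, default 0.5.
#' @param snap_to_gene When `TRUE`, whole-TU records adopt the gene's own
#'   boundaries (the combined annotation then carries the inferred TSS/TTS).
#'   Off by default.
#' @return data.frame `chrom, start, end, strand, gene_id, name, origin,
#'   overlap_fraction_of_gene, parent_tu`, ordered by (chrom, start, end).
#'   Segments of one parent TU tile it exactly; zero-length segments are
#'   dropped.
#' @export
annotate_tus <- function(tus, genes, min_frac = 0.5, snap_to_gene = FALSE) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  idcol <- intersect(c("id", "name", "source_id"), names(tus))[1]
  tu_id <- if (is.na(idcol)) paste0("tu_", seq_len(nrow(tus))) else as.character(tus[[idcol]])
  rows <- vector("list", nrow(tus))
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, , drop = FALSE]
    cand <- genes[genes$chrom == tu$chrom & genes$strand == tu$strand, , drop = FALSE]
    if (nrow(cand)) {
      inter <- pmax(0, pmin(tu$end, cand$end) - pmax(tu$start, cand$start))
      frac_gene <- inter / (cand$end - cand$start)
      cand <- cand[frac_gene >= min_frac & inter > 0, , drop = FALSE]
      frac_gene <- frac_gene[frac_gene >= min_frac & inter > 0]
    } else frac_gene <- numeric(0)
    if (!nrow(cand)) {
      rows[[i]] <- data.frame(chrom = tu$chrom, start = tu$start, end = tu$end,
                              strand = tu$strand, gene_id = UNANNOTATED,
                              origin = "intergenic", overlap_fraction_of_gene = 0,
                              parent_tu = tu_id[i], stringsAsFactors = FALSE)
      next
    }
    ord <- order(cand$start, cand$end, cand$gene_id)
    cand <- cand[ord, , drop = FALSE]
    frac_gene <- frac_gene[ord]
    k <- nrow(cand)
    if (k == 1L) {
      seg_start <- if (snap_to_gene) max(tu$start, cand$start) else tu$start
      seg_end <- if (snap_to_gene) min(tu$end, cand$end) else tu$end
      rows[[i]] <- data.frame(chrom = tu$chrom, start = seg_start, end = seg_end,
                              strand = tu$strand, gene_id = cand$gene_id,
                              origin = "whole_tu",
                              overlap_fraction_of_gene = frac_gene,
                              parent_tu = tu_id[i], stringsAsFactors = FALSE)
      next
    }
    # cut between consecutive genes at the midpoint of their facing
    # boundaries; round toward the TU's 5' end so mirroring the inputs
    # mirrors the cuts exactly
    mids <- (cand$end[-k] + cand$start[-1]) / 2
    cuts <- if (tu$strand == "+") floor(mids) else ceiling(mids)
    cuts <- cummax(pmin(pmax(cuts, tu$start), tu$end))  # keep within TU, monotone
    bounds <- c(tu$start, cuts, tu$end)
    seg <- data.frame(chrom = tu$chrom, start = bounds[-length(bounds)],
                      end = bounds[-1], strand = tu$strand,
                      gene_id = cand$gene_id, origin = "split_segment",
                      overlap_fraction_of_gene = frac_gene,
                      parent_tu = tu_id[i], stringsAsFactors = FALSE)
    rows[[i]] <- seg[seg$end > seg$start, , drop = FALSE]  # drop degenerate cuts
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), gene_id = character(), name = character(),
                      origin = character(), overlap_fraction_of_gene = numeric(),
                      parent_tu = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  # distinct names when a gene is carried by several records: 5'->3' ordinals
  out$name <- out$gene_id
  annotated <- out$gene_id != UNANNOTATED
  dup <- annotated & out$gene_id %in% out$gene_id[annotated][duplicated(out$gene_id[annotated])]
  if (any(dup)) {
    for (g in unique(out$gene_id[dup])) {
      j <- which(out$gene_id == g)
      j <- j[order(if (out$strand[j[1]] == "+") out$start[j] else -out$end[j])]
      out$name[j] <- paste0(g, "_", seq_along(j))
    }
  }
  out <- out[c("chrom", "start", "end", "strand", "gene_id", "name", "origin",
               "overlap_fraction_of_gene", "parent_tu")]
  rownames(out) <- NULL
  out
}
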