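# BED input/output. All coordinates are kept 0-based half-open throughout the
# package; strand is mandatory because every inference step is strand-aware.

#' Read gene/isoform annotations from BED
#'
#' @param path Path to a BED file.
#' @param dialect One of:
#'   \describe{
#'     \item{`"bed6"`}{plain 6-column BED; returns an interval table with an
#'       `id` column taken from the name field.}
#'     \item{`"bed12"`}{12-column BED with exon blocks; the first exon is
#'       extracted strand-aware (the block with the largest end coordinate for
#'       minus-strand transcripts). The name field supplies identifiers: either
#'       `gene_id|transcript_id` or a bare `gene_id` (transcript ids are then
#'       generated).}
#'     \item{`"isoform_table"`}{BED6 plus two appended columns `gene_id`,
#'       `transcript_id`. No exon structure: the first exon is taken to be the
#'       transcript interval itself, so candidate TSSs are transcript 5' ends.}
#'   }
#' @return For `"bed6"`, a data.frame with columns
#'   `chrom, start, end, id, score, strand`. For the isoform dialects, a
#'   data.frame of isoform records with columns
#'   `chrom, start, end, strand, gene_id, transcript_id, fe_start, fe_end`
#'   (`fe_*` is the first exon, whose 5' end always equals the transcript
#'   5' end).
#' @export
read_bed <- function(path, dialect = c("bed6", "bed12", "isoform_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") return(.read_bed12(path))
  ncol_min <- if (dialect == "bed6") 6L else 8L
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = paste0("V", seq_len(ncol_min)),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character", "character",
                                         "character", "character")[seq_len(ncol_min)])
  if (nrow(df) && !all(df$V6 %in% c("+", "-")))
    stop("missing or invalid strand in '", path, "': every downstream step is strand-aware")
  if (dialect == "bed6") {
    return(data.frame(chrom = df$V1, start = df$V2, end = df$V3, id = df$V4,
                      score = df$V5, strand = df$V6, stringsAsFactors = FALSE))
  }
  data.frame(chrom = df$V1, start = df$V2, end = df$V3, strand = df$V6,
             gene_id = df$V7, transcript_id = df$V8,
             fe_start = df$V2, fe_end = df$V3, stringsAsFactors = FALSE)
}

.read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*"))
    stop("missing strand in '", path, "': every downstream step is strand-aware")
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("'", path, "' has no exon blocks; use dialect='bed6' or 'isoform_table'")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("tx_", seq_along(gr))
  has_bar <- grepl("|", nm, fixed = TRUE)
  gene_id <- ifelse(has_bar, sub("\\|.*$", "", nm), nm)
  transcript_id <- ifelse(has_bar, sub("^[^|]*\\|", "", nm),
                          paste0(nm, ".", stats::ave(seq_along(nm), nm, FUN = seq_along)))
  tx_start <- GenomicRanges::start(gr) - 1L  # back to 0-based
  tx_end <- GenomicRanges::end(gr)
  fe_start <- fe_end <- numeric(length(gr))
  for (i in seq_along(gr)) {
    b <- blocks[[i]]  # 1-based, relative to the transcript start
    if (st[i] == "+") {
      j <- which.min(IRanges::start(b))
    } else {
      j <- which.max(IRanges::end(b))
    }
    fe_start[i] <- tx_start[i] + IRanges::start(b)[j] - 1L
    fe_end[i] <- tx_start[i] + IRanges::end(b)[j]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = tx_start, end = tx_end, strand = st,
             gene_id = gene_id, transcript_id = transcript_id,
             fe_start = fe_start, fe_end = fe_end, stringsAsFactors = FALSE)
}

#' Write intervals to a BED6 file
#'
#' Records are written tab-separated with 0-based half-open coordinates in a
#' deterministic order (chrom, start, end, id), so identical inputs yield
#' byte-identical files.
#'
#' @param records data.frame with columns `chrom, start, end, strand` and an
#'   identifier column (`id`, `gene_id` or `name`, first found wins). A
#'   `score` column is used if present, else 0.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines
#'   written before the records (used for provenance).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(records, path, header = NULL) {
  idcol <- intersect(c("id", "gene_id", "name"), names(records))[1]
  id <- if (is.na(idcol)) rep(".", nrow(records)) else as.character(records[[idcol]])
  score <- if ("score" %in% names(records)) records$score else rep(0, nrow(records))
  df <- data.frame(chrom = records$chrom, start = records$start, end = records$end,
                   id = id, score = score, strand = records$strand,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$id), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, as.integer(df$start),
                       as.integer(df$end), df$id,
                       format(df$score, scientific = FALSE, trim = TRUE), df$strand), con)
  invisible(path)
}

#' Write a data.frame as a TSV report
#'
#' @param df data.frame.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
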