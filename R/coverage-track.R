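# Strand-specific base-resolution coverage, stored as run-length encoded
# vectors (one Rle per chromosome per strand). Zero runs are implicit; minus-
# strand values that arrive negative in source files are stored as magnitudes.

#' Build a coverage track from per-strand signal
#'
#' A `CoverageTrack` holds strand-specific, per-chromosome read coverage as
#' run-length encoded vectors, plus per-strand totals. It is the signal
#' container every inference step queries.
#'
#' @param plus,minus `GRanges` with a numeric `score` column (one object per
#'   strand), or a named `RleList`-like list of per-chromosome run-length
#'   vectors. Negative scores are interpreted as magnitudes (the common
#'   minus-strand bedGraph convention).
#' @return An object of class `CoverageTrack` with elements `cov` (list with
#'   components `"+"` and `"-"`, each a named list of `Rle`) and `totals`
#'   (named numeric, total reads per strand).
#' @seealso [read_coverage()] to build one from bedGraph/bigWig files,
#'   [region_counts()] to query it.
#' @export
coverage_track <- function(plus, minus) {
  cov <- list("+" = .strand_cov(plus), "-" = .strand_cov(minus))
  totals <- vapply(cov, function(x) sum(vapply(x, function(r) sum(as.numeric(r)), 0)), 0)
  names(totals) <- names(cov)
  structure(list(cov = cov, totals = totals), class = "CoverageTrack")
}

.strand_cov <- function(x) {
  if (is.null(x)) return(list())
  if (methods::is(x, "GRanges")) {
    if (!"score" %in% names(S4Vectors::mcols(x)))
      stop("coverage GRanges must carry a 'score' column")
    if (!IRanges::isDisjoint(x))
      stop("overlapping intervals within one strand's coverage")
    cv <- GenomicRanges::coverage(x, weight = abs(S4Vectors::mcols(x)$score))
    return(as.list(cv))
  }
  # named list of Rle (or coercible numeric vectors)
  lapply(x, function(r) if (inherits(r, "Rle")) r else S4Vectors::Rle(abs(as.numeric(r))))
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack\n")
  for (s in c("+", "-")) {
    cat(sprintf("  strand %s: %d chromosome(s), %.0f reads\n",
                s, length(x$cov[[s]]), x$totals[[s]]))
  }
  invisible(x)
}

#' Read strand-specific coverage from bedGraph or bigWig files
#'
#' Reads one signal file per strand and expands interval values so that any
#' base-level query is answerable. Minus-strand files commonly store negative
#' values; magnitudes are taken on read.
#'
#' @param plus_path,minus_path Paths to the plus- and minus-strand signal
#'   files. Either may be `NULL` (empty strand).
#' @param format `"bedgraph"` (4-column text) or `"bigwig"`.
#' @return A [coverage_track()] object.
#' @details Intervals within one file must be non-overlapping per chromosome;
#'   overlap is a format error (a bedGraph is a step function, not a read
#'   pileup). Parsing is delegated to \pkg{rtracklayer}.
#' @examples
#' p <- tempfile(fileext = ".bg")
#' writeLines("chr1\t10\t13\t2", p)
#' tr <- read_coverage(p, NULL)
#' region_counts(tr, "chr1", 10, 13, "+")  # 6
#' @export
read_coverage <- function(plus_path, minus_path, format = c("bedgraph", "bigwig")) {
  format <- match.arg(format)
  fmt <- if (format == "bedgraph") "bedGraph" else "BigWig"
  rd <- function(path, strand) {
    if (is.null(path)) return(NULL)
    gr <- tryCatch(rtracklayer::import(path, format = fmt),
                   error = function(e) stop(sprintf("failed to parse %s-strand %s file '%s': %s",
                                                    strand, format, path, conditionMessage(e)),
                                            call. = FALSE))
    if (!IRanges::isDisjoint(gr))
      stop(sprintf("overlapping intervals in %s-strand file '%s'", strand, path), call. = FALSE)
    gr
  }
  coverage_track(rd(plus_path, "plus"), rd(minus_path, "minus"))
}

#' Count reads in genomic regions
#'
#' Sums per-base coverage over `[start, end)` on the given strand. The
#' workhorse primitive behind window scoring, signal binning and gene
#' counting.
#'
#' @param track A [coverage_track()].
#' @param chrom,start,end,strand Vectors (recycled to a common length)
#'   describing query intervals, 0-based half-open, strand in `"+"`/`"-"`.
#' @return Numeric vector of read counts, 0 for regions without signal.
#'   Querying a chromosome absent from the track returns 0 with a warning
#'   (annotation and track chromosome sets commonly differ).
#' @export
region_counts <- function(track, chrom, start, end, strand) {
  stopifnot(inherits(track, "CoverageTrack"))
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(start < 0) || any(end < start)) stop("invalid interval: need 0 <= start <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  out <- numeric(n)
  missing_chroms <- character(0)
  for (s in unique(strand)) {
    cvs <- track$cov[[s]]
    idx_s <- which(strand == s)
    for (ch in unique(chrom[idx_s])) {
      idx <- idx_s[chrom[idx_s] == ch]
      rle <- cvs[[ch]]
      if (is.null(rle)) {
        missing_chroms <- c(missing_chroms, ch)
        next
      }
      L <- length(rle)
      s1 <- pmax(start[idx] + 1, 1)  # to 1-based inclusive
      e1 <- pmin(end[idx], L)
      ok <- which(s1 <= e1)
      if (length(ok)) {
        v <- IRanges::Views(rle, start = s1[ok], end = e1[ok])
        out[idx[ok]] <- IRanges::viewSums(v)
      }
    }
  }
  if (length(missing_chroms))
    warning("chromosome(s) absent from coverage track, counted as 0: ",
            paste(unique(missing_chroms), collapse = ", "))
  out
}

#' Total mapped reads per strand
#' @param track A [coverage_track()].
#' @return Named numeric vector with components `"+"` and `"-"`.
#' @export
total_reads <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  track$totals
}

#' Write a coverage track to bedGraph files
#'
#' Emits one 4-column bedGraph per strand. Minus-strand values are written
#' negated, the common PRO-seq browser convention. Output is deterministic
#' (sorted by chromosome then start) so identical tracks produce
#' byte-identical files.
#'
#' @param track A [coverage_track()].
#' @param plus_path,minus_path Output paths; `NULL` skips a strand.
#' @return Invisibly, the paths written.
#' @export
write_coverage <- function(track, plus_path, minus_path) {
  stopifnot(inherits(track, "CoverageTrack"))
  wr <- function(cvs, path, sign) {
    if (is.null(path)) return(NULL)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (ch in sort(names(cvs))) {
      rle <- cvs[[ch]]
      rl <- S4Vectors::runLength(rle); rv <- S4Vectors::runValue(rle)
      ends <- cumsum(rl); starts <- ends - rl  # 0-based half-open
      keep <- rv != 0
      if (!any(keep)) next
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(sign * rv[keep], scientific = FALSE, trim = TRUE)), con)
    }
    path
  }
  invisible(c(wr(track$cov[["+"]], plus_path, 1),
              wr(track$cov[["-"]], minus_path, -1)))
}
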