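# One-shot pipeline: annotation prep -> TSS -> TTS -> (optional) TU
# annotation -> counts and pause indices, with every artifact written to an
# output directory under a provenance header. The command-line wrapper in
# inst/cli/ is a thin shell over these functions; running them from R gives
# identical results.

#' Default pipeline parameters
#'
#' @return Named list of every tunable parameter with its default: TSS window
#'   `W`; expression filter `min_count`/`min_density`; TTS search
#'   `gene_fraction`, `downstream_extension`, bin width `B`, decay fraction
#'   `tau`, `knots_per_kb`, `spar`, `truncate_at_next_gene`; TU annotation
#'   `min_frac`, `snap_to_gene`; pause windows `pause_len`, `body_gap`.
#' @export
default_params <- function() {
  list(W = 500, min_count = 25, min_density = 1,
       gene_fraction = 0.2, downstream_extension = 10000, B = 200, tau = 0.1,
       knots_per_kb = 1, spar = NULL, truncate_at_next_gene = FALSE,
       min_frac = 0.5, snap_to_gene = FALSE,
       pause_len = 50, body_gap = 0)
}

.validate_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg, call. = FALSE)
  chk(p$W > 0, "W must be > 0")
  chk(p$min_count >= 0 && p$min_density >= 0, "expression thresholds must be >= 0")
  chk(p$gene_fraction > 0 && p$gene_fraction <= 1, "gene_fraction must be in (0, 1]")
  chk(p$downstream_extension >= 0, "downstream_extension must be >= 0")
  chk(p$B >= 1, "B must be >= 1")
  chk(p$tau > 0 && p$tau < 1, "tau must be in (0, 1)")
  chk(p$min_frac >= 0 && p$min_frac <= 1, "min_frac must be in [0, 1]")
  chk(p$pause_len > 0 && p$body_gap >= 0, "pause windows must be positive")
  invisible(p)
}

.provenance <- function(params, inputs) {
  ver <- as.character(utils::packageVersion("nascentTx"))
  sums <- vapply(inputs, function(f)
    if (is.null(f) || !file.exists(f)) "-" else unname(tools::md5sum(f)), "")
  pstr <- paste(names(params),
                vapply(params, function(x) paste(format(x), collapse = ","), ""),
                sep = "=", collapse = " ")
  c(sprintf("# nascentTx %s", ver),
    sprintf("# params: %s", pstr),
    sprintf("# input %s md5=%s", names(sums), sums))
}

#' Run the full annotation pipeline
#'
#' Executes, in order: isoform collapse ([largest_interval()],
#' [collect_first_exons()]), expression filtering ([filter_expressed()]), TSS
#' inference ([infer_tss()]), TTS inference ([infer_tts()]), optional TU
#' annotation ([annotate_tus()]), and quantification ([count_matrix()],
#' [pause_index()] under both largest-interval and inferred coordinates).
#' Every output file starts with a provenance header (package version,
#' parameters, input checksums); given identical inputs and parameters the
#' outputs are byte-identical across runs.
#'
#' @param isoforms Isoform table (from [read_bed()] with an isoform dialect,
#'   or a path to such a file).
#' @param plus_path,minus_path Per-strand coverage files (bedGraph), or a
#'   prebuilt [coverage_track()] passed as `track`.
#' @param out_dir Output directory; created if needed.
#' @param track Optional [coverage_track()]; when supplied the coverage files
#'   are not read.
#' @param tus Optional TU table (or BED6 path); when supplied TU annotation
#'   runs, otherwise it is skipped.
#' @param params Named list overriding entries of [default_params()].
#' @return Invisibly, a list with every intermediate table (`genes`,
#'   `candidates`, `expressed`, `rejected`, `tss`, `tts`, `inferred`,
#'   `annotated_tus`, `counts`, `pause`) and the vector of paths written.
#' @export
run_pipeline <- function(isoforms, plus_path = NULL, minus_path = NULL,
                         out_dir, track = NULL, tus = NULL, params = list()) {
  p <- utils::modifyList(default_params(), params, keep.null = TRUE)
  .validate_params(p)
  stage <- "setup"
  res <- tryCatch({
    if (is.character(isoforms)) isoforms <- read_bed(isoforms, "isoform_table")
    if (is.null(track)) {
      stage <- "read_coverage"
      track <- read_coverage(plus_path, minus_path)
    }
    if (is.character(tus)) tus <- read_bed(tus, "bed6")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .provenance(p, list(plus = plus_path, minus = minus_path))

    stage <- "prep"
    genes <- largest_interval(isoforms)
    candidates <- collect_first_exons(isoforms)
    flt <- filter_expressed(genes, track, p$min_count, p$min_density)
    expressed <- flt$genes

    stage <- "tss"
    cand_expr <- candidates[candidates$gene_id %in% expressed$gene_id, , drop = FALSE]
    tss <- infer_tss(cand_expr, track, W = p$W)

    stage <- "tts"
    tts <- infer_tts(expressed, track, gene_fraction = p$gene_fraction,
                     downstream_extension = p$downstream_extension, B = p$B,
                     tau = p$tau, knots_per_kb = p$knots_per_kb, spar = p$spar,
                     truncate_at_next_gene = p$truncate_at_next_gene)
    inferred <- inferred_coordinates(tss, tts)

    annotated <- NULL
    if (!is.null(tus)) {
      stage <- "annotate_tus"
      annotated <- annotate_tus(tus, inferred, min_frac = p$min_frac,
                                snap_to_gene = p$snap_to_gene)
    }

    stage <- "quantify"
    counts <- count_matrix(inferred, list(sample = track))
    pause <- compare_pause_indices(inferred, expressed[expressed$gene_id %in% inferred$gene_id, ],
                                   track, pause_len = p$pause_len,
                                   body_gap = p$body_gap)

    stage <- "write"
    write_bed(expressed, file.path(out_dir, "largest_interval.bed"), hdr)
    write_tsv_report(flt$rejected, file.path(out_dir, "rejected_genes.tsv"), hdr)
    write_bed(data.frame(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1,
                         gene_id = tss$gene_id, strand = tss$strand),
              file.path(out_dir, "tss.bed"), hdr)
    write_tsv_report(tss, file.path(out_dir, "tss_report.tsv"), hdr)
    write_tsv_report(tts, file.path(out_dir, "tts_report.tsv"), hdr)
    write_bed(inferred, file.path(out_dir, "inferred_genes.bed"), hdr)
    if (!is.null(annotated)) {
      write_bed(annotated[c("chrom", "start", "end", "strand", "name")],
                file.path(out_dir, "annotated_tus.bed"), hdr)
      write_tsv_report(annotated, file.path(out_dir, "annotated_tus.tsv"), hdr)
    }
    cnt_df <- data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_report(cnt_df, file.path(out_dir, "counts.tsv"), hdr)
    write_tsv_report(pause, file.path(out_dir, "pause_indices.tsv"), hdr)

    list(genes = genes, candidates = candidates, expressed = expressed,
         rejected = flt$rejected, tss = tss, tts = tts, inferred = inferred,
         annotated_tus = annotated, counts = counts, pause = pause,
         out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
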