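# Synthetic PRO-seq coverage with ground truth. Each gene contributes the
# signal features the inference relies on: a sharp promoter-proximal pause
# peak a few tens of bases downstream of the true TSS, uniform Poisson
# gene-body density, continued (readthrough) density past the annotated 3'
# end, an elevated termination peak, a linear decay of the mean to zero at
# the true TTS, and optional genome-wide Poisson background. Everything is
# deterministic given the seed.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Build a table of synthetic gene specifications
#'
#' Lays out non-overlapping genes along one chromosome with alternating
#' strands (so that each gene's 3' search region is free of same-strand
#' neighbour signal at the default spacing). Each gene gets `n_candidates`
#' candidate TSSs in 5'-to-3' order; the true TSS is the
#' `true_candidate`-th. Candidates 5' of the true one sit in silent DNA,
#' candidates 3' of it sit inside the gene body — so exactly one candidate
#' window contains the pause peak.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name, default `"chrS"`.
#' @param body_len Bases from the true TSS to the annotated 3' end (scalar or
#'   length-`n_genes`), default 10000.
#' @param gap Intergenic spacing between consecutive genes' footprints,
#'   default 14000 (a 10 kb downstream extension then never reaches the next
#'   same-strand gene).
#' @param n_candidates Candidate TSSs per gene, default 4.
#' @param true_candidate Index (5'-to-3') of the true TSS among the
#'   candidates, default 2.
#' @param candidate_spacing Distance between consecutive candidate TSSs,
#'   default 700 (> the default 500-base scoring window).
#' @param pause_offset Pause-peak position, bases 3' of the true TSS,
#'   default 40.
#' @param pause_reads Reads in the pause peak, default 200.
#' @param pause_width Width of the pause peak in bases, default 5.
#' @param body_rate Mean gene-body reads per base, default 1.
#' @param readthrough_len Bases of continued body-level transcription past the
#'   annotated 3' end before the termination peak, default 500.
#' @param termination_peak_reads Reads in the termination peak, default 100.
#' @param termination_peak_width Width of the termination peak, default 50.
#' @param termination_decay_len Bases over which the mean density decays
#'   linearly to zero past the termination peak, default 1500. The true TTS is
#'   the end of this decay.
#' @param noise_rate Genome-wide background reads per base per strand,
#'   default 0.
#' @param alternate_strands Alternate gene strands (default `TRUE`); set
#'   `FALSE` for all-plus layouts.
#' @return data.frame with one row per gene (candidates in a list column),
#'   plus the implied `chrom_len` as attribute `"chrom_len"`.
#' @export
synthetic_gene_specs <- function(n_genes, chrom = "chrS", body_len = 10000,
                                 gap = 14000, n_candidates = 4,
                                 true_candidate = 2, candidate_spacing = 700,
                                 pause_offset = 40, pause_reads = 200,
                                 pause_width = 5, body_rate = 1,
                                 readthrough_len = 500,
                                 termination_peak_reads = 100,
                                 termination_peak_width = 50,
                                 termination_decay_len = 1500,
                                 noise_rate = 0, alternate_strands = TRUE) {
  stopifnot(n_genes >= 1, true_candidate >= 1, true_candidate <= n_candidates)
  body_len <- rep_len(body_len, n_genes)
  up <- (true_candidate - 1) * candidate_spacing          # span 5' of true TSS
  tail_len <- readthrough_len + termination_decay_len
  specs <- vector("list", n_genes)
  cursor <- gap
  for (i in seq_len(n_genes)) {
    strand <- if (alternate_strands && i %% 2 == 0) "-" else "+"
    offs <- (seq_len(n_candidates) - true_candidate) * candidate_spacing
    if (strand == "+") {
      true_tss <- cursor + up
      cands <- true_tss + offs
      aend <- true_tss + body_len[i]           # annotated 3' end
      true_tts <- aend + tail_len
      gstart <- min(cands); gend <- aend
      foot_end <- true_tts
    } else {
      # mirror image: 5' is the high-coordinate side
      true_tts <- cursor
      aend <- true_tts + tail_len              # annotated 3' end (left boundary)
      true_tss <- aend + body_len[i] - 1       # initiating base
      cands <- true_tss - offs
      gstart <- aend; gend <- max(cands) + 1
      foot_end <- max(cands)
    }
    specs[[i]] <- data.frame(gene_id = sprintf("gene_%03d", i), chrom = chrom,
                             strand = strand, true_tss = true_tss,
                             annotated_end = aend, true_tts = true_tts,
                             gstart = gstart, gend = gend,
                             pause_offset = pause_offset,
                             pause_reads = pause_reads, pause_width = pause_width,
                             body_rate = body_rate,
                             readthrough_len = readthrough_len,
                             termination_peak_reads = termination_peak_reads,
                             termination_peak_width = termination_peak_width,
                             termination_decay_len = termination_decay_len,
                             noise_rate = noise_rate, stringsAsFactors = FALSE)
    specs[[i]]$candidates <- I(list(sort(cands)))
    cursor <- foot_end + gap
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  attr(out, "chrom_len") <- cursor
  out
}

# Deterministically spread `n` reads over `w` bases starting at `pos`
# (0-based): equal share per base, remainder at the central base.
.spread_reads <- function(vec, pos, w, n) {
  if (n <= 0 || w <= 0) return(vec)
  idx <- pos + seq_len(w)  # 1-based into vec
  idx <- idx[idx >= 1 & idx <= length(vec)]
  per <- n %/% w
  vec[idx] <- vec[idx] + per
  mid <- pos + ceiling(w / 2)
  if (mid >= 1 && mid <= length(vec)) vec[mid] <- vec[mid] + n %% w
  vec
}

#' Generate synthetic strand-specific PRO-seq coverage
#'
#' Renders the signal described by a [synthetic_gene_specs()] table into a
#' [coverage_track()], together with the ground-truth table and a matching
#' isoform annotation (one isoform per candidate TSS, first exon at the
#' candidate).
#'
#' @param specs Specification table from [synthetic_gene_specs()] (or an
#'   equivalently shaped data.frame). Genes must not overlap on a strand.
#' @param chrom_len Chromosome length in bases; defaults to the spec table's
#'   `"chrom_len"` attribute.
#' @param seed Integer seed; all random draws (gene-body Poisson counts,
#'   decay Poisson counts, background read placement) are deterministic given
#'   it.
#' @return List with elements:
#'   \describe{
#'     \item{`track`}{the [coverage_track()];}
#'     \item{`truth`}{per-gene ground truth (`true_tss`, `true_tts`,
#'       `annotated_end`, largest interval `gstart`/`gend`, candidates);}
#'     \item{`isoforms`}{isoform table consumable by [largest_interval()] and
#'       [collect_first_exons()];}
#'     \item{`chrom_len`}{the chromosome length used.}
#'   }
#' @export
generate_coverage <- function(specs, chrom_len = attr(specs, "chrom_len"),
                              seed = 1) {
  stopifnot(!is.null(chrom_len))
  if (length(unique(specs$chrom)) > 1L)
    stop("single-chromosome spec tables only")
  .check_no_overlap(specs)
  chrom <- specs$chrom[1]
  dense <- list("+" = numeric(chrom_len), "-" = numeric(chrom_len))
  .with_seed(seed, {
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      v <- dense[[s$strand]]
      dirn <- if (s$strand == "+") 1 else -1
      # gene body + readthrough: Poisson(body_rate) per base from the true
      # TSS through annotated end to the termination peak
      body_span <- s$annotated_end - s$true_tss  # signed length-ish
      if (s$strand == "+") {
        body_pos <- s$true_tss:(s$annotated_end + s$readthrough_len - 1)
        peak_pos <- s$annotated_end + s$readthrough_len
        decay_pos <- peak_pos + seq_len(s$termination_decay_len) - 1
      } else {
        body_pos <- (s$annotated_end - s$readthrough_len):s$true_tss
        peak_pos <- s$annotated_end - s$readthrough_len  # decay runs leftward
        decay_pos <- peak_pos - seq_len(s$termination_decay_len)
      }
      body_pos <- body_pos[body_pos >= 0 & body_pos < chrom_len]
      if (s$body_rate > 0 && length(body_pos))
        v[body_pos + 1] <- v[body_pos + 1] + stats::rpois(length(body_pos), s$body_rate)
      # pause peak, a fixed number of reads in a narrow window 3' of the TSS
      pp <- s$true_tss + dirn * s$pause_offset
      pstart <- if (s$strand == "+") pp else pp - s$pause_width + 1
      v <- .spread_reads(v, pstart, s$pause_width, s$pause_reads)
      # termination peak at the decay start
      tstart <- if (s$strand == "+") peak_pos else peak_pos - s$termination_peak_width
      v <- .spread_reads(v, tstart, s$termination_peak_width, s$termination_peak_reads)
      # linear decay of the Poisson mean to zero at the true TTS
      if (s$termination_decay_len > 0 && s$body_rate > 0) {
        d <- seq_len(s$termination_decay_len) - 1
        mu <- s$body_rate * (1 - d / s$termination_decay_len)
        ok <- decay_pos >= 0 & decay_pos < chrom_len
        v[decay_pos[ok] + 1] <- v[decay_pos[ok] + 1] + stats::rpois(sum(ok), mu[ok])
      }
      dense[[s$strand]] <- v
    }
    # genome-wide background, as a homogeneous Poisson process per strand
    nr <- unique(specs$noise_rate)
    if (length(nr) > 1L) stop("noise_rate must be constant across the spec table")
    if (nr > 0) {
      for (st in c("+", "-")) {
        n <- stats::rpois(1, nr * chrom_len)
        if (n > 0) {
          pos <- sample.int(chrom_len, n, replace = TRUE)
          tab <- tabulate(pos, nbins = chrom_len)
          dense[[st]] <- dense[[st]] + tab
        }
      }
    }
  })
  cov <- lapply(dense, function(v) stats::setNames(list(S4Vectors::Rle(v)), chrom))
  track <- coverage_track(cov[["+"]], cov[["-"]])
  truth <- specs[c("gene_id", "chrom", "strand", "true_tss", "annotated_end",
                   "true_tts", "gstart", "gend", "candidates")]
  list(track = track, truth = truth, isoforms = .specs_to_isoforms(specs),
       chrom_len = chrom_len)
}

.check_no_overlap <- function(specs) {
  for (st in unique(specs$strand)) {
    s <- specs[specs$strand == st, ]
    if (st == "+") {
      lo <- s$gstart; hi <- pmax(s$gend, s$true_tts)
    } else {
      lo <- pmin(s$gstart, s$true_tts); hi <- s$gend
    }
    o <- order(lo)
    if (any(lo[o][-1] < hi[o][-length(o)]))
      stop("overlapping gene specs on strand ", st)
  }
  invisible(TRUE)
}

# One isoform per candidate TSS: transcript from the candidate to the
# annotated 3' end, first exon being the candidate-proximal 200 bases.
.specs_to_isoforms <- function(specs) {
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    cands <- s$candidates[[1]]
    if (s$strand == "+") {
      start <- cands; end <- rep(s$annotated_end, length(cands))
      fe_start <- cands; fe_end <- pmin(cands + 200, end)
    } else {
      start <- rep(s$annotated_end, length(cands)); end <- cands + 1
      fe_end <- cands + 1; fe_start <- pmax(cands + 1 - 200, start)
    }
    data.frame(chrom = s$chrom, start = start, end = end, strand = s$strand,
               gene_id = s$gene_id,
               transcript_id = paste0(s$gene_id, ".", seq_along(cands)),
               fe_start = fe_start, fe_end = fe_end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic de novo TU calls
#'
#' Stands in for an unsupervised TU caller: emits each gene's true primary
#' transcript span with optional uniform boundary jitter, merging same-strand
#' neighbours closer than `merge_gap` into a single TU (to exercise
#' [annotate_tus()] splitting).
#'
#' @param truth Truth table from [generate_coverage()].
#' @param merge_gap Same-strand TUs closer than this many bases are merged,
#'   default 0 (no merging).
#' @param jitter Maximum absolute uniform boundary jitter in bases, default 0.
#' @param seed Integer seed for the jitter draws.
#' @return data.frame of TU calls: `chrom, start, end, strand, id` and a
#'   `genes` column listing the true constituent gene_ids (comma-separated).
#' @export
generate_tu_calls <- function(truth, merge_gap = 0, jitter = 0, seed = 1) {
  plus <- truth$strand == "+"
  start <- ifelse(plus, truth$true_tss, truth$true_tts)
  end <- ifelse(plus, truth$true_tts, truth$true_tss + 1)
  .with_seed(seed, {
    if (jitter > 0) {
      start <- start + round(stats::runif(length(start), -jitter, jitter))
      end <- end + round(stats::runif(length(end), -jitter, jitter))
      end <- pmax(end, start + 1)
      start <- pmax(start, 0)
    }
  })
  df <- data.frame(chrom = truth$chrom, start = start, end = end,
                   strand = truth$strand, genes = truth$gene_id,
                   stringsAsFactors = FALSE)
  out <- list()
  for (st in unique(df$strand)) {
    d <- df[df$strand == st, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    for (j in seq_len(nrow(d))[-1]) {
      if (d$start[j] - cur$end < merge_gap) {
        cur$end <- max(cur$end, d$end[j])
        cur$genes <- paste(cur$genes, d$genes[j], sep = ",")
      } else {
        out[[length(out) + 1]] <- cur
        cur <- d[j, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  res$id <- sprintf("tu_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Write a synthetic fixture set to disk
#'
#' Emits the formats the pipeline consumes: per-strand bedGraph (minus-strand
#' values negated), an isoform table, optional TU calls, and the truth table
#' as TSV. Output is deterministic, so identical generator calls produce
#' byte-identical files.
#'
#' @param gen Result of [generate_coverage()].
#' @param dir Output directory (created if needed).
#' @param tus Optional TU calls from [generate_tu_calls()].
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_fixtures <- function(gen, dir, tus = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plus = file.path(dir, "plus.bedGraph"),
             minus = file.path(dir, "minus.bedGraph"),
             isoforms = file.path(dir, "isoforms.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_coverage(gen$track, paths[["plus"]], paths[["minus"]])
  iso <- gen$isoforms
  bed8 <- data.frame(chrom = iso$chrom, start = iso$start, end = iso$end,
                     name = iso$transcript_id, score = 0, strand = iso$strand,
                     gene_id = iso$gene_id, transcript_id = iso$transcript_id)
  utils::write.table(bed8, paths[["isoforms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth_flat <- gen$truth
  truth_flat$candidates <- vapply(truth_flat$candidates, paste, "", collapse = ",")
  utils::write.table(truth_flat, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tus)) {
    paths <- c(paths, tus = file.path(dir, "tus.bed"))
    write_bed(tus, paths[["tus"]])
  }
  invisible(paths)
}
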