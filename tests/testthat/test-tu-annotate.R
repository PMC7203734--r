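iv <- function(start, end, strand = "+", chrom = "chr1", id = NULL, gene_id = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- id
  if (!is.null(gene_id)) df$gene_id <- gene_id
  df
}

test_that("overlap_fraction returns reciprocal fractions", {
  expect_equal(overlap_fraction(iv(0, 100), iv(0, 100)),
               data.frame(frac_tu = 1, frac_gene = 1))
  expect_equal(overlap_fraction(iv(0, 100), iv(500, 600))$frac_tu, 0)
  of <- overlap_fraction(iv(0, 1000), iv(500, 1500))
  expect_equal(c(of$frac_tu, of$frac_gene), c(0.5, 0.5))
  # different strand or chromosome -> (0, 0)
  expect_equal(overlap_fraction(iv(0, 100), iv(0, 100, strand = "-"))$frac_gene, 0)
  expect_equal(overlap_fraction(iv(0, 100), iv(0, 100, chrom = "chr2"))$frac_tu, 0)
})

test_that("single-gene TUs carry the gene name whole; intergenic TUs stay unannotated", {
  genes <- iv(1000, 4000, gene_id = "geneA")
  out <- annotate_tus(iv(1000, 4000, id = "tu1"), genes)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_id, "geneA")
  expect_equal(out$origin, "whole_tu")
  expect_equal(out$overlap_fraction_of_gene, 1)

  far <- annotate_tus(iv(9000, 9500, id = "tu2"), genes)
  expect_equal(far$gene_id, UNANNOTATED)
  expect_equal(far$origin, "intergenic")
  expect_equal(c(far$start, far$end), c(9000, 9500))
})

test_that("multi-gene TUs split at boundary midpoints into exact tiles", {
  genes <- rbind(iv(1000, 4000, gene_id = "geneA"), iv(6000, 9000, gene_id = "geneB"))
  out <- annotate_tus(iv(0, 10000, id = "tu1"), genes)
  expect_equal(out$start, c(0, 5000))  # midpoint (4000 + 6000) / 2
  expect_equal(out$end, c(5000, 10000))
  expect_equal(out$gene_id, c("geneA", "geneB"))
  expect_equal(unique(out$origin), "split_segment")
})

test_that("split segments tile each parent TU and recover every planted gene over random seeds", {
  for (seed in 1:50) {
    set.seed(seed)
    k <- sample(2:5, 1)
    gstart <- cumsum(sample(500:3000, k)) + (0:(k - 1)) * sample(200:2000, 1)
    glen <- sample(400:2500, k)
    st <- sample(c("+", "-"), 1)
    genes <- iv(gstart, gstart + glen, strand = st,
                gene_id = sprintf("g%02d", seq_len(k)))
    tu <- iv(max(0, gstart[1] - sample(0:500, 1)),
             gstart[k] + glen[k] + sample(0:500, 1), strand = st, id = "tu")
    out <- annotate_tus(tu, genes, min_frac = 0.5)
    expect_setequal(out$gene_id, genes$gene_id)
    out <- out[order(out$start), ]
    expect_equal(out$start[1], tu$start)
    expect_equal(out$end[nrow(out)], tu$end)
    if (nrow(out) > 1)
      expect_equal(out$start[-1], out$end[-nrow(out)])  # no gaps, no overlaps
  }
})

test_that("the gene-fraction threshold governs qualification", {
  genes <- iv(0, 10000, gene_id = "geneA")
  grazing <- annotate_tus(iv(8000, 12000, id = "tu"), genes, min_frac = 0.5)
  expect_equal(grazing$gene_id, UNANNOTATED)  # covers only 20% of the gene
  ok <- annotate_tus(iv(8000, 12000, id = "tu"), genes, min_frac = 0.2)
  expect_equal(ok$gene_id, "geneA")
})

test_that("a gene covered by several TUs gets ordinal-suffixed names, gene_id unsuffixed", {
  genes <- iv(0, 10000, gene_id = "geneA")
  tus <- rbind(iv(0, 5000, id = "tu1"), iv(5000, 10000, id = "tu2"))
  out <- annotate_tus(tus, genes, min_frac = 0.5)
  expect_equal(out$gene_id, c("geneA", "geneA"))
  expect_equal(out$name, c("geneA_1", "geneA_2"))
})

test_that("annotation is idempotent and invariant to input order", {
  set.seed(63)
  genes <- iv(c(100, 3000, 7000), c(2000, 5000, 9500),
              gene_id = c("gA", "gB", "gC"))
  tus <- rbind(iv(0, 5500, id = "tu1"), iv(6800, 9900, id = "tu2"),
               iv(15000, 16000, id = "tu3"))
  ref <- annotate_tus(tus, genes)
  for (k in 1:5) {
    perm <- annotate_tus(tus[sample.int(3), ], genes[sample.int(3), ])
    expect_equal(perm, ref)
  }
  # re-annotating single-gene segments against the same genes changes nothing
  single <- ref[ref$origin == "whole_tu", c("chrom", "start", "end", "strand", "gene_id")]
  names(single)[5] <- "id"
  again <- annotate_tus(single, genes)
  expect_equal(again$gene_id, ref$gene_id[ref$origin == "whole_tu"])
})

test_that("merged synthetic TUs are split back into their constituent genes", {
  gen <- synth_scene(8, seed = 31, alternate_strands = FALSE, gap = 1000)
  tus <- generate_tu_calls(gen$truth, merge_gap = 2000, jitter = 0, seed = 31)
  expect_lt(nrow(tus), 8)  # neighbours merged
  inferred_like <- data.frame(gene_id = gen$truth$gene_id, chrom = gen$truth$chrom,
                              start = ifelse(gen$truth$strand == "+",
                                             gen$truth$true_tss, gen$truth$true_tts),
                              end = ifelse(gen$truth$strand == "+",
                                           gen$truth$true_tts, gen$truth$true_tss + 1),
                              strand = gen$truth$strand, stringsAsFactors = FALSE)
  out <- annotate_tus(tus, inferred_like, min_frac = 0.5)
  expect_setequal(out$gene_id, gen$truth$gene_id)
  for (tu_id in unique(out$parent_tu)) {
    seg <- out[out$parent_tu == tu_id, ]
    seg <- seg[order(seg$start), ]
    parent <- tus[tus$id == tu_id, ]
    expect_equal(seg$start[1], parent$start)
    expect_equal(seg$end[nrow(seg)], parent$end)
    if (nrow(seg) > 1) expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
})
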