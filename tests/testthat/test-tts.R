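gene_df <- function(id, start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

mk_binned <- function(counts, fitted = NULL, B = 200, strand = "+") {
  structure(list(gene_id = "g", chrom = "chr1", strand = strand, B = B,
                 bin_start = seq(0, by = B, length.out = length(counts)),
                 counts = counts, fitted = fitted, peak_index = NULL,
                 decay_index = NULL), class = "binned_signal")
}

test_that("search regions span the 3' gene fraction plus the downstream extension", {
  r <- define_search_region(gene_df("g", 0, 10000), 0.2, 5000)
  expect_equal(c(r$start, r$end), c(8000, 15000))
  rm_ <- define_search_region(gene_df("g", 5000, 10000, strand = "-"), 0.2, 1000)
  expect_equal(c(rm_$start, rm_$end), c(4000, 6000))
  set.seed(41)
  for (k in 1:100) {
    # genes placed away from the chromosome edge so no clipping applies
    s <- 20000 + sample.int(50000, 1); len <- sample(1000:30000, 1)
    fr <- runif(1, 0.05, 1); ext <- sample.int(20000, 1)
    st <- sample(c("+", "-"), 1)
    r <- define_search_region(gene_df("g", s, s + len, strand = st), fr, ext)
    expect_equal(r$end - r$start, round(fr * len) + ext)
  }
})

test_that("bin_signal tiles whole bins from the 5' end and drops the partial bin", {
  tr <- track_from_dense(plus = list(chr1 = rep(1, 3000)),
                         minus = list(chr1 = rep(1, 3000)))
  reg <- data.frame(gene_id = "g", chrom = "chr1", start = 500, end = 1550,
                    strand = "+", stringsAsFactors = FALSE)
  bs <- bin_signal(reg, tr, B = 100)
  expect_length(bs$counts, 10)  # 1050 bases -> 10 bins, 50 dropped at the 3' end
  expect_equal(bs$counts, rep(100, 10))
  expect_equal(bs$bin_start[1], 500)
  # minus strand: bins run right to left; the partial bin drops at the left (3') end
  reg$strand <- "-"
  bsm <- bin_signal(reg, tr, B = 100)
  expect_equal(bsm$bin_start[1], 1450)
  expect_equal(bsm$bin_start[10], 550)
  expect_error(bin_signal(data.frame(gene_id = "g", chrom = "chr1", start = 0,
                                     end = 350, strand = "+"), tr, B = 100),
               "unprocessable")
})

test_that("bin counts sum to the region count over the binned span", {
  set.seed(55)
  L <- 30000
  dense <- dense_from_steps(rand_steps(L, 400), L)
  tr <- track_from_dense(plus = list(chr1 = dense), minus = list(chr1 = dense))
  for (k in 1:200) {
    s <- sample.int(L - 6000, 1); e <- s + 800 + sample.int(5000, 1)
    st <- sample(c("+", "-"), 1)
    B <- sample(c(50, 100, 200), 1)
    reg <- data.frame(gene_id = "g", chrom = "chr1", start = s, end = e,
                      strand = st, stringsAsFactors = FALSE)
    bs <- bin_signal(reg, tr, B)
    n <- floor((e - s) / B)
    span <- if (st == "+") c(s, s + n * B) else c(e - n * B, e)
    expect_equal(sum(bs$counts), region_counts(tr, "chr1", span[1], span[2], st))
  }
})

test_that("the smoothing spline reproduces constant and linear profiles and preserves a triangular argmax", {
  const <- fit_smooth_curve(mk_binned(rep(7, 20)))
  expect_lt(max(abs(const$fitted - 7)), 1e-6 * 7)
  ramp <- fit_smooth_curve(mk_binned(seq(0, 95, by = 5)), knots_per_kb = 2)
  expect_lt(max(abs(ramp$fitted - seq(0, 95, by = 5))), 0.2)
  tri <- c(1:10 * 10, 9:1 * 10, rep(0, 10))
  fit <- fit_smooth_curve(mk_binned(tri), knots_per_kb = 5)
  expect_equal(which.max(fit$fitted), which.max(tri))
})

test_that("locate_peak takes the global fitted maximum above the background floor", {
  bs <- mk_binned(c(1, 2, 9, 3, 1), fitted = c(1, 2, 9, 3, 1))
  expect_equal(locate_peak(bs)$peak_index, 3)
  zero <- fit_smooth_curve(mk_binned(rep(0, 10)))
  expect_null(locate_peak(zero)$peak_index)
  # a maximum below half the 5'-leading background is not a peak
  flatish <- mk_binned(c(100, 100, 100, 30, 20, 10), fitted = c(100, 100, 100, 30, 20, 10))
  expect_equal(locate_peak(flatish)$peak_index, 1)  # global max is bin 1 here
  low <- mk_binned(c(100, 100, 100, 0, 0, 0), fitted = c(0, 0, 0, 40, 0, 0))
  expect_null(locate_peak(low)$peak_index)  # 40 < 0.5 * mean(100, 100, 100)
})

test_that("locate_decay finds the first bin at or below tau * peak", {
  bs <- mk_binned(rep(0, 6), fitted = c(0, 10, 5, 2, 0.5, 0.2))
  bs$peak_index <- 2L
  expect_equal(locate_decay(bs, tau = 0.1)$decay_index, 5)
  mono <- mk_binned(rep(0, 5), fitted = c(1, 2, 3, 4, 5))
  mono$peak_index <- 2L
  expect_null(locate_decay(mono, tau = 0.1)$decay_index)
})

test_that("locate_decay agrees with a linear-scan oracle on random curves", {
  set.seed(77)
  for (k in 1:500) {
    n <- sample(6:40, 1)
    fitted <- runif(n, 0, 100)
    p <- sample.int(n - 2, 1)
    tau <- runif(1, 0.05, 0.9)
    bs <- mk_binned(rep(0, n), fitted = fitted)
    bs$peak_index <- p
    got <- locate_decay(bs, tau)$decay_index
    oracle <- NULL
    for (j in (p + 1):n) if (fitted[j] <= tau * fitted[p]) { oracle <- j; break }
    expect_identical(got, oracle)
  }
})

test_that("infer_tts composes the steps and lands within a bin of a planted decay", {
  # body rate 1/base to 10,000, termination peak at 10,500, decay to zero by
  # 12,000; search region [8,000, 15,000), B = 200, tau = 0.1
  set.seed(8)
  dense <- numeric(16000)
  dense[1:10000] <- rpois(10000, 1)
  dense[10001:10500] <- rpois(500, 1)
  dense[10476:10525] <- dense[10476:10525] + 2          # termination peak, 100 reads
  dense[10501:12000] <- rpois(1500, 1 - (0:1499) / 1500)
  tr <- track_from_dense(plus = list(chr1 = dense))
  tts <- infer_tts(gene_df("g", 0, 10000), tr, gene_fraction = 0.2,
                   downstream_extension = 5000, B = 200, tau = 0.1)
  expect_equal(tts$status, "decay_found")
  expect_gte(tts$tts, 11800)
  expect_lte(tts$tts, 12400)
})

test_that("fallback statuses cover silent regions and never-decaying signal", {
  tr0 <- track_from_dense(plus = list(chr1 = numeric(20000)),
                          minus = list(chr1 = numeric(20000)))
  g <- gene_df("g", 2000, 12000)
  out <- infer_tts(g, tr0, downstream_extension = 4000)
  expect_equal(out$status, "no_peak_gene_end")
  expect_equal(out$tts, 12000)  # annotated 3' end

  # strong signal that never decays before the region end
  tr1 <- track_from_dense(plus = list(chr1 = rep(5, 20000)))
  out1 <- infer_tts(g, tr1, downstream_extension = 4000)
  expect_equal(out1$status, "no_decay_region_end")
  expect_equal(out1$tts, 16000)  # region 3' end

  # region too short to bin
  short <- infer_tts(gene_df("s", 100, 400), tr0, gene_fraction = 0.5,
                     downstream_extension = 100, B = 200)
  expect_equal(short$status, "unprocessable")

  # single sharp peak at the gene end with silence beyond: decay found one
  # bin 3' of the peak (near-interpolating fit: an isolated spike among
  # zeros carries no noise to smooth away)
  tr2dense <- numeric(20000); tr2dense[11951:12000] <- 20
  tr2 <- track_from_dense(plus = list(chr1 = tr2dense))
  out2 <- infer_tts(g, tr2, downstream_extension = 4000, knots_per_kb = 5,
                    spar = 0)
  expect_equal(out2$status, "decay_found")
  expect_equal(out2$tts, out2$peak_coord + 200)
})

test_that("the inferred TTS stays inside the search region and respects tau monotonicity", {
  gen <- synth_scene(30, noise_rate = 0.01, seed = 19)
  regions <- define_search_region(gen$genes, 0.2, 5000)
  for (tau in c(0.3, 0.1)) {
    tts <- infer_tts(gen$genes, gen$track, downstream_extension = 5000, tau = tau)
    m <- merge(tts, regions[c("gene_id", "start", "end")], by = "gene_id")
    expect_true(all(m$tts >= m$start & m$tts <= m$end))
  }
  # smaller tau (stricter decay) never moves the TTS 5'-ward
  t_loose <- infer_tts(gen$genes, gen$track, downstream_extension = 5000, tau = 0.3)
  t_strict <- infer_tts(gen$genes, gen$track, downstream_extension = 5000, tau = 0.05)
  both <- merge(t_loose, t_strict, by = c("gene_id", "strand"), suffixes = c("_l", "_s"))
  ok <- both$status_l == "decay_found" & both$status_s == "decay_found"
  plus <- both$strand == "+"
  expect_true(all(both$tts_s[ok & plus] >= both$tts_l[ok & plus]))
  expect_true(all(both$tts_s[ok & !plus] <= both$tts_l[ok & !plus]))
})

test_that("readthrough past the annotated 3' end is detected on synthetic genes", {
  gen <- synth_scene(60, noise_rate = 0, seed = 29)
  tts <- infer_tts(gen$genes, gen$track, downstream_extension = 5000)
  m <- merge(tts, gen$truth[c("gene_id", "annotated_end")], by = "gene_id")
  plus <- m$strand == "+"
  beyond <- ifelse(plus, m$tts > m$annotated_end, m$tts < m$annotated_end)
  expect_gte(mean(beyond), 0.95)
})
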