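# interval algebra: merging, summit windows, overlap pairs, nearest TSS

test_that("merge_intervals closes gaps up to and including max_gap", {
  df <- data.frame(chrom = "chr1", start = c(0L, 150L, 400L),
                   end = c(50L, 200L, 450L))
  out <- merge_intervals(df, max_gap = 100)
  expect_equal(out$start, c(0L, 400L))   # gap 100 merges, gap 200 does not
  expect_equal(out$end, c(200L, 450L))
  out2 <- merge_intervals(data.frame(chrom = "chr1", start = c(0L, 151L),
                                     end = c(50L, 200L)), max_gap = 100)
  expect_equal(nrow(out2), 2L)           # gap 101 stays split
  expect_equal(nrow(merge_intervals(df[0, ], 100)), 0L)
  expect_error(merge_intervals(df, max_gap = -1), ">= 0")
})

test_that("merge_intervals is idempotent and only grows coverage", {
  set.seed(41)
  for (rep in 1:50) {
    df <- random_intervals(sample(1:60, 1))
    gap <- sample(c(0L, 10L, 100L), 1)
    m <- merge_intervals(df, gap)
    expect_identical(merge_intervals(m, gap), m)
    cov_in <- sum(merge_intervals(df, 0)$end - merge_intervals(df, 0)$start)
    cov_out <- sum(m$end - m$start)
    expect_gte(cov_out, cov_in)
    if (gap == 0L) expect_equal(cov_out, cov_in)
  }
})

test_that("merge_intervals matches the brute-force scan on random inputs", {
  set.seed(42)
  for (rep in 1:100) {
    df <- random_intervals(sample(1:80, 1))
    gap <- sample(0:150, 1)
    expect_equal(merge_intervals(df, gap), bf_merge(df, gap),
                 ignore_attr = TRUE)
  }
})

test_that("summit windows are fixed-width and clip at chromosome edges", {
  sizes <- c(chr1 = 10000L)
  w <- summit_windows(data.frame(chrom = "chr1", summit = 500L), 100, sizes)
  expect_equal(c(w$start, w$end), c(400L, 600L))
  w2 <- summit_windows(data.frame(chrom = "chr1", summit = 40L), 100, sizes)
  expect_equal(c(w2$start, w2$end), c(0L, 140L))
  w3 <- summit_windows(data.frame(chrom = "chr1", summit = 9950L), 100, sizes)
  expect_equal(c(w3$start, w3$end), c(9850L, 10000L))
  expect_error(summit_windows(data.frame(chrom = "chr1", summit = 10000L),
                              100, sizes), "outside")
  # interior summits always give width exactly 2 * flank
  set.seed(5)
  s <- data.frame(chrom = "chr1",
                  summit = sample(100:9900, 50))
  ww <- summit_windows(s, 100, sizes)
  expect_true(all(ww$end - ww$start == 200L))
})

test_that("overlap_pairs agrees with the all-pairs scan and handles edges", {
  expect_equal(nrow(overlap_pairs(
    data.frame(chrom = "chr1", start = 0L, end = 10L),
    data.frame(chrom = "chr2", start = 0L, end = 10L))), 0L)
  p <- overlap_pairs(data.frame(chrom = "chr1", start = 0L, end = 200L),
                     data.frame(chrom = "chr1", start = c(150L, 500L),
                                end = c(350L, 600L)))
  expect_equal(p, data.frame(query = 1L, subject = 1L), ignore_attr = TRUE)
  # bookended intervals (half-open) do not overlap
  p2 <- overlap_pairs(data.frame(chrom = "chr1", start = 0L, end = 100L),
                      data.frame(chrom = "chr1", start = 100L, end = 200L))
  expect_equal(nrow(p2), 0L)
  set.seed(43)
  for (rep in 1:100) {
    q <- random_intervals(sample(1:40, 1))
    s <- random_intervals(sample(1:40, 1))
    expect_equal(overlap_pairs(q, s), bf_overlap_pairs(q, s),
                 ignore_attr = TRUE)
  }
})

test_that("nearest_tss picks the closest in-range TSS with signed distance", {
  tm <- toy_transcripts()  # GENEA + at tss 10000, GENEB - at tss 31500
  r <- function(mid) data.frame(chrom = "chr1", start = mid - 10L,
                                end = mid + 10L)
  out <- nearest_tss(r(11000L), tm, tss_range = 100000)
  expect_equal(out$gene_symbol, "GENEA")
  expect_equal(out$tss_distance, 1000L)       # downstream of a + TSS
  out2 <- nearest_tss(r(32500L), tm, tss_range = 100000)
  expect_equal(out2$gene_symbol, "GENEB")
  expect_equal(out2$tss_distance, -1000L)     # upstream of a - TSS
  out3 <- nearest_tss(r(30500L), tm, tss_range = 100000)
  expect_equal(out3$gene_symbol, "GENEB")
  expect_equal(out3$tss_distance, 1000L)      # downstream of a - TSS
  out4 <- nearest_tss(r(11000L), tm, tss_range = 500)
  expect_true(is.na(out4$gene_symbol))        # out of range -> none
})

test_that("nearest_tss ties break by distance, then gene, then transcript", {
  feats <- rbind(
    data.frame(chrom = "chr1", start = 1000L, end = 1200L, strand = "+",
               type = "exon", transcript_id = "T2", gene_symbol = "GB"),
    data.frame(chrom = "chr1", start = 3000L, end = 3200L, strand = "-",
               type = "exon", transcript_id = "T1", gene_symbol = "GA")
  )
  tm <- peaklink:::build_transcript_models(feats)
  # anchor 2100: TSS at 1000 (GB) and 3200 (GA), distances 1100 both
  out <- nearest_tss(data.frame(chrom = "chr1", start = 2090L, end = 2110L),
                     tm, tss_range = 10000)
  expect_equal(out$gene_symbol, "GA")  # lexicographic gene wins the tie
})

test_that("nearest_tss agrees with the exhaustive scan on random instances", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 8e5, n_genes = 50,
                    n_peaks = 30, deg_count = 10, cistrome_count = 10,
                    n_dar = 5, depth = 1000)
  tm <- simulate_annotation(cfg)$transcripts
  set.seed(44)
  for (rep in 1:20) {
    regions <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                          start = sample.int(790000L, 40))
    regions$end <- regions$start + sample.int(500L, 40)
    rng <- sample(c(5000L, 50000L, 100000L), 1)
    expect_equal(nearest_tss(regions, tm, rng),
                 bf_nearest_tss(regions, tm, rng), ignore_attr = TRUE)
  }
})
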