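# differential accessibility: down-sampling, cut sites, counting, testing

test_that("downsample_fragments is a deterministic uniform subset", {
  frags <- data.frame(chrom = "chr1", start = 0:99, end = 10:109)
  expect_identical(downsample_fragments(frags, 200, seed = 1), frags)
  expect_equal(nrow(downsample_fragments(frags, 0, seed = 1)), 0L)
  expect_error(downsample_fragments(frags, -1), ">= 0")
  a <- downsample_fragments(frags, 30, seed = 9)
  b <- downsample_fragments(frags, 30, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 30L)
  # inclusion frequency ~ n/total across seeds (binomial CI)
  inc <- rowSums(vapply(1:400, function(s) {
    0:99 %in% downsample_fragments(frags, 30, seed = s)$start
  }, logical(100)))
  p_hat <- inc / 400
  ci <- 4 * sqrt(0.3 * 0.7 / 400)
  expect_true(all(abs(p_hat - 0.3) < ci))
})

test_that("cut sites anchor at read 5' ends and fragment ends", {
  plus <- data.frame(chrom = "chr1", start = 1000L, end = 1050L, strand = "+")
  expect_equal(extract_cut_sites(plus, 9)[, c("start", "end")],
               data.frame(start = 1000L, end = 1009L), ignore_attr = TRUE)
  minus <- data.frame(chrom = "chr1", start = 1950L, end = 2000L, strand = "-")
  expect_equal(extract_cut_sites(minus, 9)[, c("start", "end")],
               data.frame(start = 1991L, end = 2000L), ignore_attr = TRUE)
  frag <- data.frame(chrom = "chr1", start = 1000L, end = 1050L, strand = ".")
  cs <- extract_cut_sites(frag, 9)
  expect_equal(sort(cs$start), c(1000L, 1041L))
  expect_error(extract_cut_sites(frag, 0), "cut_width")
  # clipping to chromosome
  edge <- data.frame(chrom = "chr1", start = 95L, end = 120L, strand = "+")
  clipped <- extract_cut_sites(edge, 9, sizes = c(chr1 = 100L))
  expect_equal(clipped$end, 100L)
})

test_that("count_in_regions counts overlapping cut sites per sample", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  cuts <- list(
    s1 = data.frame(chrom = "chr1", start = c(10L, 20L, 30L),
                    end = c(19L, 29L, 39L)),
    s2 = data.frame(chrom = "chr1", start = 1200L, end = 1209L)
  )
  sig <- count_in_regions(regions, cuts, c("vehicle", "treated"))
  expect_equal(unname(sig$counts[, "s1"]), c(3L, 0L))
  expect_equal(unname(sig$counts[, "s2"]), c(0L, 1L))
  expect_true(all(colSums(sig$counts) <= sig$library_sizes))
  empty <- count_in_regions(regions, list(s1 = cuts$s1[0, ], s2 = cuts$s2),
                            c("vehicle", "treated"))
  expect_equal(sum(empty$counts[, "s1"]), 0L)
  overlapping <- data.frame(chrom = "chr1", start = c(0L, 400L),
                            end = c(500L, 900L))
  expect_error(count_in_regions(overlapping, cuts, c("a", "b")), "disjoint")
})

test_that("normalization scales each sample to a common in-region total", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  cuts <- list(
    s1 = data.frame(chrom = "chr1", start = c(10L, 1100L), end = c(19L, 1109L)),
    s2 = data.frame(chrom = "chr1", start = rep(c(10L, 1100L), 2),
                    end = rep(c(19L, 1109L), 2))
  )
  sig <- count_in_regions(regions, cuts, c("a", "b"))
  expect_equal(colSums(sig$normalized), c(s1 = 1e7, s2 = 1e7))
})

test_that("bh_adjust matches the hand-rolled step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(48)
  for (rep in 1:200) {
    p <- runif(sample(1:500, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
  }
})

test_that("the vectorized row t test matches stats::t.test", {
  set.seed(49)
  y <- matrix(rnorm(50 * 7, mean = 5), nrow = 50)
  ia <- 1:3; ib <- 4:7
  w <- peaklink:::.t_rows(y, ia, ib)
  for (i in sample(50, 10)) {
    tt <- t.test(y[i, ib], y[i, ia], var.equal = TRUE)
    expect_equal(w$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(w$diff[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("identical groups give log2fc 0, p 1, class unchanged", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  cut1 <- data.frame(chrom = "chr1", start = c(10L, 1100L), end = c(19L, 1109L))
  cuts <- list(a1 = cut1, a2 = cut1, b1 = cut1, b2 = cut1)
  sig <- count_in_regions(regions, cuts, c("vehicle", "vehicle",
                                           "treated", "treated"))
  dar <- test_differential(sig)
  expect_equal(dar$log2fc, c(0, 0))
  expect_equal(dar$p, c(1, 1))
  expect_equal(dar$class, c("unchanged", "unchanged"))
})

test_that("relabeling conditions flips log2fc signs and classes, not p", {
  cfg <- sim_config(seed = 51, n_chroms = 1, chrom_length = 1e6, n_genes = 30,
                    n_peaks = 120, depth = 3e4, n_dar = 20, dar_log2fc = 2,
                    deg_count = 20, cistrome_count = 20)
  sim <- simulate_dataset(cfg)
  regions <- merge_intervals(rbind(sim$peaks$peaks_a[, 1:3],
                                   sim$peaks$peaks_b[, 1:3]), 100)
  sig <- count_in_regions(regions, sim$fragments$cuts,
                          sim$fragments$conditions)
  fwd <- test_differential(sig, treatment = "treated", reference = "vehicle")
  rev <- test_differential(sig, treatment = "vehicle", reference = "treated")
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$class == "increased", fwd$class == "decreased")
})

test_that("replicate and region preconditions are enforced", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  cuts <- list(a = data.frame(chrom = "chr1", start = 1L, end = 10L),
               b = data.frame(chrom = "chr1", start = 1L, end = 10L))
  sig <- count_in_regions(regions, cuts, c("vehicle", "treated"))
  expect_error(test_differential(sig), "2 replicates")
})

test_that("planted strong increases are recovered", {
  cfg <- sim_config(seed = 52, n_chroms = 1, chrom_length = 2e6, n_genes = 50,
                    n_peaks = 200, depth = 8e4, n_dar = 30, dar_log2fc = 3,
                    deg_count = 20, cistrome_count = 20)
  sim <- simulate_dataset(cfg)
  regions <- merge_intervals(rbind(sim$peaks$peaks_a[, 1:3],
                                   sim$peaks$peaks_b[, 1:3]), 100)
  sig <- count_in_regions(regions, sim$fragments$cuts,
                          sim$fragments$conditions)
  dar <- test_differential(sig)
  planted <- sim$peaks$truth[sim$peaks$truth$dar, c("chrom", "start", "end")]
  inc <- dar[dar$class == "increased", c("chrom", "start", "end")]
  hits <- overlap_pairs(planted, inc)
  expect_gte(length(unique(hits$query)) / nrow(planted), 0.9)
})
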