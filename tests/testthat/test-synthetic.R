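# generator determinism, self-consistency, and analytic expectations

small_cfg <- function(seed = 61, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length = 1.5e6, n_genes = 40,
               n_peaks = 150, depth = 2e4, n_dar = 15, deg_count = 30,
               cistrome_count = 40)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the generator is a pure function of config and seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_cfg(), dir = d1)
  simulate_dataset(small_cfg(), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the draw
  pk1 <- simulate_peaks(small_cfg(), simulate_annotation(small_cfg()))
  pk2 <- simulate_peaks(small_cfg(seed = 62),
                        simulate_annotation(small_cfg(seed = 62)))
  expect_false(identical(pk1$truth$summit, pk2$truth$summit))
})

test_that("emitted files pass their own readers and invariants", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(), dir = d)
  sizes <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(sizes, sim$annotation$sizes)
  tm <- read_transcripts(file.path(d, "annotation.gtf"))
  expect_true(validate_transcripts(tm))
  expect_equal(nrow(tm), 40L)
  pa <- read_peaks(file.path(d, "peaks_vehicle.narrowPeak"), sizes = sizes)
  expect_equal(pa$summit, sim$peaks$peaks_a$summit)
  cuts <- read_peaks(file.path(d, "cuts_treated_rep1.bed"), sizes = sizes)
  expect_equal(nrow(cuts), small_cfg()$depth)
  expect_true(all(cuts$end - cuts$start <= 9))
  degs <- read_table(file.path(d, "degs.tsv"))
  expect_equal(sort(degs$gene), sort(sim$degs$degs$gene))
})

test_that("an empty annotation and zero depth are valid degenerate outputs", {
  cfg <- sim_config(seed = 63, n_chroms = 1, chrom_length = 1e6, n_genes = 0,
                    n_peaks = 50, deg_count = 0, cistrome_count = 10,
                    n_dar = 5, depth = 0)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$transcripts), 0L)
  pk <- simulate_peaks(cfg, ann)
  fr <- simulate_fragments(cfg, pk)
  expect_true(all(vapply(fr$cuts, nrow, 1L) == 0L))
})

test_that("infeasible configurations fail loudly", {
  expect_error(simulate_annotation(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 1e4, n_genes = 50,
               n_peaks = 10, deg_count = 0, cistrome_count = 1, n_dar = 0,
               depth = 10)), "fit")
  expect_error(simulate_peaks(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 1e5, n_peaks = 500,
               n_genes = 0, deg_count = 0, cistrome_count = 1, n_dar = 0,
               depth = 10),
    simulate_annotation(
      sim_config(seed = 1, n_chroms = 1, chrom_length = 1e5, n_peaks = 500,
                 n_genes = 0, deg_count = 0, cistrome_count = 1, n_dar = 0,
                 depth = 10))), "infeasible")
  expect_error(sim_config(shared_fraction = 1.2), "fractions")
})

test_that("planted DEG linkage is recovered exactly through the analysis path", {
  cfg <- small_cfg(seed = 64)
  sim <- simulate_dataset(cfg)
  ann <- sim$annotation
  idx <- build_feature_models(ann$transcripts,
                              cfg$params$promoter_flank, ann$sizes)
  ga <- peaks_to_unique_genes(
    annotate_peaks(sim$peaks$peaks_a, idx, ann$transcripts,
                   cfg$params$tss_range))
  gb <- peaks_to_unique_genes(
    annotate_peaks(sim$peaks$peaks_b, idx, ann$transcripts,
                   cfg$params$tss_range))
  da <- classify_deg_association(sim$degs$degs$gene, ga, gb)
  n_linked <- round(cfg$deg_linked_fraction * cfg$deg_count)
  expect_equal(unname(da$counts["total"] - da$counts["neither"]), n_linked)
  expect_equal(unname(da$counts["neither"]), cfg$deg_count - n_linked)
  # per-gene agreement with the recorded truth
  linked_genes <- names(sim$degs$truth$linked)[sim$degs$truth$linked]
  called <- da$table$gene[da$table$class != "neither"]
  expect_setequal(called, linked_genes)
  # degenerate fractions
  for (lf in c(0, 1)) {
    cfg2 <- small_cfg(seed = 65, deg_linked_fraction = lf)
    sim2 <- simulate_dataset(cfg2)
    ga2 <- peaks_to_unique_genes(
      annotate_peaks(sim2$peaks$peaks_a, idx <- build_feature_models(
        sim2$annotation$transcripts, cfg2$params$promoter_flank,
        sim2$annotation$sizes), sim2$annotation$transcripts,
        cfg2$params$tss_range))
    gb2 <- peaks_to_unique_genes(
      annotate_peaks(sim2$peaks$peaks_b, idx, sim2$annotation$transcripts,
                     cfg2$params$tss_range))
    da2 <- classify_deg_association(sim2$degs$degs$gene, ga2, gb2)
    expect_equal(unname(da2$counts["neither"]),
                 as.integer((1 - lf) * cfg2$deg_count))
  }
})

test_that("planted cistrome overlap is recovered exactly", {
  cfg <- small_cfg(seed = 66, cistrome_overlap_fraction = 0.5946,
                   cistrome_count = 74)
  sim <- simulate_dataset(cfg)
  wb <- summit_windows(sim$peaks$summits_b, cfg$params$summit_flank,
                       sim$peaks$sizes)
  s <- summarize_cistrome_overlap(wb, sim$cistrome$cistrome)
  expect_equal(s$n_subject_overlapping, round(0.5946 * 74))
  expect_equal(s$n_subject_overlapping, sum(sim$cistrome$truth$overlaps))
  for (f in c(0, 1)) {
    cfg2 <- small_cfg(seed = 67, cistrome_overlap_fraction = f)
    sim2 <- simulate_dataset(cfg2)
    wb2 <- summit_windows(sim2$peaks$summits_b, cfg2$params$summit_flank,
                          sim2$peaks$sizes)
    s2 <- summarize_cistrome_overlap(wb2, sim2$cistrome$cistrome)
    expect_equal(s2$n_subject_overlapping, as.integer(f * cfg2$cistrome_count))
  }
})

test_that("per-region counts match the analytic multinomial expectation", {
  cfg <- small_cfg(seed = 68, n_dar = 0)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  fr <- simulate_fragments(cfg, pk)
  w <- (pk$truth$end - pk$truth$start) * cfg$peak_enrichment
  total <- sum(w[pk$truth$in_a]) +
    (cfg$chrom_length - sum(pk$truth$end[pk$truth$in_a] -
                              pk$truth$start[pk$truth$in_a]))
  expected <- cfg$depth * w[pk$truth$in_a] / total
  sig <- count_in_regions(pk$truth[pk$truth$in_a, c("chrom", "start", "end")],
                          fr$cuts["vehicle_rep1"], "vehicle")
  obs <- as.numeric(sig$counts[, 1])
  # each count is Binomial(depth, w_i / total); allow 5 sigma
  sd <- sqrt(expected * (1 - w[pk$truth$in_a] / total))
  expect_true(all(abs(obs - expected) <= 5 * sd + 3))
  # pooled in-peak fraction is close to its expectation
  expect_equal(sum(obs) / cfg$depth, sum(expected) / cfg$depth,
               tolerance = 0.05)
})

test_that("down-sampling then counting matches binomial thinning in expectation", {
  cfg <- small_cfg(seed = 69)
  pk <- simulate_peaks(cfg, simulate_annotation(cfg))
  fr <- simulate_fragments(cfg, pk)
  cuts <- fr$cuts$vehicle_rep1
  regions <- pk$truth[pk$truth$in_a, c("chrom", "start", "end")]
  full <- count_in_regions(regions, list(s = cuts), "vehicle")$counts[, 1]
  frac <- 0.3
  sub <- vapply(1:30, function(s) {
    d <- downsample_fragments(cuts, round(frac * nrow(cuts)), seed = s)
    count_in_regions(regions, list(s = d), "vehicle")$counts[, 1]
  }, numeric(nrow(regions)))
  expect_equal(mean(rowMeans(sub)), frac * mean(full), tolerance = 0.02)
})
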