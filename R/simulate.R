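# Seeded synthetic-data generator. Emits every input the workflow consumes
# (annotation, two-condition peak/summit sets, per-sample cut sites, a DEG
# list, a cistrome peak set) with recorded ground truth, so each analysis
# stage has an exact or statistical oracle. Placement is slot-based with
# guaranteed spacing: within-condition summit windows never overlap, peaks
# never merge across slots, and condition-specific windows never touch the
# other condition's windows, which makes planted shared / overlap / linkage
# fractions exactly recoverable.

#' Simulation configuration
#'
#' Defaults are desk-scale: a 2 x 5 Mb genome, 300 genes, 2,000 peaks per
#' condition with 80% shared summits, 3 + 3 replicates at 500,000 cut sites
#' each, 5-fold in-peak enrichment, and 100 planted differential regions at
#' log2FC 3.
#'
#' @param seed integer master seed; every generator draw derives from it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes,exons_per_gene annotation shape.
#' @param n_peaks peaks per condition.
#' @param shared_fraction fraction of summits identical between conditions.
#' @param peak_width bp per peak interval.
#' @param n_replicates replicates per condition.
#' @param depth cut sites per sample.
#' @param peak_enrichment per-bp enrichment of peak over background mass.
#' @param n_dar shared peaks planted as differential (treated mass scaled
#'   by `2^dar_log2fc`).
#' @param dar_log2fc planted effect size (log2).
#' @param deg_count genes on the differential expression list.
#' @param deg_linked_fraction fraction of DEGs guaranteed a peak annotating
#'   to them within `tss_range`; the rest are guaranteed none.
#' @param cistrome_count cistrome peaks.
#' @param cistrome_overlap_fraction fraction of cistrome peaks placed over a
#'   treated summit window.
#' @param params an [analysis_params()] list (merge gap, summit flank, TSS
#'   range, cut width are taken from here).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 5e6,
                       n_genes = 300L, exons_per_gene = 3L,
                       n_peaks = 2000L, shared_fraction = 0.8,
                       peak_width = 300L, n_replicates = 3L, depth = 5e5,
                       peak_enrichment = 5, n_dar = 100L, dar_log2fc = 3,
                       deg_count = 200L, deg_linked_fraction = 0.8,
                       cistrome_count = 500L,
                       cistrome_overlap_fraction = 0.6,
                       params = analysis_params()) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_peaks = as.integer(n_peaks),
              shared_fraction = shared_fraction,
              peak_width = as.integer(peak_width),
              n_replicates = as.integer(n_replicates),
              depth = as.integer(depth),
              peak_enrichment = peak_enrichment,
              n_dar = as.integer(n_dar), dar_log2fc = dar_log2fc,
              deg_count = as.integer(deg_count),
              deg_linked_fraction = deg_linked_fraction,
              cistrome_count = as.integer(cistrome_count),
              cistrome_overlap_fraction = cistrome_overlap_fraction,
              params = params)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= 1000,
            cfg$n_genes >= 0, cfg$exons_per_gene >= 1,
            cfg$n_peaks >= 1, cfg$peak_width >= 50,
            cfg$n_replicates >= 1, cfg$depth >= 0,
            cfg$peak_enrichment > 0, cfg$n_dar >= 0,
            cfg$deg_count >= 0, cfg$cistrome_count >= 0)
  if (shared_fraction < 0 || shared_fraction > 1 ||
      deg_linked_fraction < 0 || deg_linked_fraction > 1 ||
      cistrome_overlap_fraction < 0 || cistrome_overlap_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

.sim_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

# fixed gene geometry: 200 bp exons separated by 800 bp introns
.gene_span <- function(exons_per_gene) {
  200L * exons_per_gene + 800L * (exons_per_gene - 1L)
}

#' Generate a synthetic transcript annotation
#'
#' Genes are placed in non-overlapping slots (gene span plus promoter
#' clearance) sampled uniformly over the genome, with alternating strands.
#' Each gene has `exons_per_gene` 200 bp exons separated by 800 bp introns
#' and a CDS that leaves a 100 bp UTR at each end.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (a `transcript_models`) and `sizes`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- .sim_sizes(config)
  span <- .gene_span(config$exons_per_gene)
  slot <- span + 2L * config$params$promoter_flank + 1000L
  per_chrom <- config$chrom_length %/% slot
  total <- per_chrom * config$n_chroms
  if (config$n_genes > total) {
    stop("genes do not fit: need chromosomes of at least ",
         ceiling(config$n_genes / config$n_chroms) * slot, " bp")
  }
  if (config$n_genes == 0L) {
    return(list(transcripts = build_transcript_models(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), type = character(),
                 transcript_id = character(), gene_symbol = character())[0, ]),
      sizes = sizes))
  }
  pick <- with_seed(config$seed + 1L, sort(sample.int(total, config$n_genes)))
  chrom_i <- (pick - 1L) %/% per_chrom + 1L
  slot_i <- (pick - 1L) %% per_chrom
  gstart <- slot_i * slot + config$params$promoter_flank + 500L
  rows <- lapply(seq_len(config$n_genes), function(i) {
    s <- gstart[i]
    ex_start <- s + (seq_len(config$exons_per_gene) - 1L) * 1000L
    exons <- cbind(start = ex_start, end = ex_start + 200L)
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene <- sprintf("GENE%04d", i)
    tx <- sprintf("TX%04d", i)
    feat <- data.frame(
      chrom = paste0("chr", chrom_i[i]),
      start = exons[, "start"], end = exons[, "end"],
      strand = strand, type = "exon",
      transcript_id = tx, gene_symbol = gene,
      stringsAsFactors = FALSE
    )
    cds <- data.frame(
      chrom = paste0("chr", chrom_i[i]),
      start = s + 100L, end = s + span - 100L,
      strand = strand, type = "CDS",
      transcript_id = tx, gene_symbol = gene,
      stringsAsFactors = FALSE
    )
    rbind(feat, cds)
  })
  tm <- build_transcript_models(do.call(rbind, rows))
  list(transcripts = tm, sizes = sizes)
}

# slot geometry for peak placement; guarantees: within- and cross-condition
# summit windows disjoint, inter-peak gaps > merge_gap, summit jitter safe
.peak_slots <- function(config) {
  flank <- config$params$summit_flank
  pslot <- config$peak_width + 2L * flank + config$params$merge_gap + 300L
  per_chrom <- config$chrom_length %/% pslot
  slots <- data.frame(
    chrom = rep(paste0("chr", seq_len(config$n_chroms)), each = per_chrom),
    center = rep(seq_len(per_chrom) - 1L, config$n_chroms) * pslot + pslot %/% 2L,
    stringsAsFactors = FALSE
  )
  list(slots = slots, pslot = pslot)
}

#' Generate two-condition peak and summit sets with known shared fraction
#'
#' `round(shared_fraction * n_peaks)` summit positions are identical between
#' conditions; the remaining summits occupy slots of their own, so a
#' condition-specific window can never overlap the other condition's
#' windows and the planted shared fraction is exactly recoverable by
#' [classify_condition_overlap()]. `n_dar` shared peaks are flagged as
#' planted differential regions. When the configuration requests unlinked
#' DEGs, a contiguous run of genes is reserved and its `tss_range`
#' neighbourhood is excluded from peak placement.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return a `sim_peaks` list: `peaks_a`, `peaks_b` (narrowPeak-style
#'   data.frames), `summits_a`, `summits_b`, `truth` (per-location
#'   data.frame with `shared`, `in_a`, `in_b`, `dar`), `reserved_genes`,
#'   `sizes`, `slot_info` (slot table with usage flags).
#' @export
simulate_peaks <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  tm <- annotation$transcripts
  sizes <- annotation$sizes
  n_shared <- round(config$shared_fraction * config$n_peaks)
  n_spec <- config$n_peaks - n_shared
  if (config$n_dar > n_shared) stop("n_dar cannot exceed the shared peak count")
  n_unlinked <- config$deg_count - round(config$deg_linked_fraction * config$deg_count)
  sl <- .peak_slots(config)
  slots <- sl$slots

  reserved <- character(0)
  if (n_unlinked > 0L) {
    if (nrow(tm) < n_unlinked) {
      stop("cannot reserve ", n_unlinked, " unlinked genes from ",
           nrow(tm), " genes")
    }
    o <- order(tm$chrom, tm$tss, method = "radix")
    ord <- tm[o, c("chrom", "tss", "gene_symbol")]
    runs <- which(vapply(seq_len(nrow(ord) - n_unlinked + 1L), function(i) {
      ord$chrom[i] == ord$chrom[i + n_unlinked - 1L]
    }, TRUE))
    if (!length(runs)) stop("constraints unsatisfiable: no chromosome holds ",
                            n_unlinked, " genes for the unlinked reserve")
    start_i <- with_seed(config$seed + 2L, sample(runs, 1L))
    block <- ord[start_i:(start_i + n_unlinked - 1L), ]
    reserved <- block$gene_symbol
    margin <- config$params$tss_range + sl$pslot
    lo <- min(block$tss) - margin
    hi <- max(block$tss) + margin
    excl <- slots$chrom == block$chrom[1] & slots$center >= lo & slots$center <= hi
    slots <- slots[!excl, , drop = FALSE]
  }

  needed <- n_shared + 2L * n_spec
  if (needed > nrow(slots)) {
    stop("infeasible peak density: need ", needed, " slots, have ", nrow(slots))
  }
  half <- config$peak_width %/% 2L
  drawn <- with_seed(config$seed + 3L, {
    idx <- sample.int(nrow(slots), needed)
    jit <- sample.int(201L, needed, replace = TRUE) - 101L  # -100..100
    list(idx = idx, jit = jit)
  })
  summit <- slots$center[drawn$idx] + drawn$jit
  chrom <- slots$chrom[drawn$idx]
  grp <- rep(c("shared", "a", "b"), c(n_shared, n_spec, n_spec))
  dar_pick <- if (config$n_dar > 0L) {
    with_seed(config$seed + 4L, sample.int(n_shared, config$n_dar))
  } else integer(0)

  truth <- data.frame(
    peak_id = sprintf("peak%05d", seq_len(needed)),
    chrom = chrom,
    start = summit - half,
    end = summit - half + config$peak_width,
    summit = summit,
    shared = grp == "shared",
    in_a = grp != "b",
    in_b = grp != "a",
    dar = seq_len(needed) %in% dar_pick,
    dar_log2fc = ifelse(seq_len(needed) %in% dar_pick, config$dar_log2fc, 0),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$chrom, truth$start, method = "radix"), ]
  rownames(truth) <- NULL

  mk_peaks <- function(flag) {
    d <- truth[truth[[flag]], , drop = FALSE]
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               name = d$peak_id, score = 0, strand = ".",
               signal = 1, p_neglog10 = NA_real_, q_neglog10 = NA_real_,
               summit_offset = d$summit - d$start,
               summit = d$summit, stringsAsFactors = FALSE)
  }
  peaks_a <- mk_peaks("in_a")
  peaks_b <- mk_peaks("in_b")
  slot_info <- sl$slots
  slot_info$used <- paste(slot_info$chrom, slot_info$center) %in%
    paste(slots$chrom[drawn$idx], slots$center[drawn$idx])
  structure(list(
    peaks_a = peaks_a, peaks_b = peaks_b,
    summits_a = peaks_a[, c("chrom", "summit")],
    summits_b = peaks_b[, c("chrom", "summit")],
    truth = truth, reserved_genes = reserved, sizes = sizes,
    slot_info = slot_info, pslot = sl$pslot, config = config
  ), class = "sim_peaks")
}

# uniform positions over the complement of the peak set (per condition)
.sample_background <- function(n, gaps) {
  if (n == 0L) return(gaps[0, c("chrom", "start")])
  w <- gaps$end - gaps$start
  cum <- cumsum(as.numeric(w))
  u <- floor(stats::runif(n) * cum[length(cum)])
  gi <- findInterval(u, c(0, cum[-length(cum)]))
  data.frame(chrom = gaps$chrom[gi],
             start = gaps$start[gi] + as.integer(u - c(0, cum)[gi]),
             stringsAsFactors = FALSE)
}

#' Generate per-sample cut-site sets from planted peak structure
#'
#' Each sample draws `depth` cut sites. A site falls in peak i with
#' probability proportional to `peak_width * peak_enrichment`
#' (times `2^dar_log2fc` for planted differential peaks in treated
#' samples), otherwise uniformly over the non-peak background; positions
#' are uniform within the chosen stratum. Per-region counts are therefore
#' multinomial, hence marginally binomial - the analytic oracle used by
#' the calibration tests.
#'
#' @param config a [sim_config()].
#' @param peaks a `sim_peaks` object.
#' @return list with `cuts` (named list of cut-site data.frames,
#'   `vehicle_rep*` then `treated_rep*`) and `conditions`.
#' @export
simulate_fragments <- function(config, peaks) {
  stopifnot(inherits(config, "sim_config"), inherits(peaks, "sim_peaks"))
  cw <- config$params$cut_width
  sizes <- peaks$sizes
  genome <- data.frame(chrom = names(sizes), start = 0L,
                       end = as.integer(sizes), stringsAsFactors = FALSE)
  conds <- c(rep("vehicle", config$n_replicates),
             rep("treated", config$n_replicates))
  names <- c(paste0("vehicle_rep", seq_len(config$n_replicates)),
             paste0("treated_rep", seq_len(config$n_replicates)))
  cuts <- vector("list", length(conds))
  for (s in seq_along(conds)) {
    cond <- conds[s]
    flag <- if (cond == "vehicle") "in_a" else "in_b"
    pk <- peaks$truth[peaks$truth[[flag]], , drop = FALSE]
    mult <- if (cond == "treated") 2^pk$dar_log2fc else rep(1, nrow(pk))
    w_pk <- (pk$end - pk$start) * config$peak_enrichment * mult
    gaps <- .complement_intervals(pk, genome)
    w_bg <- sum(as.numeric(gaps$end - gaps$start))
    probs <- c(w_pk, w_bg)
    cuts[[s]] <- with_seed(config$seed + 10L + s, {
      n_comp <- as.integer(stats::rmultinom(1, config$depth, probs))
      idx <- rep.int(seq_len(nrow(pk)), n_comp[seq_len(nrow(pk))])
      pos_pk <- data.frame(
        chrom = pk$chrom[idx],
        start = pk$start[idx] + floor(stats::runif(length(idx)) *
                  (pk$end[idx] - pk$start[idx] - cw + 1L)),
        stringsAsFactors = FALSE
      )
      pos_bg <- .sample_background(n_comp[length(probs)], gaps)
      pos <- rbind(pos_pk, pos_bg)
      pos$start <- as.integer(pos$start)
      pos$end <- pmin(as.integer(sizes[pos$chrom]), pos$start + as.integer(cw))
      pos <- pos[order(pos$chrom, pos$start, method = "radix"),
                 c("chrom", "start", "end")]
      rownames(pos) <- NULL
      pos
    })
  }
  names(cuts) <- names
  list(cuts = cuts, conditions = conds)
}

# genome minus an interval set (intervals assumed disjoint after sorting)
.complement_intervals <- function(intervals, genome) {
  pieces <- lapply(seq_len(nrow(genome)), function(g) {
    chr <- genome$chrom[g]
    d <- intervals[intervals$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    bounds <- c(genome$start[g], rbind(d$start, d$end), genome$end[g])
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e > s
    data.frame(chrom = chr, start = as.integer(s[keep]),
               end = as.integer(e[keep]), stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Generate a differential expression gene list with known peak linkage
#'
#' `round(deg_linked_fraction * deg_count)` DEGs are sampled from genes that
#' the generator verifies (by exhaustive nearest-TSS scan over peak
#' midpoints) to be peak-associated within `tss_range`; the remainder come
#' from the reserved gene block around which no peak was placed, so they
#' are guaranteed unassociated.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param peaks a `sim_peaks` object.
#' @return list with `degs` (data.frame `gene, direction`), and `truth`
#'   (logical `linked` per DEG, plus the generator's `genes_a`/`genes_b`
#'   association sets).
#' @export
simulate_degs <- function(config, annotation, peaks) {
  stopifnot(inherits(config, "sim_config"), inherits(peaks, "sim_peaks"))
  tm <- annotation$transcripts
  if (!nrow(tm) && config$deg_count > 0L) stop("no genes to draw DEGs from")
  n_linked <- round(config$deg_linked_fraction * config$deg_count)
  n_unlinked <- config$deg_count - n_linked
  assoc <- function(pk) {
    if (!nrow(pk)) return(character(0))
    mid <- (pk$start + pk$end) %/% 2L
    # exhaustive scan: distance of every peak midpoint to every TSS
    genes <- character(0)
    for (chr in unique(pk$chrom)) {
      m <- mid[pk$chrom == chr]
      tt <- tm[tm$chrom == chr, , drop = FALSE]
      if (!nrow(tt)) next
      d <- abs(outer(m, tt$tss, `-`))
      nearest <- apply(d, 1L, function(row) {
        ok <- which(row <= config$params$tss_range)
        if (!length(ok)) return(NA_integer_)
        ok[order(row[ok], tt$gene_symbol[ok], tt$transcript_id[ok])[1]]
      })
      genes <- c(genes, tt$gene_symbol[nearest[!is.na(nearest)]])
    }
    unique(genes)
  }
  genes_a <- assoc(peaks$peaks_a)
  genes_b <- assoc(peaks$peaks_b)
  pool <- sort(union(genes_a, genes_b), method = "radix")
  pool <- setdiff(pool, peaks$reserved_genes)
  if (n_linked > length(pool)) {
    stop("constraints unsatisfiable: only ", length(pool),
         " peak-associated genes for ", n_linked, " linked DEGs")
  }
  if (n_unlinked > length(peaks$reserved_genes)) {
    stop("constraints unsatisfiable: reserved gene block too small")
  }
  drawn <- with_seed(config$seed + 5L, {
    linked <- sample(pool, n_linked)
    unlinked <- if (n_unlinked > 0L) sample(peaks$reserved_genes, n_unlinked)
                else character(0)
    dir <- sample(c("up", "down"), n_linked + n_unlinked, replace = TRUE)
    list(gene = c(linked, unlinked), dir = dir)
  })
  linked_flag <- c(rep(TRUE, n_linked), rep(FALSE, n_unlinked))
  o <- order(drawn$gene, method = "radix")
  list(
    degs = data.frame(gene = drawn$gene[o], direction = drawn$dir[o],
                      stringsAsFactors = FALSE),
    truth = list(linked = setNames(linked_flag[o], drawn$gene[o]),
                 genes_a = genes_a, genes_b = genes_b)
  )
}

#' Generate a cistrome peak set with known accessibility overlap
#'
#' `round(cistrome_overlap_fraction * cistrome_count)` cistrome peaks are
#' centered on distinct treated-condition summits (certain window overlap);
#' the rest sit at centers of unused placement slots, guaranteeing
#' clearance from every summit window. Exactly recoverable by
#' [summarize_cistrome_overlap()].
#'
#' @param config a [sim_config()].
#' @param peaks a `sim_peaks` object.
#' @return list with `cistrome` (data.frame `chrom, start, end, name`) and
#'   `truth` (logical `overlaps` per cistrome peak).
#' @export
simulate_cistrome <- function(config, peaks) {
  stopifnot(inherits(config, "sim_config"), inherits(peaks, "sim_peaks"))
  n_ov <- round(config$cistrome_overlap_fraction * config$cistrome_count)
  n_non <- config$cistrome_count - n_ov
  nb <- nrow(peaks$summits_b)
  if (n_ov > nb) {
    stop("infeasible: ", n_ov, " overlapping cistrome peaks but only ",
         nb, " treated summits")
  }
  free <- peaks$slot_info[!peaks$slot_info$used, , drop = FALSE]
  if (n_non > nrow(free)) {
    stop("infeasible cistrome density: need ", n_non,
         " free slots, have ", nrow(free))
  }
  half <- 150L
  drawn <- with_seed(config$seed + 6L, {
    ov_i <- if (n_ov > 0L) sample.int(nb, n_ov) else integer(0)
    fr_i <- if (n_non > 0L) sample.int(nrow(free), n_non) else integer(0)
    list(ov = ov_i, fr = fr_i)
  })
  ov <- data.frame(chrom = peaks$summits_b$chrom[drawn$ov],
                   center = peaks$summits_b$summit[drawn$ov],
                   overlaps = rep(TRUE, length(drawn$ov)),
                   stringsAsFactors = FALSE)
  non <- data.frame(chrom = free$chrom[drawn$fr],
                    center = free$center[drawn$fr],
                    overlaps = rep(FALSE, length(drawn$fr)),
                    stringsAsFactors = FALSE)
  all <- rbind(ov, non)
  all <- all[order(all$chrom, all$center, method = "radix"), ]
  cistrome <- data.frame(chrom = all$chrom,
                         start = as.integer(all$center - half),
                         end = as.integer(all$center + half),
                         name = sprintf("cistrome%05d", seq_len(nrow(all))),
                         stringsAsFactors = FALSE)
  list(cistrome = cistrome, truth = list(overlaps = all$overlaps))
}

#' Run the full generator, optionally writing every file format
#'
#' @param config a [sim_config()].
#' @param dir when non-NULL, write `annotation.gtf`, `chrom.sizes`,
#'   `peaks_{vehicle,treated}.narrowPeak`, `summits_{vehicle,treated}.bed`,
#'   per-sample `cuts_*.bed`, `degs.tsv`, `cistrome.bed`, and
#'   `truth_peaks.tsv` into it.
#' @return list with `annotation`, `peaks`, `fragments`, `degs`,
#'   `cistrome`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  ann <- simulate_annotation(config)
  pk <- simulate_peaks(config, ann)
  fr <- simulate_fragments(config, pk)
  dg <- simulate_degs(config, ann, pk)
  ci <- simulate_cistrome(config, pk)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gtf(ann$transcripts, file.path(dir, "annotation.gtf"))
    write_chrom_sizes(ann$sizes, file.path(dir, "chrom.sizes"))
    write_peaks(pk$peaks_a, file.path(dir, "peaks_vehicle.narrowPeak"),
                format = "narrowPeak")
    write_peaks(pk$peaks_b, file.path(dir, "peaks_treated.narrowPeak"),
                format = "narrowPeak")
    sa <- data.frame(chrom = pk$summits_a$chrom, start = pk$summits_a$summit,
                     end = pk$summits_a$summit + 1L)
    sb <- data.frame(chrom = pk$summits_b$chrom, start = pk$summits_b$summit,
                     end = pk$summits_b$summit + 1L)
    write_peaks(sa, file.path(dir, "summits_vehicle.bed"))
    write_peaks(sb, file.path(dir, "summits_treated.bed"))
    for (nm in names(fr$cuts)) {
      write_peaks(fr$cuts[[nm]], file.path(dir, paste0("cuts_", nm, ".bed")))
    }
    write_table(dg$degs, file.path(dir, "degs.tsv"))
    write_peaks(ci$cistrome, file.path(dir, "cistrome.bed"))
    write_table(pk$truth, file.path(dir, "truth_peaks.tsv"))
  }
  list(annotation = ann, peaks = pk, fragments = fr, degs = dg,
       cistrome = ci, config = config)
}
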