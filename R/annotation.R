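# Prioritized genomic-feature annotation: each peak midpoint is classified
# against promoter / 5'UTR / 3'UTR / exon / intron intervals derived from
# transcript models, with priority promoter > utr5 > utr3 > exon > intron
# and intergenic as the fallback. Gene assignment is by nearest TSS and is
# independent of the feature class.

FEATURE_CLASSES <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")

#' Build a queryable genomic-feature index from transcript models
#'
#' Per transcript the derived intervals are: promoter = TSS +/-
#' `promoter_flank` (clipped to the chromosome when sizes are given); 5'UTR
#' and 3'UTR from explicit UTR features or the exon-minus-CDS difference;
#' exon = all exon bp; intron = gene span minus exons.
#'
#' @param transcripts a `transcript_models` object.
#' @param promoter_flank bp each side of the TSS (default 2000).
#' @param sizes optional named chromosome lengths used to clip promoters.
#' @return a `feature_index`: data.frame of intervals with columns
#'   `chrom, start, end, class, gene_symbol, transcript_id`.
#' @export
build_feature_models <- function(transcripts, promoter_flank = 2000,
                                 sizes = NULL) {
  stopifnot(inherits(transcripts, "transcript_models"), promoter_flank > 0)
  .check_sizes(sizes)
  pieces <- lapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    len <- if (!is.null(sizes)) unname(sizes[t$chrom]) else Inf
    add <- function(class, s, e) {
      s <- pmax(0, s); e <- pmin(len, e)
      keep <- e > s
      if (!any(keep)) return(NULL)
      data.frame(chrom = t$chrom, start = as.integer(s[keep]),
                 end = as.integer(e[keep]), class = class,
                 gene_symbol = t$gene_symbol, transcript_id = t$transcript_id,
                 stringsAsFactors = FALSE)
    }
    ex <- t$exons[[1]]
    introns <- if (nrow(ex) > 1L) {
      cbind(start = ex[-nrow(ex), "end"], end = ex[-1L, "start"])
    } else cbind(start = integer(0), end = integer(0))
    u5 <- t$utr5[[1]]; u3 <- t$utr3[[1]]
    rbind(
      add("promoter", t$tss - promoter_flank, t$tss + promoter_flank),
      if (nrow(u5)) add("utr5", u5[, "start"], u5[, "end"]),
      if (nrow(u3)) add("utr3", u3[, "start"], u3[, "end"]),
      add("exon", ex[, "start"], ex[, "end"]),
      if (nrow(introns)) add("intron", introns[, "start"], introns[, "end"])
    )
  })
  idx <- do.call(rbind, pieces)
  if (is.null(idx)) {
    idx <- data.frame(chrom = character(), start = integer(), end = integer(),
                      class = character(), gene_symbol = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  }
  structure(idx, class = c("feature_index", "data.frame"),
            promoter_flank = promoter_flank)
}

#' Annotate peaks with a prioritized feature class and nearest gene
#'
#' Classification uses the peak midpoint `floor((start + end) / 2)`: every
#' feature interval containing the midpoint is collected and the
#' highest-priority class wins (promoter > 5'UTR > 3'UTR > exon > intron);
#' a midpoint contained in none is intergenic. When several transcripts
#' supply the winning class, the lexicographically smallest gene symbol is
#' reported as `feature_gene`. Independently, the nearest TSS within
#' `tss_range` provides `gene_symbol`, `transcript_id` and the signed
#' `tss_distance` (NA when no TSS is in range), regardless of class.
#'
#' @param peaks data.frame of peaks (`chrom, start, end`, extra columns kept).
#' @param index a `feature_index` from [build_feature_models()].
#' @param transcripts the `transcript_models` the index was built from.
#' @param tss_range bp for nearest-TSS assignment (default 100000).
#' @return the input peaks with columns `midpoint, feature_class,
#'   feature_gene, gene_symbol, transcript_id, tss_distance` appended.
#' @export
annotate_peaks <- function(peaks, index, transcripts, tss_range = 100000) {
  .check_intervals(peaks, "peaks")
  stopifnot(inherits(index, "feature_index"))
  n <- nrow(peaks)
  mid <- (peaks$start + peaks$end) %/% 2L
  cls <- rep("intergenic", n)
  fgene <- rep(NA_character_, n)
  if (n && nrow(index)) {
    qry <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(mid + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(qry, .as_granges(index),
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      rank <- match(index$class[si], FEATURE_CLASSES)
      o <- order(qi, rank, index$gene_symbol[si], index$transcript_id[si],
                 method = "radix")
      qi <- qi[o]; si <- si[o]
      first <- !duplicated(qi)
      cls[qi[first]] <- index$class[si[first]]
      fgene[qi[first]] <- index$gene_symbol[si[first]]
    }
  }
  nt <- nearest_tss(peaks, transcripts, tss_range = tss_range)
  out <- peaks
  out$midpoint <- as.integer(mid)
  out$feature_class <- cls
  out$feature_gene <- fgene
  out$gene_symbol <- nt$gene_symbol
  out$transcript_id <- nt$transcript_id
  out$tss_distance <- nt$tss_distance
  out
}

#' Distribution of peaks over the six feature classes
#'
#' @param annotations data.frame from [annotate_peaks()] (needs
#'   `feature_class`).
#' @return list with `counts` and `fractions`, both named vectors over
#'   promoter, utr5, utr3, exon, intron, intergenic; fractions sum to 1.
#' @export
feature_distribution <- function(annotations) {
  stopifnot(is.data.frame(annotations), "feature_class" %in% names(annotations))
  if (!nrow(annotations)) stop("no annotations to summarize")
  bad <- setdiff(unique(annotations$feature_class), FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ", "))
  counts <- table(factor(annotations$feature_class, levels = FEATURE_CLASSES))
  counts <- setNames(as.integer(counts), FEATURE_CLASSES)
  list(counts = counts, fractions = counts / sum(counts))
}
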