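# Interval algebra shared by every downstream stage. All coordinates are
# 0-based half-open; strand is ignored for merging and overlap and used only
# to sign TSS distances.

#' Analysis parameters
#'
#' Collects the tunable distances and thresholds of the workflow with their
#' defaults: peak merging gap 100 bp, summit windows +/-100 bp (fixed 200 bp),
#' nearest-TSS search range 100 kb, promoter TSS +/-2 kb, profile flank 2 kb
#' with 10 bp bins, 9 bp Tn5 cut sites, down-sampling depth 100 million
#' reads, and DAR calling at adjusted p < 0.05 with |log2FC| >= 1.
#'
#' @param merge_gap bp; peaks closer than or equal to this merge.
#' @param summit_flank bp added on each side of a summit.
#' @param tss_range bp; maximum anchor-to-TSS distance for gene assignment.
#' @param promoter_flank bp on each side of the TSS.
#' @param profile_flank bp on each side of a profile anchor.
#' @param bin_size bp per profile bin.
#' @param cut_width bp of read 5' end used as the accessibility signal.
#' @param downsample_n target read count for library down-sampling.
#' @param dar_adj_p adjusted p-value threshold for DAR calling.
#' @param dar_abs_log2fc absolute log2 fold-change threshold for DAR calling.
#' @return a named list of class `analysis_params`.
#' @export
analysis_params <- function(merge_gap = 100, summit_flank = 100,
                            tss_range = 100000, promoter_flank = 2000,
                            profile_flank = 2000, bin_size = 10,
                            cut_width = 9, downsample_n = 1e8,
                            dar_adj_p = 0.05, dar_abs_log2fc = 1.0) {
  p <- list(merge_gap = merge_gap, summit_flank = summit_flank,
            tss_range = tss_range, promoter_flank = promoter_flank,
            profile_flank = profile_flank, bin_size = bin_size,
            cut_width = cut_width, downsample_n = downsample_n,
            dar_adj_p = dar_adj_p, dar_abs_log2fc = dar_abs_log2fc)
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  stopifnot(summit_flank > 0, tss_range > 0, promoter_flank > 0,
            profile_flank > 0, bin_size > 0, cut_width >= 1,
            downsample_n > 0, dar_abs_log2fc >= 0)
  if (dar_adj_p <= 0 || dar_adj_p > 1) stop("dar_adj_p must be in (0, 1]")
  structure(p, class = "analysis_params")
}

#' Merge intervals within a gap
#'
#' Intervals on the same chromosome whose gap (`next start - previous end`)
#' is at most `max_gap` are merged, i.e. touching intervals and intervals
#' exactly `max_gap` bp apart both merge. Strand is ignored. Output is
#' sorted by (chrom, start).
#'
#' @param intervals data.frame with `chrom, start, end` (may be unsorted and
#'   overlapping).
#' @param max_gap maximum gap in bp (default 100).
#' @return merged data.frame `chrom, start, end`.
#' @export
merge_intervals <- function(intervals, max_gap = 100) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  .check_intervals(intervals)
  if (!nrow(intervals)) return(.empty_intervals())
  gr <- GenomicRanges::reduce(.as_granges(intervals),
                              min.gapwidth = max_gap + 1L,
                              ignore.strand = TRUE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  .sort_intervals(out)
}

#' Fixed windows centered on summits
#'
#' Each summit position becomes the interval
#' `[summit - flank, summit + flank)`, clipped to the chromosome, giving a
#' fixed `2 * flank` window except at chromosome edges.
#'
#' @param summits data.frame with `chrom` and `summit` (bp positions).
#' @param flank bp on each side (default 100, i.e. 200 bp windows).
#' @param sizes named chromosome lengths (required; windows are clipped and
#'   summits are validated against it).
#' @return data.frame `chrom, start, end, summit`.
#' @export
summit_windows <- function(summits, flank = 100, sizes) {
  stopifnot(is.data.frame(summits), flank > 0)
  .check_sizes(sizes)
  if (!nrow(summits)) {
    out <- .empty_intervals()
    out$summit <- integer()
    return(out)
  }
  .check_chroms_known(summits$chrom, sizes, "summits")
  len <- sizes[summits$chrom]
  if (any(is.na(summits$summit)) || any(summits$summit < 0) ||
      any(summits$summit >= len)) {
    stop("summit position outside chromosome")
  }
  data.frame(chrom = summits$chrom,
             start = as.integer(pmax(0, summits$summit - flank)),
             end = as.integer(pmin(len, summits$summit + flank)),
             summit = as.integer(summits$summit),
             stringsAsFactors = FALSE)
}

#' All overlapping query/subject interval pairs
#'
#' A pair `(i, j)` is reported iff `query[i]` and `subject[j]` share at least
#' one bp on the same chromosome. Pairs are ordered by query index then
#' subject index. Strand is ignored.
#'
#' @param query,subject interval data.frames (`chrom, start, end`).
#' @return data.frame `query, subject` of 1-based row indices.
#' @export
overlap_pairs <- function(query, subject) {
  .check_intervals(query, "query")
  .check_intervals(subject, "subject")
  if (!nrow(query) || !nrow(subject)) {
    return(data.frame(query = integer(), subject = integer()))
  }
  # findOverlaps warns when the two sets share no chromosome names; for
  # plain coordinate bookkeeping that is a legitimate empty result
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject),
                                minoverlap = 1L, ignore.strand = TRUE)
  )
  out <- data.frame(query = S4Vectors::queryHits(hits),
                    subject = S4Vectors::subjectHits(hits))
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Nearest TSS within range
#'
#' For each region the anchor is the midpoint `floor((start + end) / 2)`.
#' The transcript minimizing `|anchor - TSS|` is returned when that distance
#' is at most `tss_range`; otherwise the row is `NA`. Distance is signed in
#' the transcription direction: positive means the anchor lies downstream of
#' the TSS, negative upstream. Ties are broken by smaller absolute distance,
#' then lexicographic gene symbol, then transcript id.
#'
#' @param regions interval data.frame (`chrom, start, end`).
#' @param transcripts a `transcript_models` object.
#' @param tss_range maximum absolute distance in bp (default 100000).
#' @return data.frame with one row per region: `gene_symbol, transcript_id,
#'   tss_distance`.
#' @export
nearest_tss <- function(regions, transcripts, tss_range = 100000) {
  .check_intervals(regions, "regions")
  stopifnot(inherits(transcripts, "transcript_models"), tss_range > 0)
  n <- nrow(regions)
  out <- data.frame(gene_symbol = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    tss_distance = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (!n || !nrow(transcripts)) return(out)
  anchor <- (regions$start + regions$end) %/% 2L
  qry <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(anchor + 1L, width = 1L))
  sub <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(pmax(0L, transcripts$tss - as.integer(tss_range)) + 1L,
                     transcripts$tss + as.integer(tss_range) + 1L)
  )
  hits <- GenomicRanges::findOverlaps(qry, sub, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(out)
  d_raw <- anchor[qi] - transcripts$tss[si]
  keep <- abs(d_raw) <= tss_range  # window join is inclusive of the clip slack
  qi <- qi[keep]; si <- si[keep]; d_raw <- d_raw[keep]
  if (!length(qi)) return(out)
  signed <- ifelse(transcripts$strand[si] == "+", d_raw, -d_raw)
  o <- order(qi, abs(d_raw), transcripts$gene_symbol[si],
             transcripts$transcript_id[si], method = "radix")
  qi <- qi[o]; si <- si[o]; signed <- signed[o]
  first <- !duplicated(qi)
  out$gene_symbol[qi[first]] <- transcripts$gene_symbol[si[first]]
  out$transcript_id[qi[first]] <- transcripts$transcript_id[si[first]]
  out$tss_distance[qi[first]] <- as.integer(signed[first])
  out
}
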