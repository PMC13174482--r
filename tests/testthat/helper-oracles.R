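# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit scans, no interval trees) so they cannot
# share a bug with the implementation they check.

bf_merge <- function(df, max_gap) {
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  out <- NULL
  for (chr in sort(unique(df$chrom))) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - e <= max_gap) {
        e <- max(e, d$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = chr, start = s, end = e))
        s <- d$start[i]; e <- d$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = chr, start = s, end = e))
  }
  rownames(out) <- NULL
  out
}

bf_overlap_pairs <- function(query, subject) {
  res <- NULL
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] &&
          subject$start[j] < query$end[i]) {
        res <- rbind(res, c(i, j))
      }
    }
  }
  if (is.null(res)) return(data.frame(query = integer(), subject = integer()))
  data.frame(query = res[, 1], subject = res[, 2])
}

bf_nearest_tss <- function(regions, tm, tss_range) {
  n <- nrow(regions)
  out <- data.frame(gene_symbol = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    tss_distance = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    anchor <- (regions$start[i] + regions$end[i]) %/% 2
    best <- NULL
    for (j in seq_len(nrow(tm))) {
      if (tm$chrom[j] != regions$chrom[i]) next
      d <- abs(anchor - tm$tss[j])
      if (d > tss_range) next
      key <- list(d = d, g = tm$gene_symbol[j], t = tm$transcript_id[j], j = j)
      if (is.null(best) || d < best$d ||
          (d == best$d && (key$g < best$g ||
                           (key$g == best$g && key$t < best$t)))) {
        best <- key
      }
    }
    if (!is.null(best)) {
      j <- best$j
      raw <- anchor - tm$tss[j]
      out$gene_symbol[i] <- tm$gene_symbol[j]
      out$transcript_id[i] <- tm$transcript_id[j]
      out$tss_distance[i] <- if (tm$strand[j] == "+") raw else -raw
    }
  }
  out
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(sorted)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# midpoint-against-every-feature annotation oracle
bf_annotate_class <- function(peaks, index) {
  priority <- c("promoter", "utr5", "utr3", "exon", "intron")
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2
    hit <- character(0)
    for (j in seq_len(nrow(index))) {
      if (index$chrom[j] == peaks$chrom[i] &&
          mid >= index$start[j] && mid < index$end[j]) {
        hit <- c(hit, index$class[j])
      }
    }
    for (cl in priority) if (cl %in% hit) return(cl)
    "intergenic"
  }, "")
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                             max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small deterministic transcript set built without the GTF reader
toy_transcripts <- function() {
  feats <- rbind(
    data.frame(chrom = "chr1", start = c(10000L, 12000L), end = c(10200L, 12500L),
               strand = "+", type = "exon", transcript_id = "TXA",
               gene_symbol = "GENEA"),
    data.frame(chrom = "chr1", start = 10100L, end = 12300L,
               strand = "+", type = "CDS", transcript_id = "TXA",
               gene_symbol = "GENEA"),
    data.frame(chrom = "chr1", start = c(30000L, 31000L), end = c(30400L, 31500L),
               strand = "-", type = "exon", transcript_id = "TXB",
               gene_symbol = "GENEB")
  )
  peaklink:::build_transcript_models(feats)
}
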