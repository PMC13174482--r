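# Transcript models: strand-aware gene structures (TSS, exons, CDS bounds,
# UTRs) parsed from refGene-style GTF that carries explicit 5UTR/3UTR rows,
# or with UTRs derived from the exon-minus-CDS set difference.

#' Read transcript models from a GTF file
#'
#' Parses exon, CDS, and (when present) 5UTR/3UTR features grouped by
#' `transcript_id`. GTF 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention (`start - 1`, `end` unchanged).
#' The TSS is the 5'-most transcribed position: the span start on the plus
#' strand, the span end on the minus strand. When explicit UTR rows are
#' absent but a CDS is present, UTR intervals are derived as exon bp outside
#' the CDS span, oriented by strand.
#'
#' @param path GTF file path.
#' @return a `transcript_models` data.frame with one row per transcript:
#'   `transcript_id, gene_symbol, chrom, strand, start, end, tss,
#'   cds_start, cds_end` plus list columns `exons`, `utr5`, `utr3`
#'   (two-column start/end matrices, 0-based half-open).
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  keep <- type %in% c("exon", "CDS", "5UTR", "3UTR",
                      "five_prime_utr", "three_prime_utr")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  type[type == "five_prime_utr"] <- "5UTR"
  type[type == "three_prime_utr"] <- "3UTR"
  tid <- as.character(meta$transcript_id)
  gene <- if (!is.null(meta$gene_name)) as.character(meta$gene_name) else
    as.character(meta$gene_id)
  if (any(is.na(tid))) stop("GTF feature without transcript_id")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, transcript_id = tid, gene_symbol = gene,
    stringsAsFactors = FALSE
  )
  build_transcript_models(df)
}

# assemble transcript_models from a long feature table (internal; also used
# by tests to build models without touching the filesystem)
build_transcript_models <- function(df) {
  ids <- unique(df$transcript_id)
  rows <- lapply(ids, function(id) {
    d <- df[df$transcript_id == id, , drop = FALSE]
    ex <- d[d$type == "exon", , drop = FALSE]
    if (!nrow(ex)) stop("transcript ", id, " has no exon feature")
    if (length(unique(d$strand)) != 1L || !d$strand[1] %in% c("+", "-")) {
      stop("transcript ", id, ": inconsistent or missing strand")
    }
    if (length(unique(d$chrom)) != 1L) {
      stop("transcript ", id, ": features on multiple chromosomes")
    }
    strand <- d$strand[1]
    o <- order(ex$start)
    exons <- cbind(start = ex$start[o], end = ex$end[o])
    if (nrow(exons) > 1L && any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
      stop("transcript ", id, ": overlapping exons")
    }
    span <- c(exons[1L, "start"], exons[nrow(exons), "end"])
    cds <- d[d$type == "CDS", , drop = FALSE]
    cds_start <- if (nrow(cds)) min(cds$start) else NA_integer_
    cds_end <- if (nrow(cds)) max(cds$end) else NA_integer_
    pick <- function(ty) {
      u <- d[d$type == ty, , drop = FALSE]
      if (nrow(u)) cbind(start = sort(u$start), end = u$end[order(u$start)]) else NULL
    }
    utr5 <- pick("5UTR")
    utr3 <- pick("3UTR")
    if (is.null(utr5) && is.null(utr3) && !is.na(cds_start)) {
      u <- derive_utrs(exons, cds_start, cds_end, strand)
      utr5 <- u$utr5
      utr3 <- u$utr3
    }
    empty <- cbind(start = integer(0), end = integer(0))
    list(transcript_id = id, gene_symbol = d$gene_symbol[1],
         chrom = d$chrom[1], strand = strand,
         start = span[1], end = span[2],
         tss = if (strand == "+") span[1] else span[2],
         cds_start = cds_start, cds_end = cds_end,
         exons = exons,
         utr5 = if (is.null(utr5)) empty else utr5,
         utr3 = if (is.null(utr3)) empty else utr3)
  })
  out <- data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_symbol = vapply(rows, `[[`, "", "gene_symbol"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = as.integer(vapply(rows, function(r) as.numeric(r$start), 1)),
    end = as.integer(vapply(rows, function(r) as.numeric(r$end), 1)),
    tss = as.integer(vapply(rows, function(r) as.numeric(r$tss), 1)),
    cds_start = as.integer(vapply(rows, function(r) as.numeric(r$cds_start), 1)),
    cds_end = as.integer(vapply(rows, function(r) as.numeric(r$cds_end), 1)),
    stringsAsFactors = FALSE
  )
  out$exons <- I(lapply(rows, `[[`, "exons"))
  out$utr5 <- I(lapply(rows, `[[`, "utr5"))
  out$utr3 <- I(lapply(rows, `[[`, "utr3"))
  class(out) <- c("transcript_models", "data.frame")
  out
}

# exon bp left/right of the CDS span, assigned to 5'/3' UTR by strand
derive_utrs <- function(exons, cds_start, cds_end, strand) {
  clip <- function(lo, hi) {
    s <- pmax(exons[, "start"], lo)
    e <- pmin(exons[, "end"], hi)
    keep <- e > s
    if (!any(keep)) NULL else cbind(start = s[keep], end = e[keep])
  }
  left <- clip(-Inf, cds_start)
  right <- clip(cds_end, Inf)
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Write transcript models as GTF
#'
#' Emits exon, CDS (when present) and 5UTR/3UTR rows, converting back to
#' 1-based inclusive GTF coordinates.
#'
#' @param transcripts a `transcript_models` object.
#' @param path output path.
#' @param source source field for column 2 (default "peaklink").
#' @export
write_gtf <- function(transcripts, path, source = "peaklink") {
  stopifnot(inherits(transcripts, "transcript_models"))
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     t$gene_symbol, t$transcript_id, t$gene_symbol)
    emit <- function(type, mat) {
      if (is.null(mat) || !nrow(mat)) return(character(0))
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, source, type, as.integer(mat[, "start"]) + 1L,
              as.integer(mat[, "end"]), t$strand, attrs)
    }
    ex <- t$exons[[1]]
    cds <- if (!is.na(t$cds_start)) {
      # CDS restricted to exon bp
      s <- pmax(ex[, "start"], t$cds_start)
      e <- pmin(ex[, "end"], t$cds_end)
      keep <- e > s
      if (any(keep)) cbind(start = s[keep], end = e[keep]) else NULL
    } else NULL
    lines <- c(lines, emit("exon", ex), emit("CDS", cds),
               emit("5UTR", t$utr5[[1]]), emit("3UTR", t$utr3[[1]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate transcript model invariants
#'
#' Checks sorted non-overlapping exons, TSS at the strand-correct span
#' boundary, and CDS bounds inside the exon span.
#'
#' @param transcripts a `transcript_models` object.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_transcripts <- function(transcripts) {
  stopifnot(inherits(transcripts, "transcript_models"))
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    ex <- t$exons[[1]]
    if (!nrow(ex)) stop(t$transcript_id, ": no exons")
    if (any(ex[, "end"] <= ex[, "start"])) stop(t$transcript_id, ": empty exon")
    if (is.unsorted(ex[, "start"])) stop(t$transcript_id, ": exons unsorted")
    if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"])) {
      stop(t$transcript_id, ": overlapping exons")
    }
    want <- if (t$strand == "+") ex[1L, "start"] else ex[nrow(ex), "end"]
    if (t$tss != want) stop(t$transcript_id, ": tss not at 5' span boundary")
    if (!is.na(t$cds_start) &&
        (t$cds_start < t$start || t$cds_end > t$end)) {
      stop(t$transcript_id, ": CDS outside exon span")
    }
  }
  invisible(TRUE)
}
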