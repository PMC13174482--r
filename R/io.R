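# Readers and writers for the plain-text formats the workflow touches.
# Internal convention everywhere: 0-based half-open coordinates (as in BED);
# GTF is converted on read (start - 1) and back on write.

#' Read a chromosome sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("malformed chrom sizes line ", bad[1])
  sizes <- as.integer(vapply(parts, `[[`, "", 2L))
  names(sizes) <- vapply(parts, `[[`, "", 1L)
  .check_sizes(sizes)
  sizes
}

#' Write a chromosome sizes file
#'
#' @param sizes named integer vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  .check_sizes(sizes)
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

.split_fields <- function(lines) {
  # tolerate space- or tab-separated records
  strsplit(trimws(lines), "[ \t]+")
}

.num_or_na <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Read peaks from BED or ENCODE narrowPeak
#'
#' BED is natively 0-based half-open and is passed through unchanged.
#' narrowPeak column 10 is the summit offset from `start`; `-1` means the
#' summit is unknown and maps to `NA`. The absolute summit position
#' (`start + summit_offset`) is returned in column `summit`.
#'
#' @param path file path.
#' @param format `"auto"` (decide from column count: 10 columns means
#'   narrowPeak), `"bed"`, or `"narrowPeak"`.
#' @param sizes optional named chromosome lengths; when given, records on
#'   unknown chromosomes or extending past the chromosome end are an error.
#' @return data.frame with columns `chrom, start, end, name, score, strand,
#'   signal, p_neglog10, q_neglog10, summit_offset, summit`. Missing optional
#'   fields are `NA`.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       sizes = NULL) {
  format <- match.arg(format)
  .check_sizes(sizes)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  parts <- .split_fields(lines[keep])
  if (!length(parts)) {
    return(cbind(.empty_intervals(),
                 data.frame(name = character(), score = numeric(),
                            strand = character(), signal = numeric(),
                            p_neglog10 = numeric(), q_neglog10 = numeric(),
                            summit_offset = integer(), summit = integer())))
  }
  nf <- vapply(parts, length, 1L)
  if (format == "auto") format <- if (all(nf == 10L)) "narrowPeak" else "bed"
  minf <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < minf)
  if (length(bad)) {
    stop("malformed ", format, " line ", lineno[bad[1]], ": expected >= ",
         minf, " fields, got ", nf[bad[1]])
  }
  if (format == "narrowPeak" && any(nf != 10L)) {
    stop("malformed narrowPeak line ", lineno[which(nf != 10L)[1]],
         ": expected exactly 10 fields")
  }
  fld <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  chrom <- fld(1)
  start <- .num_or_na(fld(2))
  end <- .num_or_na(fld(3))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": end <= start")
  }
  df <- data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
                   name = fld(4), score = .num_or_na(fld(5)), strand = fld(6),
                   stringsAsFactors = FALSE)
  df$strand[is.na(df$strand)] <- "."
  if (format == "narrowPeak") {
    df$signal <- .num_or_na(fld(7))
    df$p_neglog10 <- .num_or_na(fld(8))
    df$q_neglog10 <- .num_or_na(fld(9))
    off <- as.integer(.num_or_na(fld(10)))
    off[!is.na(off) & off < 0L] <- NA_integer_
    df$summit_offset <- off
    bad <- which(!is.na(off) & df$start + off >= df$end)
    if (length(bad)) stop("line ", lineno[bad[1]], ": summit offset outside peak")
  } else {
    df$signal <- NA_real_
    df$p_neglog10 <- NA_real_
    df$q_neglog10 <- NA_real_
    df$summit_offset <- NA_integer_
  }
  df$summit <- df$start + df$summit_offset
  if (!is.null(sizes)) {
    .check_chroms_known(df$chrom, sizes, where = path)
    bad <- which(df$end > sizes[df$chrom] | df$start < 0L)
    if (length(bad)) stop("line ", lineno[bad[1]], ": interval outside chromosome")
  }
  df
}

#' Write peaks as BED or narrowPeak
#'
#' @param peaks data.frame as returned by [read_peaks()]; for BED output only
#'   `chrom`, `start`, `end` are required.
#' @param path output path.
#' @param format `"bed"` (6 columns when name/score/strand present, else 3)
#'   or `"narrowPeak"`.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  .check_intervals(peaks, "peaks")
  g <- function(col, default) {
    v <- peaks[[col]]
    if (is.null(v)) rep(default, nrow(peaks)) else {
      v[is.na(v)] <- default
      v
    }
  }
  if (format == "bed") {
    if (all(c("name", "score", "strand") %in% names(peaks))) {
      out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                        g("name", "."), g("score", 0), g("strand", "."))
    } else {
      out <- data.frame(peaks$chrom, peaks$start, peaks$end)
    }
  } else {
    off <- peaks$summit_offset
    if (is.null(off)) off <- rep(NA_integer_, nrow(peaks))
    off[is.na(off)] <- -1L
    out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                      g("name", "."), g("score", 0), g("strand", "."),
                      g("signal", 0), g("p_neglog10", -1), g("q_neglog10", -1),
                      off)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' Four columns, 0-based half-open: chrom, start, end, value.
#'
#' @param path file path.
#' @return data.frame with columns `chrom, start, end, value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  parts <- .split_fields(lines[keep])
  if (!length(parts)) {
    out <- .empty_intervals()
    out$value <- numeric()
    return(out)
  }
  nf <- vapply(parts, length, 1L)
  bad <- which(nf < 4L)
  if (length(bad)) stop("malformed bedGraph line ", lineno[bad[1]])
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(.num_or_na(vapply(parts, `[[`, "", 2L))),
    end = as.integer(.num_or_na(vapply(parts, `[[`, "", 3L))),
    value = .num_or_na(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)
  if (length(bad)) stop("malformed bedGraph line ", lineno[bad[1]])
  df
}

#' Write a bedGraph coverage file
#'
#' @param df data.frame with `chrom, start, end, value`.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  .check_intervals(df, "bedGraph")
  write.table(df[, c("chrom", "start", "end", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a summary table deterministically
#'
#' Tab-separated with a header row. Rows are sorted by `chrom`, `start`, and
#' the first remaining column when those columns exist (otherwise input order
#' is kept), so identical inputs always produce byte-identical files.
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records must not be NULL")
  stopifnot(is.data.frame(records))
  if (all(c("chrom", "start") %in% names(records)) && nrow(records)) {
    label <- setdiff(names(records), c("chrom", "start"))
    key <- if (length(label)) records[[label[1]]] else seq_len(nrow(records))
    records <- records[order(records$chrom, records$start, key, method = "radix"), ,
                       drop = FALSE]
  }
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a summary table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
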