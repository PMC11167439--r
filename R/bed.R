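#' Read genomic intervals with per-condition signal
#'
#' Reads a BED3+ file (0-based half-open coordinates) into a
#' [GenomicRanges::GRanges]. Columns beyond `chrom/start/end` are taken from
#' a `#`-prefixed header line when present (recommended for named
#' `signal_<condition>` columns); without one the file is treated as
#' `chrom start end [name]`. Intervals come back sorted by (chrom, start)
#' so overlap queries are well defined; adjacent half-open intervals such
#' as `[0,10)` and `[10,20)` do not overlap.
#'
#' @param path path to a BED-like TSV file.
#' @return A `GRanges`, sorted, with an `id` metadata column (auto-generated
#'   `peak_<i>` when the file has no name column) plus any signal columns.
#' @export
read_bed_signal <- function(path) {
  lines <- readLines(path)
  header <- NULL
  hl <- grep("^#", lines)
  if (length(hl)) {
    header <- strsplit(sub("^#\\s*", "", lines[hl[1]]), "\t")[[1]]
    lines <- lines[-hl]
  }
  if (!length(lines)) stop_format("empty BED file")
  tab <- read.delim(text = paste(lines, collapse = "\n"), header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop_format("BED file needs >=3 columns")
  if (!is.null(header)) {
    if (length(header) != ncol(tab))
      stop_format("BED header does not match column count")
    names(tab) <- header
  } else {
    names(tab) <- c("chrom", "start", "end", "id")[seq_len(min(4, ncol(tab)))]
  }
  if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]]))
    stop_format("malformed BED coordinates")
  if (any(tab[[2]] < 0) || any(tab[[2]] >= tab[[3]]))
    stop_format("BED intervals require 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
  meta <- tab[, -(1:3), drop = FALSE]
  if (!"id" %in% names(meta))
    meta$id <- paste0("peak_", seq_len(nrow(tab)))
  sig <- grep("^signal_", names(meta), value = TRUE)
  for (s in sig) {
    if (any(meta[[s]] < 0)) stop_value("signal columns must be non-negative")
  }
  S4Vectors::mcols(gr) <- meta[, c("id", setdiff(names(meta), "id")), drop = FALSE]
  if (anyDuplicated(gr$id)) stop_format("duplicate interval ids")
  GenomicRanges::sort(gr)
}

#' Write intervals with signal columns to BED
#'
#' Inverse of [read_bed_signal()]; emits a `#` header line naming all
#' columns and 0-based half-open coordinates.
#'
#' @param gr a `GRanges` with an `id` column and optional `signal_*` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_signal <- function(gr, path) {
  meta <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   meta, check.names = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval midpoint on the 0-based half-open scale used by BED files
bed_midpoint <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}
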