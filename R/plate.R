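#' NanoString-style plate of counted transcripts
#'
#' A `PlateFile` holds raw probe counts for every well of a counted-hybridization
#' plate together with the layout metadata the three-stage normalization
#' needs: which plate column each well sits in, which plex set it was
#' hybridized with, and whether it carries an experimental sample or the
#' shared calibration sample.
#'
#' @param plate_id scalar identifier.
#' @param wells data.frame with columns `well` (unique id, e.g. "A01"),
#'   `column` (integer plate column), `row` (integer plate row), `plex_set`
#'   (id), `sample_role` (`"experimental"` or `"calibration"`).
#' @param probes data.frame with columns `probe_id` (unique) and `class`
#'   (`"Positive"`, `"Housekeeping"` or `"Endogenous"`; the synonym
#'   `"Calibration-eligible"` is accepted and stored as `"Endogenous"`).
#' @param counts numeric matrix wells x probes, dimnames matching `wells$well`
#'   and `probes$probe_id`; non-negative.
#' @return Object of class `PlateFile`; `calibration_available` records
#'   whether every plex set has at least one calibration well.
#' @export
PlateFile <- function(plate_id, wells, probes, counts) {
  need_w <- c("well", "column", "row", "plex_set", "sample_role")
  if (!all(need_w %in% names(wells))) stop_format("wells table missing columns")
  if (!all(c("probe_id", "class") %in% names(probes)))
    stop_format("probes table missing columns")
  if (anyDuplicated(wells$well)) stop_format("duplicate well ids")
  if (anyDuplicated(probes$probe_id)) stop_format("duplicate probe ids")
  probes$class[probes$class == "Calibration-eligible"] <- "Endogenous"
  bad <- setdiff(unique(probes$class), c("Positive", "Housekeeping", "Endogenous"))
  if (length(bad))
    stop_format(paste0("unknown probe class: ", paste(bad, collapse = ", ")))
  if (sum(probes$class == "Positive") < 2)
    stop_format("plate needs >=2 positive-control probes")
  if (sum(probes$class == "Housekeeping") < 1)
    stop_format("plate needs >=1 housekeeping probe")
  bad_role <- setdiff(unique(wells$sample_role), c("experimental", "calibration"))
  if (length(bad_role)) stop_format("unknown sample_role")
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_format("counts must be a numeric matrix")
  if (!identical(rownames(counts), as.character(wells$well)) ||
      !identical(colnames(counts), as.character(probes$probe_id)))
    stop_format("counts dimnames must match wells and probes tables")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_value("plate counts must be finite and non-negative")
  cal_by_plex <- tapply(wells$sample_role == "calibration", wells$plex_set, any)
  structure(list(plate_id = plate_id, wells = wells, probes = probes,
                 counts = counts,
                 calibration_available = all(cal_by_plex)),
            class = "PlateFile")
}

#' @export
print.PlateFile <- function(x, ...) {
  cat(sprintf("PlateFile '%s': %d wells x %d probes, %d plex set(s)%s\n",
              x$plate_id, nrow(x$wells), nrow(x$probes),
              length(unique(x$wells$plex_set)),
              if (x$calibration_available) "" else " [no calibration wells]"))
  invisible(x)
}

probe_ids <- function(plate, class) {
  plate$probes$probe_id[plate$probes$class %in% class]
}

#' Read a plate file
#'
#' Parses the sectioned tab-separated plate dialect written by
#' [write_plate()]: a `<Header>` section of key/value pairs (`plate_id`),
#' then `<Probes>`, `<Wells>` and `<Counts>` sections, each a TSV block with
#' a header row. Lines starting with `#` are ignored.
#'
#' @param path path to a plate file.
#' @return A [PlateFile].
#' @export
read_plate <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sec_at <- grep("^<\\w+>$", lines)
  if (!length(sec_at)) stop_format("no section markers in plate file")
  sec_names <- gsub("[<>]", "", lines[sec_at])
  bounds <- c(sec_at, length(lines) + 1L)
  sections <- lapply(seq_along(sec_at), function(i) {
    lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
  })
  names(sections) <- sec_names
  need <- c("Header", "Probes", "Wells", "Counts")
  if (!all(need %in% sec_names))
    stop_format(paste0("plate file missing section(s): ",
                       paste(setdiff(need, sec_names), collapse = ", ")))
  parse_tsv <- function(x) {
    read.delim(text = paste(x, collapse = "\n"), header = TRUE,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  hdr <- do.call(rbind, strsplit(sections$Header, "\t"))
  plate_id <- hdr[match("plate_id", hdr[, 1]), 2]
  probes <- parse_tsv(sections$Probes)
  wells <- parse_tsv(sections$Wells)
  cnt <- parse_tsv(sections$Counts)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- as.character(cnt[[1]])
  m <- m[as.character(wells$well), as.character(probes$probe_id), drop = FALSE]
  PlateFile(plate_id, wells, probes, m)
}

#' Write a plate file
#'
#' @param plate a [PlateFile].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "PlateFile"))
  con <- file(path, "w"); on.exit(close(con))
  tsv <- function(df) {
    c(paste(names(df), collapse = "\t"),
      do.call(paste, c(lapply(df, as.character), sep = "\t")))
  }
  writeLines(c("<Header>", paste0("plate_id\t", plate$plate_id),
               "<Probes>", tsv(plate$probes),
               "<Wells>", tsv(plate$wells),
               "<Counts>",
               tsv(data.frame(well = rownames(plate$counts), plate$counts,
                              check.names = FALSE))), con)
  invisible(path)
}
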