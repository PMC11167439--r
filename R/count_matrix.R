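#' Gene-by-sample count matrix with condition labels
#'
#' A `CountMatrix` is the substrate for all expression contrasts: a numeric
#' matrix of non-negative counts (genes in rows, samples in columns) plus a
#' condition label per sample. Counts are stored as reals, not integers,
#' because normalized transcript counts are generally non-integer.
#'
#' @param counts numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids); all values must be
#'   finite and `>= 0`.
#' @param condition named character vector mapping every sample id to one of
#'   `"unstim"`, `"cytoA"`, `"cytoB"`, `"combo"`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (the matrix) and `condition` (label per sample, in column order).
#' @examples
#' m <- matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' cm <- CountMatrix(m, setNames(c("unstim", "cytoA", "cytoB", "combo"),
#'                               paste0("s", 1:4)))
#' dim(cm$counts)
#' @export
CountMatrix <- function(counts, condition) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_format("counts must be a numeric matrix")
  gid <- rownames(counts); sid <- colnames(counts)
  if (is.null(gid) || is.null(sid))
    stop_format("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(gid)) stop_format("duplicate gene ids")
  if (anyDuplicated(sid)) stop_format("duplicate sample ids")
  if (any(!is.finite(counts))) stop_value("counts contain non-finite values")
  if (any(counts < 0)) stop_value("counts must be non-negative")
  missing <- setdiff(sid, names(condition))
  if (length(missing))
    stop_config(paste0("samples missing from condition map: ",
                       paste(missing, collapse = ", ")))
  condition <- condition[sid]
  bad <- setdiff(unique(condition), SYN_CONDITIONS)
  if (length(bad))
    stop_config(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")))
  structure(list(counts = counts, condition = condition), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(factor(x$condition, levels = SYN_CONDITIONS)))
  invisible(x)
}

#' Read a count table with condition labels
#'
#' Reads a tab-separated table whose header row holds sample ids and whose
#' first column holds gene ids (`#` lines are comments), and attaches a
#' condition label to every sample.
#'
#' @param path path to a TSV file.
#' @param condition_map named character vector (or path to a YAML file of
#'   `sample: condition` pairs) mapping each sample to its condition.
#' @return A [CountMatrix].
#' @export
read_count_table <- function(path, condition_map) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_format("count table needs a gene column and >=1 sample")
  gid <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric entries in count table")
  rownames(m) <- gid
  if (is.character(condition_map) && length(condition_map) == 1 &&
      file.exists(condition_map)) {
    condition_map <- read_condition_map(condition_map)
  }
  CountMatrix(m, condition_map)
}

#' Write a count table
#'
#' Inverse of [read_count_table()]: tab-separated, gene ids in the first
#' column named `gene`.
#'
#' @param cm a [CountMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-condition map from YAML
#'
#' @param path YAML file of flat `sample: condition` pairs.
#' @return Named character vector.
#' @export
read_condition_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) stop_config("empty condition map")
  setNames(vapply(y, as.character, ""), names(y))
}
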