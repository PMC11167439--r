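#' Stage 1: positive-control column normalization
#'
#' Within each plate column, every well is scaled so its positive-control
#' geometric mean matches the column's reference (the geometric mean of the
#' per-well positive-control geometric means). The factor is
#' `column_reference / well_positive_geomean`, so low-signal wells are
#' scaled up. A well's "positive control" is taken as the geometric mean of
#' all its positive-control probes.
#'
#' @param plate a [PlateFile].
#' @param counts optional matrix to normalize (defaults to `plate$counts`;
#'   passing staged counts lets the stages chain).
#' @return list with `counts` (normalized matrix) and `factors` (per-well
#'   scale factors, named by well).
#' @export
positive_control_normalize <- function(plate, counts = plate$counts) {
  pos <- probe_ids(plate, "Positive")
  pc <- counts[, pos, drop = FALSE]
  if (any(pc <= 0))
    stop_value("positive-control counts must be > 0 for geometric means")
  well_pos <- apply(pc, 1, geomean)
  col_of <- setNames(plate$wells$column, plate$wells$well)[rownames(counts)]
  col_ref <- tapply(well_pos, col_of, geomean)
  factors <- as.numeric(col_ref[as.character(col_of)]) / well_pos
  names(factors) <- rownames(counts)
  list(counts = counts * factors, factors = factors)
}

#' Stage 2: plex-set calibration normalization
#'
#' Removes per-gene plex-set hybridization variability using the shared
#' calibration sample. For each endogenous/housekeeping gene `g`, the
#' cross-plex reference `G(g)` is the geometric mean of `g`'s calibration
#' counts over all plex sets; every measurement of `g` in plex set `s` is
#' multiplied by `G(g) / cal_count(g, s)`. A plex set's calibration count
#' is the geometric mean of `g` over that set's calibration wells.
#'
#' @param counts matrix to normalize (typically stage-1 output).
#' @param plate a [PlateFile] with calibration wells in every plex set.
#' @return list with `counts` and `factors` (genes x plex sets matrix).
#' @export
plex_calibration_normalize <- function(counts, plate) {
  if (!plate$calibration_available)
    stop_config("every plex set needs a calibration well for plex normalization")
  genes <- probe_ids(plate, c("Endogenous", "Housekeeping"))
  plex_of <- setNames(plate$wells$plex_set, plate$wells$well)[rownames(counts)]
  cal_wells <- plate$wells$well[plate$wells$sample_role == "calibration"]
  plex_sets <- sort(unique(plate$wells$plex_set))
  cal <- sapply(plex_sets, function(s) {
    w <- intersect(cal_wells, plate$wells$well[plate$wells$plex_set == s])
    sub <- counts[w, genes, drop = FALSE]
    if (any(sub <= 0)) stop_value("calibration counts must be > 0")
    apply(sub, 2, geomean)
  })  # genes x plex sets
  if (any(!is.finite(cal))) stop_config("missing calibration measurement")
  G <- apply(cal, 1, geomean)
  factors <- G / cal
  out <- counts
  for (s in plex_sets) {
    w <- rownames(counts)[plex_of == s]
    out[w, genes] <- sweep(counts[w, genes, drop = FALSE], 2,
                           factors[genes, s], `*`)
  }
  list(counts = out, factors = factors)
}

#' Stage 3: housekeeper normalization
#'
#' Equalizes the housekeeper geometric mean across positions (wells): the
#' factor for position `p` is `M / h(p)` where `h(p)` is the geometric mean
#' of the housekeeper counts at `p` and `M` is the arithmetic mean of all
#' `h(p)`. Applied to all transcripts at `p`.
#'
#' @param counts matrix to normalize (typically stage-2 output).
#' @param plate a [PlateFile].
#' @param housekeepers probe ids to use; defaults to the intersection of
#'   the canonical trio (GUSB, HPRT1, NOL7) with the plate's housekeeping
#'   probes, else all probes of class Housekeeping.
#' @return list with `counts` and `factors` (per well).
#' @export
housekeeper_normalize <- function(counts, plate, housekeepers = NULL) {
  hk_all <- probe_ids(plate, "Housekeeping")
  if (is.null(housekeepers)) {
    housekeepers <- intersect(c("GUSB", "HPRT1", "NOL7"), hk_all)
    if (!length(housekeepers)) housekeepers <- hk_all
  }
  hk <- counts[, housekeepers, drop = FALSE]
  if (any(hk <= 0)) stop_value("housekeeper counts must be > 0")
  h <- apply(hk, 1, geomean)
  M <- mean(h)
  factors <- M / h
  list(counts = counts * factors, factors = factors)
}

#' Full three-stage plate normalization
#'
#' Applies, in order: positive-control column scaling (hybridization),
#' plex-set calibration scaling, and housekeeper equalization. Returns all
#' staged matrices and factors for audit.
#'
#' @param plate a [PlateFile].
#' @param housekeepers passed to [housekeeper_normalize()].
#' @return list of class `NormalizationReport`: `raw`, `post1`, `post2`,
#'   `post3` (matrices), `factors` (list `stage1`, `stage2`, `stage3`) and
#'   `normalized` (= `post3`).
#' @export
normalize_pipeline <- function(plate, housekeepers = NULL) {
  s1 <- positive_control_normalize(plate)
  s2 <- plex_calibration_normalize(s1$counts, plate)
  s3 <- housekeeper_normalize(s2$counts, plate, housekeepers)
  structure(list(raw = plate$counts, post1 = s1$counts, post2 = s2$counts,
                 post3 = s3$counts, normalized = s3$counts,
                 factors = list(stage1 = s1$factors, stage2 = s2$factors,
                                stage3 = s3$factors)),
            class = "NormalizationReport")
}

#' @export
print.NormalizationReport <- function(x, ...) {
  cat(sprintf("NormalizationReport: %d wells x %d probes; stage factor ranges:\n",
              nrow(x$raw), ncol(x$raw)))
  for (s in names(x$factors)) {
    r <- range(x$factors[[s]])
    cat(sprintf("  %s: [%.4g, %.4g]\n", s, r[1], r[2]))
  }
  invisible(x)
}
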