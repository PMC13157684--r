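# Scan- and ROI-level quality-control gates. All decisions are pure
# functions of inputs and thresholds; boundary semantics follow the printed
# rules exactly: "more than 15 %" of volumes over 1 mm fails (strict), an
# ROI spanning half or fewer of the unique slice timings fails (strict
# "more than half" to pass).

#' Motion gate
#'
#' @param motion a \code{motion_trace}.
#' @param max_abs_mm displacement threshold per volume, mm (default 1).
#' @param max_fraction maximal tolerated fraction of volumes exceeding the
#'   threshold (default 0.15); the gate fails only when the fraction is
#'   strictly greater.
#' @return list \code{(pass, fraction)}.
#' @export
qc_motion <- function(motion, max_abs_mm = 1.0, max_fraction = 0.15) {
  stopifnot(inherits(motion, "motion_trace"))
  d <- motion$displacement_mm
  if (length(d) == 0) stop("empty motion trace")
  frac <- sum(d > max_abs_mm) / length(d)
  list(pass = frac <= max_fraction, fraction = frac)
}

#' PPG quality gate
#'
#' @param cinfo a \code{cardiac_info} (carries the quality score).
#' @param min_quality minimal acceptable in-band power fraction (default
#'   0.3; a configuration value, as the published exclusion threshold is
#'   not public).
#' @return list \code{(pass, quality)}.
#' @export
qc_ppg <- function(cinfo, min_quality = 0.3) {
  stopifnot(inherits(cinfo, "cardiac_info"))
  list(pass = cinfo$quality >= min_quality, quality = cinfo$quality)
}

#' Slice-timing coverage gate
#'
#' An ROI must span more than half of the unique slice timings for its
#' hypersampled signal to be usable (e.g. with 9 timing groups, 4 covered
#' fails and 5 passes).
#'
#' @param mask an \code{roi_mask}.
#' @param table a \code{slice_timing_table} for the scan.
#' @return list \code{(pass, covered, n_time)}.
#' @export
qc_coverage <- function(mask, table) {
  stopifnot(inherits(mask, "roi_mask"), inherits(table, "slice_timing_table"))
  vox_per_slice <- apply(mask$mask, 3, sum)
  if (sum(vox_per_slice) == 0) stop("empty ROI")
  covered <- length(unique(table$group_of_slice[vox_per_slice > 0]))
  list(pass = 2 * covered > table$n_time, covered = covered,
       n_time = table$n_time)
}

#' Assemble a QC report
#'
#' @param motion_res result of \code{\link{qc_motion}}.
#' @param ppg_res result of \code{\link{qc_ppg}}.
#' @param coverage_res named list of \code{\link{qc_coverage}} results, one
#'   per ROI.
#' @return list with the per-gate results and \code{overall_pass}, the
#'   conjunction of all gates; serializable to JSON and back without loss.
#' @export
qc_report <- function(motion_res, ppg_res, coverage_res) {
  overall <- motion_res$pass && ppg_res$pass &&
    all(vapply(coverage_res, `[[`, logical(1), "pass"))
  list(motion = motion_res, ppg = ppg_res, coverage = coverage_res,
       overall_pass = overall)
}
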