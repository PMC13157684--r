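# Core hypersampling algorithm: group slices by their within-TR acquisition
# offset, average ROI voxels per timing group, detrend each group series,
# and interleave the groups in acquisition order to obtain one signal
# sampled at TR / N_Time.

#' Build a slice-timing table
#'
#' Groups slices whose within-TR acquisition offsets agree within a
#' tolerance. For a multiband acquisition with \code{n_slices} slices and
#' multiband factor \code{mb}, the number of distinct timing groups is
#' \code{N_Time = n_slices / mb}, and interleaving them raises the effective
#' sampling rate from \code{1/TR} to \code{N_Time/TR}.
#'
#' @param scan an \code{fmri_scan}, or \code{NULL} if the parameter form is
#'   used.
#' @param n_slices,mb_factor,tr_s parameter form: derive the offsets of a
#'   sequential multiband scheme instead of reading them from a scan.
#' @param tol_s offsets closer than this are considered the same timing
#'   group (default 1 ms).
#' @return An object of class \code{slice_timing_table} with fields
#'   \code{n_time}, \code{group_of_slice} (slice index -> group id, ordered
#'   by ascending offset), \code{offsets_s} (the \code{n_time} unique
#'   offsets, ascending), \code{tr_s}, \code{dt_s = tr_s/n_time}, and
#'   \code{fs_hyper_hz = n_time/tr_s}.
#' @export
build_timing_table <- function(scan = NULL, n_slices = NULL, mb_factor = NULL,
                               tr_s = NULL, tol_s = 0.001) {
  if (is.null(scan)) {
    if (is.null(n_slices) || is.null(mb_factor) || is.null(tr_s))
      stop("supply either a scan or (n_slices, mb_factor, tr_s)")
    offsets <- derive_slice_offsets(n_slices, mb_factor, tr_s)
  } else {
    stopifnot(inherits(scan, "fmri_scan"))
    offsets <- scan$slice_offsets_s
    tr_s <- scan$tr_s
  }
  # cluster offsets within tol: sort, then break where the gap exceeds tol
  ord <- order(offsets)
  sorted <- offsets[ord]
  grp_sorted <- cumsum(c(1, diff(sorted) > tol_s))
  group_of_slice <- integer(length(offsets))
  group_of_slice[ord] <- grp_sorted
  n_time <- max(grp_sorted)
  uniq <- as.numeric(tapply(offsets, group_of_slice, mean))
  sizes <- as.integer(table(group_of_slice))
  if (length(unique(sizes)) > 1L)
    warning("slice-timing groups have unequal sizes")
  dt <- tr_s / n_time
  # samples are placed on the nominal uniform grid j*dt; warn when the true
  # offsets deviate from it noticeably
  nominal <- (seq_len(n_time) - 1) * dt + uniq[1]
  if (max(abs(uniq - nominal)) > 0.1 * dt)
    warning("slice timings deviate from a uniform grid by more than 10% of TR/N_Time; hypersampled spacing is only nominal")
  structure(list(n_time = n_time, group_of_slice = group_of_slice,
                 offsets_s = uniq, tr_s = tr_s, dt_s = dt,
                 fs_hyper_hz = n_time / tr_s,
                 group_sizes = sizes),
            class = "slice_timing_table")
}

#' @export
print.slice_timing_table <- function(x, ...) {
  cat(sprintf("<slice_timing_table> N_Time = %d, TR = %g s, dt = %g s, hypersampled rate %.4g Hz (Nyquist %.4g Hz)\n",
              x$n_time, x$tr_s, x$dt_s, x$fs_hyper_hz, x$fs_hyper_hz / 2))
  invisible(x)
}

#' Remove a least-squares linear trend
#'
#' Fits intercept + slope by ordinary least squares and subtracts the fit,
#' leaving a series with zero mean and zero linear trend. First-order
#' detrending removes scanner drift and per-slice baseline differences that
#' would otherwise inject spectral lines at multiples of 1/TR into the
#' stitched signal.
#'
#' @param x numeric vector, length >= 3.
#' @return detrended vector of the same length.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3L) stop("detrend requires at least 3 samples")
  if (any(!is.finite(x))) stop("detrend requires finite values")
  t <- seq_len(n) - (n + 1) / 2          # centred time axis: orthogonal basis
  x - mean(x) - (sum(t * x) / sum(t * t)) * t
}

#' Per-timing-group ROI mean series
#'
#' For each timing group, averages the scan signal over the ROI voxels lying
#' in that group's slices (per volume) and detrends the resulting series.
#' Detrending the group mean rather than each voxel is exactly equivalent
#' (both operations are linear) and V times cheaper.
#'
#' @param scan an \code{fmri_scan}.
#' @param mask an \code{roi_mask} on the same grid.
#' @param table a \code{slice_timing_table} for the scan.
#' @return list with \code{series} (n_time x n_volumes matrix, rows ordered
#'   by ascending group offset; empty groups are NA rows) and
#'   \code{voxel_counts} (ROI voxels per group).
#' @export
slice_group_signals <- function(scan, mask, table) {
  stopifnot(inherits(scan, "fmri_scan"), inherits(mask, "roi_mask"),
            inherits(table, "slice_timing_table"))
  dims <- dim(scan$data)
  if (!all(dim(mask$mask) == dims[1:3]))
    stop("mask grid does not match scan grid")
  nt <- dims[4]
  n_time <- table$n_time
  series <- matrix(NA_real_, nrow = n_time, ncol = nt)
  counts <- integer(n_time)
  vox_per_slice <- apply(mask$mask, 3, sum)
  if (sum(vox_per_slice) == 0) stop("empty ROI")
  for (g in seq_len(n_time)) {
    slices <- which(table$group_of_slice == g)
    slices <- slices[vox_per_slice[slices] > 0]
    counts[g] <- sum(vox_per_slice[slices])
    if (counts[g] == 0L) next
    acc <- numeric(nt)
    for (s in slices) {
      m2d <- mask$mask[, , s]
      sl <- matrix(scan$data[, , s, ], ncol = nt)   # voxels x volumes
      acc <- acc + colSums(sl[as.vector(m2d), , drop = FALSE])
    }
    series[g, ] <- detrend_linear(acc / counts[g])
  }
  # order rows by ascending group offset (canonical acquisition order)
  ord <- order(table$offsets_s)
  list(series = series[ord, , drop = FALSE], voxel_counts = counts[ord],
       offsets_s = table$offsets_s[ord])
}

#' Interleave timing-group series into a hypersampled signal
#'
#' Places the \code{N_Time} group series, ordered by their slice timings, on
#' the uniform grid with spacing \code{TR/N_Time}:
#' \code{values[(k-1)*N_Time + j]} is group \code{j}'s value at volume
#' \code{k}. No interpolation is performed here; positions belonging to
#' groups with no ROI voxel are flagged invalid.
#'
#' @param group_signals output of \code{\link{slice_group_signals}}.
#' @param table the matching \code{slice_timing_table}.
#' @param roi_label label carried in the result's provenance.
#' @return An object of class \code{hypersampled_signal} with fields
#'   \code{values}, \code{valid}, \code{dt_s}, \code{roi_label},
#'   \code{coverage} (groups with >= 1 ROI voxel) and \code{n_time}.
#' @export
interleave <- function(group_signals, table, roi_label = "custom") {
  series <- group_signals$series
  n_time <- nrow(series)
  if (n_time != table$n_time)
    stop("group count does not match timing table")
  nt <- ncol(series)
  values <- as.vector(series)             # column-major: fast index = group
  valid <- rep(group_signals$voxel_counts > 0, times = nt)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, dt_s = table$dt_s,
                 n_time = n_time, tr_s = table$tr_s,
                 roi_label = roi_label,
                 coverage = sum(group_signals$voxel_counts > 0)),
            class = "hypersampled_signal")
}

#' @export
print.hypersampled_signal <- function(x, ...) {
  cat(sprintf("<hypersampled_signal> '%s': %d samples at dt = %g s (%.4g Hz), coverage %d/%d timing groups\n",
              x$roi_label, length(x$values), x$dt_s, 1 / x$dt_s,
              x$coverage, x$n_time))
  invisible(x)
}

#' Hypersample an ROI
#'
#' End-to-end per-ROI reconstruction: per-group averaging and detrending,
#' interleaving, and gap handling. Mirrors the quality-control exclusion
#' rule: an ROI covering half or fewer of the timing groups is rejected
#' outright, because the resulting signal would be dominated by
#' interpolation.
#'
#' @param scan an \code{fmri_scan}.
#' @param mask an \code{roi_mask}.
#' @param table a \code{slice_timing_table}; built from the scan when
#'   omitted.
#' @param gap_policy \code{"interpolate"} (default; linear interpolation
#'   across invalid positions, constant extrapolation at the ends),
#'   \code{"zero"} (fill 0), or \code{"strict"} (any gap is an error).
#' @return A \code{hypersampled_signal} whose \code{values} contain no NA;
#'   the \code{valid} mask still records which positions were measured.
#' @export
hypersample_roi <- function(scan, mask, table = NULL,
                            gap_policy = c("interpolate", "zero", "strict")) {
  gap_policy <- match.arg(gap_policy)
  if (is.null(table)) table <- build_timing_table(scan)
  gs <- slice_group_signals(scan, mask, table)
  hs <- interleave(gs, table, roi_label = mask$label)
  if (2 * hs$coverage <= table$n_time)
    stop(sprintf("insufficient slice-timing coverage: ROI spans %d of %d timing groups (need more than half)",
                 hs$coverage, table$n_time))
  if (anyNA(hs$values)) {
    if (gap_policy == "strict")
      stop("hypersampled signal has gaps and gap_policy = 'strict'")
    if (gap_policy == "zero") {
      hs$values[is.na(hs$values)] <- 0
    } else {
      ok <- which(!is.na(hs$values))
      hs$values <- stats::approx(ok, hs$values[ok],
                                 xout = seq_along(hs$values),
                                 method = "linear", rule = 2)$y
    }
  }
  hs$gap_policy <- gap_policy
  hs
}
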