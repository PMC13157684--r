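# Domain types and on-disk I/O: 4D NIfTI scans with slice-timing metadata,
# ROI masks, photoplethysmography traces and motion-parameter traces.

#' Construct an fMRI scan object
#'
#' The central container consumed by every analysis function: a 4D voxel
#' array together with its repetition time and the per-slice acquisition
#' offsets within a TR. Volume \code{k} (1-based), slice \code{s} is acquired
#' at \code{(k - 1) * tr_s + slice_offsets_s[s]} seconds.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t), arbitrary signal
#'   units.
#' @param tr_s repetition time in seconds (> 0).
#' @param slice_offsets_s numeric vector of per-slice acquisition offsets in
#'   seconds, one per z-slice, each in \code{[0, tr_s)}.
#' @param affine optional 4x4 voxel-to-world matrix; carried through
#'   unchanged and used only to check grid agreement with masks.
#' @param voxel_size_mm optional length-3 voxel dimensions in mm (used by the
#'   phantom propagation model and for provenance).
#' @return An object of class \code{fmri_scan}.
#' @export
fmri_scan <- function(data, tr_s, slice_offsets_s, affine = NULL,
                      voxel_size_mm = c(2.5, 2.5, 2.5)) {
  if (length(dim(data)) != 4L)
    stop("not a time series: 'data' must be a 4D array (x, y, z, t)")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("'tr_s' must be a single positive number")
  nz <- dim(data)[3L]
  nt <- dim(data)[4L]
  if (nt < 2L) stop("scan must contain at least 2 volumes")
  if (length(slice_offsets_s) != nz)
    stop(sprintf("slice timing length (%d) does not match z extent (%d)",
                 length(slice_offsets_s), nz))
  if (any(!is.finite(slice_offsets_s)))
    stop("slice offsets must be finite")
  if (any(slice_offsets_s < 0) || any(slice_offsets_s >= tr_s))
    stop("every slice offset must lie in [0, TR)")
  structure(
    list(data = data, tr_s = tr_s,
         slice_offsets_s = as.numeric(slice_offsets_s),
         n_volumes = nt, affine = affine,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "fmri_scan")
}

#' @export
print.fmri_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_scan> %d x %d x %d voxels, %d volumes, TR = %g s, %d unique slice timings\n",
              d[1], d[2], d[3], x$n_volumes, x$tr_s,
              length(unique(round(x$slice_offsets_s, 6)))))
  invisible(x)
}

#' Construct an ROI mask
#'
#' @param mask 3D logical (or numeric, nonzero = inside) array on the scan
#'   grid; must contain at least one voxel.
#' @param label region label, e.g. \code{"artery"}, \code{"SSS"},
#'   \code{"GM"}, \code{"WM"} or any custom string.
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(mask, label = "custom") {
  if (length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  m <- array(as.logical(mask != 0), dim = dim(mask))
  if (!any(m)) stop("empty ROI: mask contains no voxels")
  structure(list(mask = m, label = as.character(label)), class = "roi_mask")
}

#' Construct a physiological (PPG) recording
#'
#' @param samples numeric vector of PPG samples, arbitrary units.
#' @param fs_hz sampling rate in Hz.
#' @param start_offset_s offset of the first sample relative to the first
#'   fMRI volume, seconds (default 0: recording starts with the scan).
#' @return An object of class \code{physio_recording}.
#' @export
physio_recording <- function(samples, fs_hz, start_offset_s = 0) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("PPG samples must be finite numeric values")
  if (!is.numeric(fs_hz) || fs_hz <= 0)
    stop("'fs_hz' must be positive")
  dur <- length(samples) / fs_hz
  if (dur < 10)
    warning(sprintf("PPG recording is only %.1f s long; >= 10 s recommended", dur))
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 start_offset_s = start_offset_s),
            class = "physio_recording")
}

#' Construct a motion trace
#'
#' Per-volume absolute displacement in millimetres, as produced by a motion
#' estimator run for QC purposes only (the hypersampling itself is applied
#' to uncorrected data because motion correction destroys slice timing).
#'
#' @param displacement_mm non-negative numeric vector, one value per volume.
#' @return An object of class \code{motion_trace}.
#' @export
motion_trace <- function(displacement_mm) {
  if (!is.numeric(displacement_mm) || length(displacement_mm) == 0)
    stop("motion trace must be a non-empty numeric vector")
  if (any(!is.finite(displacement_mm)) || any(displacement_mm < 0))
    stop("motion displacements must be finite and non-negative")
  structure(list(displacement_mm = as.numeric(displacement_mm)),
            class = "motion_trace")
}

# ---------------------------------------------------------------------------
# Slice-timing helpers shared by the loader and the phantom generator.

#' Derive per-slice acquisition offsets from acquisition parameters
#'
#' Models a 2D multiband EPI acquisition: slices \code{s} and
#' \code{s + N_Time}, \code{s + 2 N_Time}, ... are excited together, so there
#' are \code{N_Time = n_slices / mb_factor} distinct acquisition events per
#' TR, spaced \code{TR / N_Time} apart.
#'
#' @param n_slices total number of slices.
#' @param mb_factor multiband (simultaneous multi-slice) factor; must divide
#'   \code{n_slices}.
#' @param tr_s repetition time, seconds.
#' @param ordering acquisition order of the timing groups within a TR:
#'   \code{"sequential"} (group 0, 1, 2, ...) or \code{"interleaved"}
#'   (even-indexed groups first, then odd).
#' @return numeric vector of length \code{n_slices}, offsets in seconds.
#' @export
derive_slice_offsets <- function(n_slices, mb_factor, tr_s,
                                 ordering = c("sequential", "interleaved")) {
  ordering <- match.arg(ordering)
  if (n_slices %% mb_factor != 0)
    stop(sprintf("n_slices (%d) is not divisible by mb_factor (%d)",
                 n_slices, mb_factor))
  n_time <- n_slices %/% mb_factor
  group <- (seq_len(n_slices) - 1L) %% n_time          # 0-based group id
  acq_order <- if (ordering == "sequential") 0:(n_time - 1L)
               else c(seq(0L, n_time - 1L, 2L), seq(1L, n_time - 1L, 2L))
  position <- match(group, acq_order) - 1L             # slot within the TR
  position * tr_s / n_time
}

# ---------------------------------------------------------------------------
# Loaders

#' Load a 4D fMRI scan from NIfTI plus slice-timing metadata
#'
#' Slice timing comes from a BIDS JSON sidecar (field \code{"SliceTiming"},
#' seconds per slice, referenced to volume start) or, failing that, from
#' acquisition parameters \code{(n_slices, mb_factor, tr_s, ordering)}. If
#' both are supplied they must agree to within \code{tol_s} per slice; the
#' sidecar is the source of truth and a larger disagreement is an error,
#' because hypersampling with wrong timings is meaningless. TR is taken from
#' the sidecar \code{"RepetitionTime"} when present, otherwise from the NIfTI
#' header \code{pixdim[4]}; a mismatch above 1 ms between the two is an
#' error.
#'
#' @param image_path path to a 4D NIfTI (.nii or .nii.gz).
#' @param sidecar_path optional path to a BIDS JSON sidecar.
#' @param n_slices,mb_factor,tr_s,ordering acquisition parameters used to
#'   derive slice offsets when no sidecar is given (see
#'   \code{\link{derive_slice_offsets}}).
#' @param tol_s per-slice tolerance, seconds, for sidecar/parameter
#'   consistency (default 0.001).
#' @return An \code{\link{fmri_scan}}.
#' @export
load_fmri <- function(image_path, sidecar_path = NULL,
                      n_slices = NULL, mb_factor = NULL, tr_s = NULL,
                      ordering = "sequential", tol_s = 0.001) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("not a time series: image is not 4D")
  hdr_tr <- RNifti::pixdim(img)[4]
  vox <- RNifti::pixdim(img)[1:3]

  sidecar <- NULL
  if (!is.null(sidecar_path))
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)

  # TR resolution: sidecar > explicit parameter > header
  tr_used <- if (!is.null(sidecar$RepetitionTime)) sidecar$RepetitionTime
             else if (!is.null(tr_s)) tr_s
             else hdr_tr
  if (is.null(tr_used) || !is.finite(tr_used) || tr_used <= 0)
    stop("repetition time unavailable: supply a sidecar or tr_s")
  if (is.finite(hdr_tr) && hdr_tr > 0 && abs(hdr_tr - tr_used) > 0.001)
    stop(sprintf("TR mismatch: header %g s vs metadata %g s (> 1 ms)",
                 hdr_tr, tr_used))

  offs_sidecar <- if (!is.null(sidecar$SliceTiming))
    as.numeric(sidecar$SliceTiming) else NULL
  offs_derived <- if (!is.null(n_slices) && !is.null(mb_factor))
    derive_slice_offsets(n_slices, mb_factor, tr_used, ordering) else NULL

  if (is.null(offs_sidecar) && is.null(offs_derived))
    stop("slice timing unavailable: supply a sidecar 'SliceTiming' array or (n_slices, mb_factor, tr_s)")
  if (!is.null(offs_sidecar) && length(offs_sidecar) != d[3])
    stop(sprintf("sidecar SliceTiming length (%d) does not match z extent (%d)",
                 length(offs_sidecar), d[3]))
  if (!is.null(offs_sidecar) && !is.null(offs_derived) &&
      max(abs(offs_sidecar - offs_derived)) > tol_s)
    stop("sidecar SliceTiming and derived offsets disagree by more than the tolerance")
  offsets <- if (!is.null(offs_sidecar)) offs_sidecar else offs_derived

  fmri_scan(array(as.numeric(img), dim = d), tr_s = tr_used,
            slice_offsets_s = offsets,
            affine = structure(RNifti::xform(img), code = NULL),
            voxel_size_mm = vox)
}

#' Write an fMRI scan to NIfTI plus BIDS sidecar
#'
#' Inverse of \code{\link{load_fmri}}; the array round-trips bit-exactly
#' (stored as 64-bit float).
#'
#' @param scan an \code{fmri_scan}.
#' @param image_path output NIfTI path.
#' @param sidecar_path output JSON path (\code{SliceTiming},
#'   \code{RepetitionTime}).
#' @export
write_fmri <- function(scan, image_path, sidecar_path = NULL) {
  stopifnot(inherits(scan, "fmri_scan"))
  img <- RNifti::asNifti(scan$data)
  RNifti::pixdim(img) <- c(scan$voxel_size_mm, scan$tr_s)
  RNifti::writeNifti(img, image_path, datatype = "double")
  if (!is.null(sidecar_path))
    jsonlite::write_json(
      list(RepetitionTime = scan$tr_s, SliceTiming = scan$slice_offsets_s),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Load an ROI mask and pair it with a scan
#'
#' Nonzero voxels become TRUE. The mask must live on exactly the scan's
#' grid: shape must match and, when both carry an affine, the affines must
#' agree within \code{1e-3}. No resampling is ever attempted; a mismatched
#' grid is an error.
#'
#' @param path NIfTI mask path.
#' @param scan the \code{fmri_scan} the mask annotates.
#' @param label region label stored on the mask.
#' @return An \code{\link{roi_mask}}.
#' @export
load_mask <- function(path, scan, label = "custom") {
  stopifnot(inherits(scan, "fmri_scan"))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  if (length(d) != 3L) stop("mask must be a 3D volume")
  if (!all(d == dim(scan$data)[1:3]))
    stop("mask grid does not match scan grid (no resampling is performed)")
  if (!is.null(scan$affine)) {
    maff <- structure(RNifti::xform(img), code = NULL)
    if (max(abs(maff - scan$affine)) > 1e-3)
      stop("mask affine does not match scan affine (tolerance 1e-3)")
  }
  roi_mask(array(as.numeric(img), dim = d) != 0, label = label)
}

#' Write an ROI mask to NIfTI
#' @param mask an \code{roi_mask}.
#' @param path output path.
#' @param scan optional scan providing voxel dimensions for the header.
#' @export
write_mask <- function(mask, path, scan = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  if (!is.null(scan)) RNifti::pixdim(img) <- scan$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load a physiological recording from single-column text/TSV
#'
#' @param path text file with one numeric sample per row (a header line is
#'   tolerated and skipped).
#' @param fs_hz sampling rate of the recording, Hz.
#' @param start_offset_s offset of the first sample relative to the first
#'   volume, seconds.
#' @return A \code{\link{physio_recording}}.
#' @export
load_physio <- function(path, fs_hz, start_offset_s = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) > 0 && is.na(vals[1]) && !any(is.na(vals[-1])))
    vals <- vals[-1]                               # drop a header line
  if (any(is.na(vals)))
    stop("non-numeric rows in physio file")
  physio_recording(vals, fs_hz = fs_hz, start_offset_s = start_offset_s)
}

#' Load a motion trace from text
#'
#' Accepts either a single column of absolute displacements (mm) or a
#' 6-column rigid-body parameter file (3 rotations in radians then 3
#' translations in mm, the mcflirt \code{.par} layout), in which case the
#' displacement defaults to the Euclidean norm of the translations.
#'
#' @param path whitespace-delimited text, one row per volume.
#' @param displacement_fun for 6-column files, a function mapping the
#'   6-column numeric matrix to a displacement vector; default takes the
#'   Euclidean norm of columns 4:6.
#' @param scan optional \code{fmri_scan}; when given, the trace length must
#'   equal the number of volumes.
#' @return A \code{\link{motion_trace}}.
#' @export
load_motion <- function(path, displacement_fun = NULL, scan = NULL) {
  tab <- utils::read.table(path, header = FALSE)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric rows in motion file")
  disp <- if (ncol(tab) == 1L) {
    tab[[1]]
  } else if (ncol(tab) == 6L) {
    if (is.null(displacement_fun))
      displacement_fun <- function(m) sqrt(rowSums(m[, 4:6, drop = FALSE]^2))
    displacement_fun(as.matrix(tab))
  } else {
    stop(sprintf("motion file must have 1 or 6 columns, found %d", ncol(tab)))
  }
  tr <- motion_trace(disp)
  if (!is.null(scan) && length(tr$displacement_mm) != scan$n_volumes)
    stop(sprintf("motion trace length (%d) does not match scan volumes (%d)",
                 length(tr$displacement_mm), scan$n_volumes))
  tr
}

#' Export a hypersampled signal as TSV
#'
#' Columns \code{time_s}, \code{value}, \code{valid} at the effective
#' sampling interval \code{dt_s}.
#'
#' @param hs a \code{hypersampled_signal}.
#' @param path output TSV path.
#' @export
write_hypersampled_tsv <- function(hs, path) {
  stopifnot(inherits(hs, "hypersampled_signal"))
  df <- data.frame(time_s = (seq_along(hs$values) - 1) * hs$dt_s,
                   value = hs$values, valid = hs$valid)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
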