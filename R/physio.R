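# Photoplethysmography processing: heart-frequency estimation, a spectral
# quality score, and beat-to-beat cardiac phase for retrospective
# realignment.

#' Estimate the fundamental cardiac frequency from a PPG recording
#'
#' Takes the argmax of the recording's periodogram within a physiological
#' search range. The default 0.6-2.0 Hz (36-120 bpm) covers resting adult
#' heart rates across a wide age range; narrow it if the recording is known
#' to be cleaner.
#'
#' @param ppg a \code{physio_recording}.
#' @param search_range_hz length-2 numeric, inclusive frequency window.
#' @return estimated frequency, Hz.
#' @export
estimate_cardiac_frequency <- function(ppg, search_range_hz = c(0.6, 2.0)) {
  stopifnot(inherits(ppg, "physio_recording"))
  n <- length(ppg$samples)
  if (n / ppg$fs_hz < 10)
    stop("PPG recording shorter than 10 s: cardiac frequency unreliable")
  x <- detrend_linear(ppg$samples)
  if (stats::sd(x) == 0) stop("no cardiac peak: PPG signal is constant")
  ps <- periodogram_psd(x, ppg$fs_hz)
  sel <- which(ps$freqs_hz >= search_range_hz[1] &
               ps$freqs_hz <= search_range_hz[2])
  if (!length(sel)) stop("search range contains no frequency bins")
  if (max(ps$psd[sel]) == 0) stop("no cardiac peak in the search range")
  ps$freqs_hz[sel[which.max(ps$psd[sel])]]
}

#' PPG quality score
#'
#' Proportion of the recording's total signal power that lies within the
#' cardiac band \code{f_card +/- halfwidth}. The denominator excludes power
#' below 0.01 Hz so slow baseline wander (common in optical pulse sensors)
#' does not deflate the score. Values near 1 indicate a clean pulse; broad-
#' band noise drives the score toward the band's share of the spectrum.
#'
#' @param ppg a \code{physio_recording}.
#' @param f_card_hz cardiac frequency (estimated or supplied).
#' @param halfwidth_hz cardiac band half-width, Hz.
#' @return fraction in [0, 1].
#' @export
ppg_quality <- function(ppg, f_card_hz, halfwidth_hz = 0.15) {
  stopifnot(inherits(ppg, "physio_recording"))
  x <- detrend_linear(ppg$samples)
  ps <- periodogram_psd(x, ppg$fs_hz)
  total <- bandpower(ps, list(lo_hz = 0.01, hi_hz = ps$fs_hz / 2))
  if (total == 0) stop("zero total power in PPG recording")
  card <- bandpower(ps, list(lo_hz = max(0.01, f_card_hz - halfwidth_hz),
                             hi_hz = min(ps$fs_hz / 2,
                                         f_card_hz + halfwidth_hz)))
  min(1, card / total)
}

#' Detect beats in a PPG recording
#'
#' Band-passes the signal around the cardiac frequency (Butterworth order 2,
#' zero-phase) and takes local maxima separated by at least half a cardiac
#' period. A deliberately simple detector, adequate for clean finger PPG.
#'
#' @param ppg a \code{physio_recording}.
#' @param f_card_hz cardiac frequency, Hz.
#' @param bp_halfwidth_hz band-pass half-width around \code{f_card_hz}.
#' @return beat times in seconds on the scan clock (i.e. including
#'   \code{start_offset_s}).
#' @export
detect_beats <- function(ppg, f_card_hz, bp_halfwidth_hz = 0.3) {
  stopifnot(inherits(ppg, "physio_recording"))
  x <- detrend_linear(ppg$samples)
  nyq <- ppg$fs_hz / 2
  lo <- max(f_card_hz - bp_halfwidth_hz, 0.1) / nyq
  hi <- min(f_card_hz + bp_halfwidth_hz, 0.98 * nyq) / nyq
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  xf <- signal::filtfilt(bf, x)
  min_sep <- max(1L, floor(0.5 / f_card_hz * ppg$fs_hz))
  n <- length(xf)
  is_peak <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] &
                      xf[2:(n - 1)] >= xf[3:n], FALSE)
  cand <- which(is_peak)
  cand <- cand[order(xf[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in cand)                            # greedy peak pruning by height
    if (!any(keep[max(1, i - min_sep):min(n, i + min_sep)])) keep[i] <- TRUE
  beats <- sort(which(keep))
  if (length(beats) < 3) stop("fewer than 3 beats detected")
  (beats - 1) / ppg$fs_hz + ppg$start_offset_s
}

#' Cardiac phase at arbitrary scan times
#'
#' Phase is the elapsed fraction of the current beat-to-beat interval:
#' linear interpolation between detected beat times, 0 exactly at a beat.
#' Times before the first or after the last detected beat cannot be
#' assigned a phase and are masked out. Phase is by construction invariant
#' to PPG amplitude scaling and DC offset.
#'
#' @param ppg a \code{physio_recording}.
#' @param f_card_hz cardiac frequency, Hz.
#' @param times_s scan times at which the phase is wanted, seconds.
#' @param beats optional precomputed beat times (skips detection).
#' @return list with \code{phase} (in [0,1), NA where undefined) and
#'   \code{valid} (logical mask).
#' @export
cardiac_phase <- function(ppg, f_card_hz, times_s, beats = NULL) {
  if (is.null(beats)) beats <- detect_beats(ppg, f_card_hz)
  if (length(beats) < 3) stop("fewer than 3 beats detected")
  valid <- times_s >= beats[1] & times_s < beats[length(beats)]
  phase <- rep(NA_real_, length(times_s))
  idx <- findInterval(times_s[valid], beats)
  phase[valid] <- (times_s[valid] - beats[idx]) /
    (beats[idx + 1] - beats[idx])
  list(phase = phase, valid = valid, beats = beats)
}

#' Summarize a PPG recording into cardiac information
#'
#' Convenience wrapper: frequency estimate, quality score and beat list in
#' one object, serializable into the run report.
#'
#' @param ppg a \code{physio_recording}.
#' @param search_range_hz passed to \code{\link{estimate_cardiac_frequency}}.
#' @param halfwidth_hz cardiac band half-width for the quality score.
#' @return An object of class \code{cardiac_info} with fields
#'   \code{f_card_hz}, \code{quality}, \code{beats}.
#' @export
cardiac_info <- function(ppg, search_range_hz = c(0.6, 2.0),
                         halfwidth_hz = 0.15) {
  f <- estimate_cardiac_frequency(ppg, search_range_hz)
  q <- ppg_quality(ppg, f, halfwidth_hz)
  beats <- tryCatch(detect_beats(ppg, f), error = function(e) numeric(0))
  structure(list(f_card_hz = f, quality = q, beats = beats, ppg = ppg),
            class = "cardiac_info")
}

#' @export
print.cardiac_info <- function(x, ...) {
  cat(sprintf("<cardiac_info> f_card = %.3f Hz (%.0f bpm), quality = %.2f, %d beats\n",
              x$f_card_hz, 60 * x$f_card_hz, x$quality, length(x$beats)))
  invisible(x)
}
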