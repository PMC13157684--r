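# Spectral estimation: rectangular-window periodogram, physiological band
# definitions, integrated bandpower, and the two analytic oracles used in
# validation (alias folding and slice-averaging attenuation).

#' One-sided periodogram power spectral density
#'
#' Demeans the input and computes the raw (rectangular-window, unpadded)
#' periodogram \eqn{|X_k|^2 / (f_s N)}, one-sided: bins other than DC and
#' (for even N) Nyquist are doubled. Satisfies Parseval's identity:
#' \code{sum(psd) * df} equals the mean square of the demeaned input. Raw
#' periodogram rather than Welch averaging is used deliberately: absolute
#' bandpower is the quantity of interest, and segment averaging would change
#' its scale and resolution.
#'
#' @param values numeric vector, length >= 8, no NA (fill gaps upstream).
#' @param fs_hz sampling rate, Hz.
#' @param tr_s optional original repetition time; when given, bins within
#'   half a bin of a multiple of \code{1/tr_s} are flagged as potential
#'   slice-stitching residual lines in the \code{stitch_lines_hz} attribute.
#' @return An object of class \code{power_spectrum}: \code{freqs_hz},
#'   \code{psd} (units^2/Hz), \code{df_hz}, \code{n_samples}, \code{fs_hz}.
#' @export
periodogram_psd <- function(values, fs_hz, tr_s = NULL) {
  n <- length(values)
  if (n < 8L) stop("periodogram requires at least 8 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("periodogram input contains NA or non-finite values; fill gaps upstream")
  x <- values - mean(values)
  X <- stats::fft(x)
  nk <- n %/% 2 + 1L                      # DC .. Nyquist (or near-Nyquist)
  p <- (Mod(X[seq_len(nk)])^2) / (fs_hz * n)
  scale <- rep(2, nk); scale[1] <- 1
  if (n %% 2 == 0) scale[nk] <- 1         # true Nyquist bin is unpaired
  psd <- p * scale
  freqs <- (seq_len(nk) - 1) * fs_hz / n
  stitch <- NULL
  if (!is.null(tr_s)) {
    k <- seq_len(floor(max(freqs) * tr_s))
    if (length(k)) {
      lines_hz <- k / tr_s
      hit <- vapply(lines_hz, function(f) any(abs(freqs - f) <= fs_hz / n / 2),
                    logical(1))
      stitch <- lines_hz[hit]
    }
  }
  structure(list(freqs_hz = freqs, psd = psd, df_hz = fs_hz / n,
                 n_samples = n, fs_hz = fs_hz, stitch_lines_hz = stitch),
            class = "power_spectrum")
}

#' Physiological frequency bands
#'
#' Fixed low-frequency-oscillation and respiratory bands plus a cardiac band
#' centred on the measured heart frequency: LFO 0.01-0.1 Hz, respiratory
#' 0.2-0.4 Hz, cardiac \code{f_card +/- halfwidth}. A slow heart rate
#' (\code{f_card - halfwidth < 0.4}) makes the cardiac band overlap the
#' respiratory band; the overlap is flagged, not silently ignored.
#'
#' @param f_card_hz heart frequency, Hz.
#' @param halfwidth_hz cardiac band half-width (default 0.15 Hz).
#' @return list of three band definitions (\code{name}, \code{lo_hz},
#'   \code{hi_hz}), with attribute \code{overlap_warning} set when cardiac
#'   and respiratory bands intersect.
#' @export
make_bands <- function(f_card_hz, halfwidth_hz = 0.15) {
  if (f_card_hz <= halfwidth_hz)
    stop("cardiac frequency must exceed the band half-width")
  bands <- list(
    list(name = "lfo", lo_hz = 0.01, hi_hz = 0.1),
    list(name = "resp", lo_hz = 0.2, hi_hz = 0.4),
    list(name = "cardiac", lo_hz = f_card_hz - halfwidth_hz,
         hi_hz = f_card_hz + halfwidth_hz))
  attr(bands, "overlap_warning") <- (f_card_hz - halfwidth_hz) < 0.4
  bands
}

#' Integrated power in a frequency band
#'
#' Integrates the PSD over \code{[lo, hi]} by summing \code{psd * df} over
#' the bins whose centre frequency falls inside the band (closed interval).
#' The bin-centre rule is stated explicitly because absolute bandpower
#' comparisons depend on the edge convention. A warning is emitted when the
#' band contains a flagged stitching line at a multiple of 1/TR.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param band a band definition from \code{\link{make_bands}} (or any list
#'   with \code{lo_hz}, \code{hi_hz}).
#' @return scalar power, signal units squared.
#' @export
bandpower <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  nyq <- spectrum$fs_hz / 2
  if (band$hi_hz > nyq + 1e-12)
    stop(sprintf("band [%.3g, %.3g] Hz exceeds the Nyquist frequency %.4g Hz",
                 band$lo_hz, band$hi_hz, nyq))
  if (band$lo_hz >= band$hi_hz || band$lo_hz < 0)
    stop("band edges must satisfy 0 <= lo < hi")
  sel <- spectrum$freqs_hz >= band$lo_hz - 1e-12 &
         spectrum$freqs_hz <= band$hi_hz + 1e-12
  if (!is.null(spectrum$stitch_lines_hz)) {
    inside <- spectrum$stitch_lines_hz >= band$lo_hz &
              spectrum$stitch_lines_hz <= band$hi_hz
    if (any(inside))
      warning(sprintf("band [%.3g, %.3g] Hz contains possible stitching line(s) at %s Hz",
                      band$lo_hz, band$hi_hz,
                      paste(signif(spectrum$stitch_lines_hz[inside], 4),
                            collapse = ", ")))
  }
  sum(spectrum$psd[sel]) * spectrum$df_hz
}

#' Aliased (folded) frequency under uniform sampling
#'
#' A component at \code{f} sampled at \code{fs} appears at
#' \code{|f - round(f/fs) * fs|}, always within \code{[0, fs/2]}. At the
#' per-volume rate of a typical multiband protocol (e.g. 1.25 Hz for TR
#' 0.8 s) a 1 Hz cardiac pulsation folds to 0.25 Hz, inside the respiratory
#' band — the contamination hypersampling removes.
#'
#' @param f_hz true frequency, Hz.
#' @param fs_hz sampling rate, Hz.
#' @return apparent frequency, Hz. Vectorised over \code{f_hz}.
#' @export
alias_frequency <- function(f_hz, fs_hz) {
  stopifnot(all(f_hz > 0), fs_hz > 0)
  abs(f_hz - round(f_hz / fs_hz) * fs_hz)
}

#' Amplitude attenuation from averaging across slice timings
#'
#' Averaging an ROI across slices ignores slice timing: the contributing
#' slices sample a sinusoid at \code{N} phases spaced \code{TR/N} apart, and
#' their mean has amplitude
#' \deqn{\left|\frac{1}{N}\sum_{j=0}^{N-1} e^{i 2\pi f j TR / N}\right| =
#'       \frac{|\sin(\pi f TR)|}{N |\sin(\pi f TR / N)|}}
#' (a Dirichlet kernel), which tends to 1 as \code{f -> 0} and can be far
#' below 1 at cardiac frequencies. The squared value predicts the power an
#' ROI-mean series loses relative to the hypersampled reconstruction —
#' the mechanism behind the near-unity LFO/respiratory agreement versus the
#' inflated hypersampled-to-ROI-mean cardiac slope.
#'
#' @param f_hz frequency of the component, Hz (vectorised).
#' @param tr_s repetition time, seconds.
#' @param n_time number of distinct slice timings averaged.
#' @return amplitude ratio in [0, 1].
#' @export
averaging_attenuation <- function(f_hz, tr_s, n_time) {
  stopifnot(n_time >= 1)
  vapply(f_hz, function(f) {
    # evaluate the Dirichlet sum directly; no removable singularities
    Mod(sum(exp(2i * pi * f * tr_s * (0:(n_time - 1)) / n_time))) / n_time
  }, numeric(1))
}

#' Export a power spectrum as TSV
#' @param spectrum a \code{power_spectrum}.
#' @param path output TSV path (columns \code{freq_hz}, \code{psd}).
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(freq_hz = spectrum$freqs_hz, psd = spectrum$psd),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
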