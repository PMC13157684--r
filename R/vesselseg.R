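# Data-driven vessel segmentation: voxels whose cardiac-cycle-aligned
# waveform reproduces across two random halves of the timepoints are
# pulsatile (vascular); thresholding the split-half correlation inside a
# search region yields the artery / superior-sagittal-sinus masks.

#' Bin a voxel time series by cardiac phase
#'
#' Retrospective realignment to the cardiac cycle: the detrended series is
#' averaged within equal-width phase bins. Bins that receive no sample are
#' returned as NA; more than half the bins empty is an error (the waveform
#' would be meaningless).
#'
#' @param voxel_series numeric vector (one value per retained volume).
#' @param volume_phases cardiac phase in [0,1) per retained volume.
#' @param n_phase_bins number of bins over one cardiac cycle (>= 4).
#' @param detrend detrend the series first (default TRUE; set FALSE if it
#'   was already detrended upstream).
#' @return numeric vector of bin means, length \code{n_phase_bins}, with
#'   attribute \code{bin_centers} (phase at bin centres).
#' @export
cardiac_realign <- function(voxel_series, volume_phases, n_phase_bins = 10,
                            detrend = TRUE) {
  if (n_phase_bins < 4) stop("need at least 4 phase bins")
  if (length(voxel_series) != length(volume_phases))
    stop("series and phase vectors differ in length")
  keep <- !is.na(volume_phases)
  x <- if (detrend) detrend_linear(voxel_series) else voxel_series
  x <- x[keep]
  ph <- volume_phases[keep]
  if (any(ph < 0 | ph >= 1)) stop("phases must lie in [0, 1)")
  bin <- pmin(floor(ph * n_phase_bins) + 1L, n_phase_bins)
  out <- rep(NA_real_, n_phase_bins)
  means <- tapply(x, factor(bin, levels = seq_len(n_phase_bins)), mean)
  out[] <- as.numeric(means)
  if (sum(is.na(out)) > n_phase_bins / 2)
    stop("more than half the cardiac phase bins are empty")
  attr(out, "bin_centers") <- (seq_len(n_phase_bins) - 0.5) / n_phase_bins
  out
}

#' Split-half cardiac-aligned pulsatility map
#'
#' For every voxel (optionally restricted to a mask for speed): the volumes
#' are split by a seeded random permutation into two equal halves, each half
#' is realigned to the cardiac cycle (\code{\link{cardiac_realign}}), and
#' the Pearson correlation between the two binned waveforms is recorded.
#' Genuinely pulsatile voxels reproduce their waveform and score near 1;
#' noise voxels scatter around 0. The cardiac phase of a volume is evaluated
#' at the volume's mean slice-acquisition offset.
#'
#' @param scan an \code{fmri_scan}.
#' @param cinfo a \code{cardiac_info} for the simultaneous PPG recording.
#' @param n_phase_bins cardiac-cycle bins (default 10).
#' @param seed integer seed for the random split.
#' @param mask optional \code{roi_mask} restricting the computation.
#' @param split \code{"random"} (default) or \code{"duplicate"} (both halves
#'   are all volumes — a self-check that must give r = 1).
#' @return 3D array of correlations in [-1, 1] (NA outside \code{mask} or
#'   where a waveform is degenerate).
#' @export
split_half_pulsatility_map <- function(scan, cinfo, n_phase_bins = 10,
                                       seed = 1L, mask = NULL,
                                       split = c("random", "duplicate")) {
  stopifnot(inherits(scan, "fmri_scan"), inherits(cinfo, "cardiac_info"))
  split <- match.arg(split)
  nt <- scan$n_volumes
  if (nt < 4 * n_phase_bins)
    stop(sprintf("need at least %d volumes for %d phase bins",
                 4 * n_phase_bins, n_phase_bins))
  t_vol <- (seq_len(nt) - 1) * scan$tr_s + mean(scan$slice_offsets_s)
  ph <- cardiac_phase(cinfo$ppg, cinfo$f_card_hz, t_vol,
                      beats = if (length(cinfo$beats)) cinfo$beats)$phase
  if (sum(!is.na(ph)) < 4 * n_phase_bins)
    stop("too few volumes with defined cardiac phase: check PPG/scan alignment")

  if (split == "duplicate") {
    half1 <- half2 <- seq_len(nt)
  } else {
    perm <- with_seed(seed, sample.int(nt))
    half1 <- sort(perm[seq_len(nt %/% 2)])
    half2 <- sort(perm[(nt %/% 2 + 1):nt])
  }

  dims <- dim(scan$data)[1:3]
  voxels <- if (is.null(mask)) seq_len(prod(dims)) else which(mask$mask)
  flat <- matrix(scan$data, nrow = prod(dims), ncol = nt)
  out <- array(NA_real_, dim = dims)
  for (v in voxels) {
    series <- detrend_linear(flat[v, ])
    w1 <- tryCatch(cardiac_realign(series[half1], ph[half1], n_phase_bins,
                                   detrend = FALSE),
                   error = function(e) NULL)
    w2 <- tryCatch(cardiac_realign(series[half2], ph[half2], n_phase_bins,
                                   detrend = FALSE),
                   error = function(e) NULL)
    if (is.null(w1) || is.null(w2)) next
    ok <- !is.na(w1) & !is.na(w2)
    if (sum(ok) < 3) next
    if (stats::sd(w1[ok]) == 0 || stats::sd(w2[ok]) == 0) next
    out[v] <- stats::cor(w1[ok], w2[ok])
  }
  out
}

# largest 6-connected component of a 3D logical array (simple BFS; vessel
# masks are small)
largest_component <- function(m) {
  dims <- dim(m)
  lab <- array(0L, dim = dims)
  cur <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(p, ncol = 3)
    lab[p[1], p[2], p[3]] <- cur
    while (nrow(queue) > 0) {
      q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in 1:6) {
        nb <- q + nbr[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (m[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  if (cur == 0L) return(m)
  counts <- tabulate(lab[lab > 0L], nbins = cur)
  lab == which.max(counts)
}

#' Threshold a pulsatility map into a vessel mask
#'
#' Keeps voxels with split-half correlation at or above the threshold inside
#' the search region. The defaults (threshold 0.5, 10 phase bins) are
#' pragmatic configuration values, surfaced in the run report so they are
#' never silent.
#'
#' @param pulsatility_map 3D correlation array from
#'   \code{\link{split_half_pulsatility_map}}.
#' @param search_mask an \code{roi_mask} delimiting where the target vessel
#'   may lie.
#' @param r_threshold correlation cutoff in (0, 1).
#' @param min_voxels minimal acceptable mask size; fewer voxels is an error
#'   (the segmentation is deemed unreliable, mirroring the QC exclusions).
#' @param keep_largest retain only the largest 6-connected component.
#' @param label label for the output mask.
#' @return An \code{roi_mask}.
#' @export
segment_vessels <- function(pulsatility_map, search_mask, r_threshold = 0.5,
                            min_voxels = 1L, keep_largest = FALSE,
                            label = "vessel") {
  stopifnot(inherits(search_mask, "roi_mask"))
  if (!all(dim(pulsatility_map) == dim(search_mask$mask)))
    stop("pulsatility map and search mask are on different grids")
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must lie in (0, 1)")
  sel <- !is.na(pulsatility_map) & pulsatility_map >= r_threshold &
         search_mask$mask
  if (keep_largest && any(sel)) sel <- largest_component(sel)
  if (sum(sel) < min_voxels)
    stop(sprintf("unreliable vessel segmentation: %d voxel(s) above threshold (need >= %d)",
                 sum(sel), min_voxels))
  roi_mask(sel, label = label)
}

#' Dice overlap between two masks
#'
#' @param a,b \code{roi_mask} objects (or 3D logical arrays) on the same
#'   grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  stopifnot(all(dim(ma) == dim(mb)))
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
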