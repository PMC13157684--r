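# Synthetic multiband fMRI phantom with known physiological ground truth.
# Every voxel carries a sum of compartment-specific sinusoids (LFO,
# respiratory, cardiac with optional harmonics), optionally phase-delayed by
# a travelling wave, sampled at its slice's acquisition times, plus a
# per-slice baseline gradient and white Gaussian noise. A matched PPG pulse
# train is generated at the cardiac frequency.

#' Specify a synthetic phantom
#'
#' @param nx,ny,nz grid dimensions; \code{nz} must be divisible by
#'   \code{mb_factor}.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of volumes.
#' @param mb_factor multiband factor.
#' @param ordering slice-timing group order within the TR (see
#'   \code{\link{derive_slice_offsets}}).
#' @param freqs_hz named vector of component frequencies; defaults place one
#'   component per physiological band: LFO 0.05 Hz, respiratory 0.3 Hz,
#'   cardiac 1.0 Hz.
#' @param speeds_m_s named vector of propagation speeds; \code{Inf} means
#'   coherent (no phase delay). Defaults are test conveniences in the
#'   physiologically motivated order — fast cardiac pulse-wave (2 m/s), slow
#'   respiratory spread (0.1 m/s), coherent LFO.
#' @param compartments named list; each element is a list with \code{mask}
#'   (3D logical on the grid) and \code{amp} (named numeric, amplitude per
#'   component, same names as \code{freqs_hz}). \code{NULL} gives a single
#'   whole-volume compartment \code{"GM"} with unit amplitudes.
#' @param n_harmonics harmonics of the cardiac waveform in the fMRI signal
#'   (amplitude decaying as 1/h); 1 keeps the signal a pure sinusoid so
#'   analytic power predictions hold exactly.
#' @param noise_sd standard deviation of additive white Gaussian noise.
#' @param baseline_range peak-to-peak amplitude of a linear per-slice
#'   baseline gradient emulating coil/slice-profile differences (exercises
#'   the detrend step that prevents stitching artifacts).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param source_voxel origin (1-based voxel index, length 3) from which
#'   propagation distance is measured.
#' @param ppg_fs_hz PPG sampling rate, Hz (>= 50).
#' @param seed integer seed; all phantom randomness flows from it.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(nx = 8, ny = 8, nz = 40, tr_s = 0.366,
                         n_volumes = 500, mb_factor = 8,
                         ordering = "sequential",
                         freqs_hz = c(lfo = 0.05, resp = 0.3, cardiac = 1.0),
                         speeds_m_s = c(lfo = Inf, resp = 0.1, cardiac = 2),
                         compartments = NULL,
                         n_harmonics = 1L, noise_sd = 0,
                         baseline_range = 1, voxel_size_mm = 2.5,
                         source_voxel = c(1, 1, 1),
                         ppg_fs_hz = 100, seed = 1L) {
  if (nz %% mb_factor != 0)
    stop("nz must be divisible by mb_factor")
  if (any(freqs_hz <= 0)) stop("component frequencies must be positive")
  band_ok <- c(
    lfo = is.na(freqs_hz["lfo"]) ||
      (freqs_hz["lfo"] >= 0.01 && freqs_hz["lfo"] <= 0.1),
    resp = is.na(freqs_hz["resp"]) ||
      (freqs_hz["resp"] >= 0.2 && freqs_hz["resp"] <= 0.4),
    cardiac = is.na(freqs_hz["cardiac"]) ||
      (freqs_hz["cardiac"] >= 0.5 && freqs_hz["cardiac"] <= 2.0))
  if (!all(band_ok))
    stop("component frequencies must lie in their physiological bands: LFO [0.01, 0.1], resp [0.2, 0.4], cardiac [0.5, 2.0] Hz")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ppg_fs_hz < 50) stop("PPG sampling rate must be >= 50 Hz")
  if (is.null(compartments)) {
    m <- array(TRUE, dim = c(nx, ny, nz))
    compartments <- list(GM = list(mask = m,
                                   amp = stats::setNames(rep(1, length(freqs_hz)),
                                                         names(freqs_hz))))
  }
  for (nm in names(compartments)) {
    cp <- compartments[[nm]]
    if (!all(dim(cp$mask) == c(nx, ny, nz)))
      stop(sprintf("compartment '%s' mask does not match the grid", nm))
    if (any(cp$amp < 0)) stop("amplitudes must be >= 0")
    if (!all(names(cp$amp) %in% names(freqs_hz)))
      stop(sprintf("compartment '%s' has amplitudes for unknown components", nm))
  }
  structure(list(nx = nx, ny = ny, nz = nz, tr_s = tr_s,
                 n_volumes = n_volumes, mb_factor = mb_factor,
                 ordering = ordering, freqs_hz = freqs_hz,
                 speeds_m_s = speeds_m_s, compartments = compartments,
                 n_harmonics = as.integer(n_harmonics),
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 voxel_size_mm = voxel_size_mm,
                 source_voxel = source_voxel, ppg_fs_hz = ppg_fs_hz,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Acquisition presets for the phantom
#'
#' \code{"hcp_like"} emulates the HCP-Aging protocol (72 slices, MB 8,
#' TR 0.8 s, 488 volumes, 2 mm voxels; N_Time = 9);
#' \code{"local_like"} the fast local protocol (40 slices, MB 8, TR 0.366 s,
#' 500 volumes, 2.5 mm voxels; N_Time = 5);
#' \code{"propagation_demo"} is the local protocol with a fast cardiac
#' pulse wave (3 m/s), a slow respiratory wave (0.05 m/s) and coherent LFO,
#' illustrating destructive interference of short-wavelength components.
#'
#' @param preset one of \code{"hcp_like"}, \code{"local_like"},
#'   \code{"propagation_demo"}.
#' @param ... overrides passed on to \code{\link{phantom_spec}}.
#' @return A \code{phantom_spec}.
#' @export
phantom_preset <- function(preset = c("hcp_like", "local_like",
                                      "propagation_demo"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    hcp_like = list(nz = 72, mb_factor = 8, tr_s = 0.8, n_volumes = 488,
                    voxel_size_mm = 2.0),
    local_like = list(nz = 40, mb_factor = 8, tr_s = 0.366, n_volumes = 500,
                      voxel_size_mm = 2.5),
    propagation_demo = list(nz = 40, mb_factor = 8, tr_s = 0.366,
                            n_volumes = 500, voxel_size_mm = 2.5,
                            speeds_m_s = c(lfo = Inf, resp = 0.05,
                                           cardiac = 3)))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

#' Default four-compartment layout
#'
#' Splits the grid along x into four strips standing in for the large
#' cerebral arteries, superior sagittal sinus, gray matter and white matter,
#' each spanning all slices so slice-timing coverage is complete. Amplitude
#' patterns follow the characteristic physiology: cardiac-dominant artery,
#' mixed SSS, LFO-dominant GM and WM.
#'
#' @param nx,ny,nz grid dimensions (nx >= 4).
#' @return named compartment list for \code{\link{phantom_spec}}.
#' @export
default_compartments <- function(nx = 8, ny = 8, nz = 40) {
  stopifnot(nx >= 4)
  strip <- function(cols) {
    m <- array(FALSE, dim = c(nx, ny, nz)); m[cols, , ] <- TRUE; m
  }
  edges <- round(seq(0, nx, length.out = 5))
  cols <- lapply(1:4, function(i) (edges[i] + 1):edges[i + 1])
  list(
    artery = list(mask = strip(cols[[1]]),
                  amp = c(lfo = 0.3, resp = 0.4, cardiac = 3)),
    SSS = list(mask = strip(cols[[2]]),
               amp = c(lfo = 1.2, resp = 1, cardiac = 2)),
    GM = list(mask = strip(cols[[3]]),
              amp = c(lfo = 2, resp = 0.6, cardiac = 0.5)),
    WM = list(mask = strip(cols[[4]]),
              amp = c(lfo = 0.8, resp = 0.25, cardiac = 0.3)))
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic phantom
#'
#' Voxel \code{v} in compartment \code{c}, slice \code{s}, volume \code{k}
#' takes the value
#' \deqn{b(s) + \sum_{comp} \sum_{h=1}^{H} \frac{a_{c,comp}}{h}
#'   \sin\!\big(2\pi h f_{comp} (t_{k,s} - \tau_{comp}(v))\big) +
#'   \mathcal{N}(0, \sigma^2)}
#' with \code{t_{k,s} = (k-1) TR + offset(s)} and travelling-wave delay
#' \code{tau = distance(v, source) / speed} (0 when coherent). Harmonics
#' apply to the cardiac component only. The matched PPG trace is a peaked
#' periodic pulse waveform at the cardiac frequency.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with elements \code{scan} (\code{fmri_scan}), \code{ppg}
#'   (\code{physio_recording}), \code{masks} (named list of
#'   \code{roi_mask}), and \code{truth}: a data frame
#'   (\code{compartment}, \code{band}, \code{power}) of exact
#'   continuous-time in-band power, \code{sum(amp^2/2)} over the in-band
#'   sinusoids.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz; nt <- spec$n_volumes
  offsets <- derive_slice_offsets(nz, spec$mb_factor, spec$tr_s,
                                  spec$ordering)
  # enumerate elementary sinusoids: (component, harmonic) -> freq, relamp
  comps <- names(spec$freqs_hz)
  sines <- do.call(rbind, lapply(comps, function(cn) {
    H <- if (cn == "cardiac") spec$n_harmonics else 1L
    data.frame(component = cn, harmonic = seq_len(H),
               freq_hz = spec$freqs_hz[[cn]] * seq_len(H),
               relamp = 1 / seq_len(H),
               speed = spec$speeds_m_s[[cn]])
  }))

  baseline <- if (nz > 1)
    spec$baseline_range * (seq_len(nz) - 1) / (nz - 1) else rep(0, nz)

  # propagation delay per voxel (seconds) for a given speed
  ix <- (seq_len(nx) - spec$source_voxel[1])
  iy <- (seq_len(ny) - spec$source_voxel[2])
  iz <- (seq_len(nz) - spec$source_voxel[3])
  dist_mm <- sqrt(outer(outer(ix^2, iy^2, "+"),  iz^2, "+")) * spec$voxel_size_mm

  data <- array(0, dim = c(nx, ny, nz, nt))
  kvec <- seq_len(nt) - 1
  for (s in seq_len(nz)) {
    t_s <- kvec * spec$tr_s + offsets[s]
    plane <- matrix(baseline[s], nrow = nx * ny, ncol = nt)
    for (cname in names(spec$compartments)) {
      cp <- spec$compartments[[cname]]
      vox <- which(cp$mask[, , s])
      if (!length(vox)) next
      contrib <- matrix(0, nrow = length(vox), ncol = nt)
      for (r in seq_len(nrow(sines))) {
        a <- cp$amp[sines$component[r]]
        if (is.na(a) || a == 0) next
        f <- sines$freq_hz[r]
        tau <- if (is.finite(sines$speed[r]))
          (dist_mm[, , s][vox] / 1000) / sines$speed[r] else rep(0, length(vox))
        # rows: voxels (phase), cols: volumes (time)
        contrib <- contrib + a * sines$relamp[r] *
          sin(outer(-2 * pi * f * tau, 2 * pi * f * t_s, "+"))
      }
      plane[vox, ] <- plane[vox, ] + contrib
    }
    data[, , s, ] <- plane
  }
  if (spec$noise_sd > 0)
    data <- data + with_seed(spec$seed,
      array(stats::rnorm(length(data), sd = spec$noise_sd), dim = dim(data)))

  scan <- fmri_scan(data, tr_s = spec$tr_s, slice_offsets_s = offsets,
                    voxel_size_mm = rep(spec$voxel_size_mm, 3))

  # PPG: peaked pulse waveform at the cardiac frequency (sum of decaying
  # cosine harmonics -> one sharp maximum per cycle at t = m / f_card)
  f_card <- spec$freqs_hz[["cardiac"]]
  tp <- seq(0, nt * spec$tr_s, by = 1 / spec$ppg_fs_hz)
  ppg_vals <- Reduce(`+`, lapply(1:4, function(h)
    cos(2 * pi * h * f_card * tp) / h))
  ppg <- physio_recording(ppg_vals, fs_hz = spec$ppg_fs_hz)

  masks <- lapply(names(spec$compartments), function(nm)
    roi_mask(spec$compartments[[nm]]$mask, label = nm))
  names(masks) <- names(spec$compartments)

  bands <- make_bands(f_card)
  truth <- do.call(rbind, lapply(names(spec$compartments), function(nm) {
    cp <- spec$compartments[[nm]]
    pw <- vapply(bands, function(b) {
      inb <- sines$freq_hz >= b$lo_hz & sines$freq_hz <= b$hi_hz
      amps <- cp$amp[sines$component[inb]] * sines$relamp[inb]
      amps[is.na(amps)] <- 0
      sum(amps^2 / 2)
    }, numeric(1))
    data.frame(compartment = nm,
               band = vapply(bands, `[[`, character(1), "name"),
               power = pw, row.names = NULL)
  }))

  list(scan = scan, ppg = ppg, masks = masks, truth = truth, spec = spec)
}

#' Write a phantom dataset to disk
#'
#' Produces a complete file set runnable by the pipeline: 4D NIfTI + BIDS
#' sidecar, PPG TSV, one mask NIfTI per compartment, and an all-zero motion
#' trace.
#'
#' @param phantom output of \code{\link{generate_phantom}}.
#' @param outdir output directory (created if missing).
#' @param prefix filename prefix.
#' @return named character vector of the files written.
#' @export
write_phantom <- function(phantom, outdir, prefix = "phantom") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(prefix, ...))
  files <- c(image = p("_bold.nii.gz"), sidecar = p("_bold.json"),
             physio = p("_physio.tsv"), motion = p("_motion.txt"))
  write_fmri(phantom$scan, files[["image"]], files[["sidecar"]])
  writeLines(format(phantom$ppg$samples, digits = 10, trim = TRUE),
             files[["physio"]])
  writeLines(format(rep(0, phantom$scan$n_volumes)), files[["motion"]])
  for (nm in names(phantom$masks)) {
    f <- p("_mask-", nm, ".nii.gz")
    write_mask(phantom$masks[[nm]], f, scan = phantom$scan)
    files[paste0("mask_", nm)] <- f
  }
  files
}
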