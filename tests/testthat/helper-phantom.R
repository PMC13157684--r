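# Shared builders for small test objects. Everything is generated in code;
# no stored fixtures.

# a tiny scan with explicitly controlled voxel values
tiny_scan <- function(nx = 2, ny = 2, nz = 4, nt = 20, tr_s = 0.5,
                      offsets = NULL, fill = 0) {
  if (is.null(offsets)) offsets <- (seq_len(nz) - 1) %% (nz / 2) * tr_s / (nz / 2)
  fmri_scan(array(fill, dim = c(nx, ny, nz, nt)), tr_s = tr_s,
            slice_offsets_s = offsets)
}

# single-compartment noiseless coherent phantom with one active component
single_sine_phantom <- function(f_hz, preset = "local_like", amp = 1,
                                nx = 4, ny = 4, n_volumes = NULL, ...) {
  comp_name <- if (f_hz <= 0.1) "lfo" else if (f_hz <= 0.4) "resp" else "cardiac"
  freqs <- c(lfo = 0.05, resp = 0.3, cardiac = 1.0)
  amps <- c(lfo = 0, resp = 0, cardiac = 0)
  freqs[comp_name] <- f_hz
  amps[comp_name] <- amp
  base <- phantom_preset(preset)
  nv <- if (is.null(n_volumes)) base$n_volumes else n_volumes
  cmp <- list(R = list(mask = array(TRUE, c(nx, ny, base$nz)), amp = amps))
  phantom_preset(preset, nx = nx, ny = ny, n_volumes = nv, noise_sd = 0,
                 compartments = cmp, freqs_hz = freqs,
                 speeds_m_s = c(lfo = Inf, resp = Inf, cardiac = Inf), ...)
}

# vessel-segmentation scenario: a 2x2x12 vessel block inside an 8x8x20 grid,
# search region = vessel dilated by one voxel, pulsatile background tissue
vessel_scenario <- function(seed = 1, noise_sd = 1, cardiac_amp = 5,
                            n_volumes = 500) {
  m_ves <- array(FALSE, c(8, 8, 20)); m_ves[4:5, 4:5, 5:16] <- TRUE
  dil <- array(FALSE, c(8, 8, 20))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    dil[pmax(pmin(4:5 + dx, 8), 1), pmax(pmin(4:5 + dy, 8), 1),
        pmax(pmin(5:16 + dz, 20), 1)] <- TRUE
  comp <- list(
    vessel = list(mask = m_ves,
                  amp = c(lfo = 0.2, resp = 0.2, cardiac = cardiac_amp)),
    tissue = list(mask = !m_ves, amp = c(lfo = 0.5, resp = 0.2, cardiac = 0)))
  spec <- phantom_spec(nx = 8, ny = 8, nz = 20, mb_factor = 4, tr_s = 0.366,
                       n_volumes = n_volumes, noise_sd = noise_sd,
                       compartments = comp, seed = seed,
                       freqs_hz = c(lfo = 0.05, resp = 0.3, cardiac = 1.07))
  list(spec = spec, search = roi_mask(dil, "search"))
}

# independent O(N^2) DFT periodogram oracle (one-sided, demeaned)
naive_periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  nk <- n %/% 2 + 1L
  psd <- numeric(nk)
  for (k in seq_len(nk)) {
    w <- exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n)
    psd[k] <- Mod(sum(x * w))^2 / (fs * n)
  }
  scale <- rep(2, nk); scale[1] <- 1
  if (n %% 2 == 0) scale[nk] <- 1
  list(freqs = (seq_len(nk) - 1) * fs / n, psd = psd * scale)
}
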