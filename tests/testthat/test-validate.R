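test_that("ROI-mean power approximates hypersampled power at low frequencies", {
  # coherent LFO-only phantom: attenuation at 0.05 Hz is ~1, so the two
  # measures agree within 5%
  spec <- single_sine_phantom(0.05, "local_like", nx = 2, ny = 2,
                              n_volumes = 400)
  ph <- generate_phantom(spec)
  bands <- make_bands(1.0)
  hp <- hypersampled_power(ph$scan, ph$masks$R, bands)
  rp <- roi_mean_power(ph$scan, ph$masks$R, bands)
  ratio <- rp$power[rp$band == "lfo"] / hp$power[hp$band == "lfo"]
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
})

test_that("n_time = 1 makes ROI-mean and hypersampled power identical", {
  offs <- rep(0, 4)
  set.seed(12)
  scan <- fmri_scan(array(rnorm(2 * 2 * 4 * 128), c(2, 2, 4, 128)), 0.5, offs)
  m <- roi_mask(array(TRUE, c(2, 2, 4)))
  bands <- list(list(name = "low", lo_hz = 0.05, hi_hz = 0.3),
                list(name = "high", lo_hz = 0.5, hi_hz = 0.9))
  hp <- hypersampled_power(scan, m, bands)
  rp <- roi_mean_power(scan, m, bands)
  expect_equal(hp$power, rp$power, tolerance = 1e-10)
})

test_that("cardiac band above the per-volume Nyquist errors for slow scans", {
  spec <- single_sine_phantom(0.05, "hcp_like", nx = 2, ny = 2,
                              n_volumes = 100)
  ph <- generate_phantom(spec)
  bands <- make_bands(1.0)      # cardiac band up to 1.15 Hz > 0.625 Hz
  expect_error(roi_mean_power(ph$scan, ph$masks$R, bands), "Nyquist")
  expect_error(voxelwise_mean_power(ph$scan, ph$masks$R, bands), "Nyquist")
})

test_that("coherent noiseless phantom: voxelwise equals ROI-mean power", {
  # the ROI is confined to one slice so that no slice-offset phase mixing
  # enters the ROI mean; with identical voxel series the two measures are
  # exactly the same quantity
  spec <- single_sine_phantom(0.3, "local_like", nx = 2, ny = 2,
                              n_volumes = 300)
  ph <- generate_phantom(spec)
  bands <- make_bands(1.0)
  m_sl <- array(FALSE, c(2, 2, 40)); m_sl[, , 12] <- TRUE
  roi_slice <- roi_mask(m_sl, "slice")
  vp <- voxelwise_mean_power(ph$scan, roi_slice, bands)
  rp <- roi_mean_power(ph$scan, roi_slice, bands)
  expect_equal(vp$power, rp$power, tolerance = 1e-8)

  # single-voxel ROI: voxelwise mean is that voxel's bandpower
  m1 <- array(FALSE, c(2, 2, 40)); m1[1, 1, 7] <- TRUE
  v1 <- voxelwise_mean_power(ph$scan, roi_mask(m1), bands)
  ps <- periodogram_psd(detrend_linear(ph$scan$data[1, 1, 7, ]),
                        1 / ph$scan$tr_s)
  expect_equal(v1$power[v1$band == "resp"],
               bandpower(ps, bands[[2]]), tolerance = 1e-12)
})

test_that("voxelwise power is blind to propagation; averaged power is not", {
  roi <- array(FALSE, c(2, 2, 40)); roi[, , 11:30] <- TRUE
  cmp <- list(R = list(mask = roi, amp = c(lfo = 0, resp = 1, cardiac = 0)))
  mk <- function(resp_speed) phantom_preset(
    "local_like", nx = 2, ny = 2, compartments = cmp, noise_sd = 0,
    source_voxel = c(1, 1, 11),
    speeds_m_s = c(lfo = Inf, resp = resp_speed, cardiac = Inf))
  coh <- generate_phantom(mk(Inf))
  prop <- generate_phantom(mk(0.05))
  bands <- make_bands(1.0)
  v_coh <- voxelwise_mean_power(coh$scan, coh$masks$R, bands)
  v_prop <- voxelwise_mean_power(prop$scan, prop$masks$R, bands)
  expect_equal(v_prop$power[2], v_coh$power[2], tolerance = 0.02)
  h_coh <- hypersampled_power(coh$scan, coh$masks$R, bands)
  h_prop <- hypersampled_power(prop$scan, prop$masks$R, bands)
  expect_lt(h_prop$power[2], 0.8 * h_coh$power[2])
})

test_that("regression summary matches the closed-form least squares", {
  expect_equal(compare_power_sets(1:10, 1:10)$slope, 1, tolerance = 1e-12)
  expect_equal(compare_power_sets(1:10, 1:10)$pearson_r, 1, tolerance = 1e-12)
  expect_equal(compare_power_sets(1:10, 2 * (1:10))$slope, 2,
               tolerance = 1e-12)
  # fixed 10-point table against an explicit normal-equations solve
  x <- c(0.11, 0.52, 0.93, 1.4, 2.2, 3.1, 4.05, 5.2, 6.1, 7.3)
  y <- c(0.3, 0.9, 1.7, 2.6, 4.1, 6.0, 7.7, 10.2, 11.9, 14.5)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- compare_power_sets(x, y)
  expect_equal(res$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$slope, beta[2], tolerance = 1e-10)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_direct, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_error(compare_power_sets(rep(1, 5), 1:5), "zero variance")
  expect_error(compare_power_sets(1:2, 1:2), "at least 3")
})

test_that("propagation sensitivity: respiration attenuates most", {
  roi <- array(FALSE, c(4, 4, 40)); roi[, , 11:30] <- TRUE
  cmp <- list(R = list(mask = roi, amp = c(lfo = 1, resp = 1, cardiac = 1)))
  spec <- phantom_preset("propagation_demo", nx = 4, ny = 4,
                         compartments = cmp, noise_sd = 0.2, seed = 2,
                         source_voxel = c(1, 1, 11),
                         freqs_hz = c(lfo = 0.05, resp = 0.3, cardiac = 1.07))
  r <- propagation_sensitivity(spec, "R")
  expect_lt(r$ratio[r$band == "resp"], 0.8)
  expect_gt(r$ratio[r$band == "lfo"], 0.95)
  expect_gt(r$ratio[r$band == "cardiac"], 0.95)

  # all speeds infinite: every ratio ~ 1
  spec_coh <- phantom_preset("local_like", nx = 4, ny = 4,
                             compartments = cmp, noise_sd = 0,
                             freqs_hz = c(lfo = 0.05, resp = 0.3,
                                          cardiac = 1.07),
                             speeds_m_s = c(lfo = Inf, resp = Inf,
                                            cardiac = Inf))
  rc <- propagation_sensitivity(spec_coh, "R")
  expect_true(all(abs(rc$ratio - 1) < 0.05))

  # near-point ROI (one voxel per timing group, 5 adjacent slices): too
  # little spatial extent for propagation to dephase anything. A literal
  # single voxel covers only one timing group and is rejected by the
  # coverage gate, so this is the smallest hypersample-able ROI.
  m1 <- array(FALSE, c(4, 4, 40)); m1[1, 1, 11:15] <- TRUE
  cmp1 <- list(R = list(mask = m1, amp = c(lfo = 1, resp = 1, cardiac = 1)))
  spec1 <- phantom_preset("propagation_demo", nx = 4, ny = 4,
                          compartments = cmp1, noise_sd = 0,
                          source_voxel = c(1, 1, 11),
                          freqs_hz = c(lfo = 0.05, resp = 0.3,
                                       cardiac = 1.07))
  r1 <- propagation_sensitivity(spec1, "R")
  expect_true(all(abs(r1$ratio - 1) < 0.05))
})

test_that("long-format bandpower export has the modelling-ready layout", {
  df <- data.frame(roi = rep(c("GM", "SSS"), each = 3),
                   band = rep(c("lfo", "resp", "cardiac"), 2),
                   power = c(2, 0.1, 0.2, 1, 0.9, 2.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- write_bandpower_table(df, f, participant = "p01", scan_id = 1,
                               age = 55, sex = "F")
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 6)
  expect_equal(back$log_power, log(df$power))
  expect_equal(unique(back$participant), "p01")
})
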