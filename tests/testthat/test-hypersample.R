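test_that("timing table reproduces the multiband arithmetic", {
  t72 <- build_timing_table(n_slices = 72, mb_factor = 8, tr_s = 0.8)
  expect_equal(t72$n_time, 9)
  expect_equal(t72$dt_s, 0.8 / 9)
  expect_equal(t72$fs_hyper_hz, 9 / 0.8)

  t40 <- build_timing_table(n_slices = 40, mb_factor = 8, tr_s = 0.366)
  expect_equal(t40$n_time, 5)
  expect_equal(t40$fs_hyper_hz / 2, 5 / (2 * 0.366))

  # mb = n_slices degenerates to one timing group (no hypersampling gain)
  t1 <- build_timing_table(n_slices = 8, mb_factor = 8, tr_s = 1)
  expect_equal(t1$n_time, 1)
  expect_error(build_timing_table(n_slices = 10, mb_factor = 4, tr_s = 1),
               "divisible")
})

test_that("timing groups merge offsets within tolerance and flag unequal sizes", {
  offs <- c(0, 0.0004, 0.25, 0.2501, 0.5, 0.75)   # 4 groups under 1 ms tol
  scan <- fmri_scan(array(0, c(1, 1, 6, 4)), 1, offs)
  expect_warning(tb <- build_timing_table(scan), "unequal")
  expect_equal(tb$n_time, 4)
})

test_that("detrend_linear matches the closed-form least-squares solution", {
  # exact line is annihilated
  t <- 1:50
  expect_equal(detrend_linear(2 + 3 * t), rep(0, 50), tolerance = 1e-12)
  # a sinusoid even about the series midpoint over whole periods is
  # orthogonal to both the constant and the (centred) linear term
  x <- cos(2 * pi * 5 * ((0:99) - 49.5) / 100)
  expect_equal(detrend_linear(x), x, tolerance = 1e-9)
  # sinusoid + ramp: compare against an explicit normal-equations solve
  set.seed(11)
  y <- sin(2 * pi * (1:40) / 7.3) + 0.2 * (1:40) + rnorm(40)
  X <- cbind(1, 1:40)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(detrend_linear(y), as.numeric(y - X %*% beta),
               tolerance = 1e-10)
  expect_error(detrend_linear(c(1, 2)), "at least 3")
})

test_that("slice_group_signals averages per timing group and detrends", {
  spec <- single_sine_phantom(1.0, "local_like", nx = 2, ny = 2,
                              n_volumes = 60, baseline_range = 0)
  ph <- generate_phantom(spec)
  tb <- build_timing_table(ph$scan)
  gs <- slice_group_signals(ph$scan, ph$masks$R, tb)
  # noiseless coherent phantom: each group series equals the generative
  # sinusoid sampled at k*TR + group offset, minus its least-squares line
  k <- 0:59
  for (g in 1:5) {
    expected <- detrend_linear(sin(2 * pi * 1.0 * (k * spec$tr_s +
                                                   gs$offsets_s[g])))
    expect_equal(gs$series[g, ], expected, tolerance = 1e-9)
  }
  expect_equal(gs$voxel_counts, rep(2 * 2 * 8, 5))
})

test_that("single-voxel ROI and constant shifts behave under grouping", {
  scan <- tiny_scan(nx = 2, ny = 2, nz = 4, nt = 30, tr_s = 0.5)
  set.seed(3)
  series <- rnorm(30)
  scan$data[1, 1, 2, ] <- series
  m <- array(FALSE, c(2, 2, 4)); m[1, 1, 2] <- TRUE
  tb <- build_timing_table(scan)
  gs <- slice_group_signals(scan, roi_mask(m), tb)
  g <- which(gs$voxel_counts > 0)
  expect_length(g, 1)
  expect_equal(gs$series[g, ], detrend_linear(series), tolerance = 1e-12)
  expect_true(all(is.na(gs$series[-g, ])))

  # adding a constant to a second voxel in the same group changes nothing
  scan$data[2, 1, 2, ] <- series + 7
  m2 <- m; m2[2, 1, 2] <- TRUE
  gs2 <- slice_group_signals(scan, roi_mask(m2), tb)
  expect_equal(gs2$series[g, ], detrend_linear(series), tolerance = 1e-10)
})

test_that("interleave places groups in slice-timing order on the fast axis", {
  spec <- single_sine_phantom(1.0, "local_like", nx = 2, ny = 2,
                              n_volumes = 40)
  ph <- generate_phantom(spec)
  tb <- build_timing_table(ph$scan)
  gs <- slice_group_signals(ph$scan, ph$masks$R, tb)
  hs <- interleave(gs, tb, "R")
  expect_length(hs$values, 40 * 5)
  for (k in c(1, 20, 40)) for (j in 1:5)
    expect_equal(hs$values[(k - 1) * 5 + j], gs$series[j, k])
  # reversing the stored group order while keeping offsets attached is
  # canonicalized away by the sort on offsets
  rev_gs <- list(series = gs$series[5:1, , drop = FALSE],
                 voxel_counts = gs$voxel_counts[5:1],
                 offsets_s = gs$offsets_s[5:1])
  ord <- order(rev_gs$offsets_s)
  rev_sorted <- list(series = rev_gs$series[ord, , drop = FALSE],
                     voxel_counts = rev_gs$voxel_counts[ord],
                     offsets_s = rev_gs$offsets_s[ord])
  expect_equal(interleave(rev_sorted, tb, "R")$values, hs$values)
})

test_that("n_time = 1 hypersampling is the detrended ROI mean", {
  scan <- tiny_scan(nx = 2, ny = 2, nz = 2, nt = 25, tr_s = 0.5,
                    offsets = c(0, 0))
  set.seed(8)
  scan$data <- array(rnorm(2 * 2 * 2 * 25), dim(scan$data))
  m <- roi_mask(array(TRUE, c(2, 2, 2)))
  hs <- hypersample_roi(scan, m)
  flat <- matrix(scan$data, nrow = 8, ncol = 25)
  expect_equal(hs$values, detrend_linear(colMeans(flat)), tolerance = 1e-12)
  expect_equal(hs$dt_s, 0.5)
})

test_that("coverage rule: spanning half or fewer timing groups is rejected", {
  offs <- derive_slice_offsets(18, 2, 0.8)        # n_time = 9
  scan <- fmri_scan(array(stats::rnorm(18 * 40), c(1, 1, 18, 40)), 0.8, offs)
  tb <- build_timing_table(scan)
  mk <- function(groups) {
    m <- array(FALSE, c(1, 1, 18))
    m[1, 1, which((tb$group_of_slice) %in% groups)[seq_along(groups)]] <- TRUE
    roi_mask(m)
  }
  expect_error(hypersample_roi(scan, mk(1:4), tb), "insufficient")
  hs <- hypersample_roi(scan, mk(1:5), tb, gap_policy = "interpolate")
  expect_equal(hs$coverage, 5)
  expect_true(any(!hs$valid))
  expect_false(anyNA(hs$values))
  expect_error(hypersample_roi(scan, mk(1:5), tb, gap_policy = "strict"),
               "gaps")
})

test_that("gap interpolation equals explicit linear interpolation", {
  offs <- derive_slice_offsets(6, 2, 0.6)         # n_time = 3
  scan <- fmri_scan(array(stats::rnorm(6 * 30), c(1, 1, 6, 30)), 0.6, offs)
  tb <- build_timing_table(scan)
  m <- array(FALSE, c(1, 1, 6))
  m[1, 1, which(tb$group_of_slice %in% c(1, 3))[1:2]] <- TRUE
  hs <- hypersample_roi(scan, roi_mask(m), tb)
  raw <- interleave(slice_group_signals(scan, roi_mask(m), tb), tb)
  ok <- which(!is.na(raw$values))
  ref <- stats::approx(ok, raw$values[ok], xout = seq_along(raw$values),
                       rule = 2)$y
  expect_equal(hs$values, ref)
})

test_that("hypersampling is linear and commutes with voxel-wise detrending", {
  offs <- derive_slice_offsets(8, 2, 0.5)
  mk <- function(seed) {
    set.seed(seed)
    fmri_scan(array(rnorm(2 * 2 * 8 * 24), c(2, 2, 8, 24)), 0.5, offs)
  }
  s1 <- mk(1); s2 <- mk(2)
  m <- roi_mask(array(TRUE, c(2, 2, 8)))
  tb <- build_timing_table(s1)
  comb <- s1; comb$data <- 2 * s1$data - 0.5 * s2$data
  h <- hypersample_roi(comb, m, tb)$values
  expect_equal(h, 2 * hypersample_roi(s1, m, tb)$values -
                  0.5 * hypersample_roi(s2, m, tb)$values,
               tolerance = 1e-10)

  # detrend-then-average equals average-then-detrend (both linear)
  vd <- s1
  flat <- matrix(vd$data, nrow = 2 * 2 * 8)
  for (v in seq_len(nrow(flat))) flat[v, ] <- detrend_linear(flat[v, ])
  vd$data <- array(flat, dim(vd$data))
  expect_equal(hypersample_roi(vd, m, tb)$values,
               hypersample_roi(s1, m, tb)$values, tolerance = 1e-10)
})

test_that("hypersampling un-aliases any coherent tone below the raised Nyquist", {
  # property over a frequency grid: hypersampled PSD peaks at the true
  # frequency even when it exceeds the per-volume Nyquist 1/(2 TR)
  for (f in c(0.7, 1.0, 1.3)) {
    spec <- single_sine_phantom(f, "hcp_like", nx = 2, ny = 2,
                                n_volumes = 200)
    ph <- generate_phantom(spec)
    hs <- hypersample_roi(ph$scan, ph$masks$R)
    ps <- periodogram_psd(hs$values, fs_hz = 1 / hs$dt_s)
    peak <- ps$freqs_hz[which.max(ps$psd)]
    expect_lt(abs(peak - f), 1.5 * ps$df_hz)
    expect_gt(f, 1 / (2 * ph$scan$tr_s))    # genuinely above original Nyquist
  }
})

test_that("incoherent voxel phases are suppressed by ROI averaging", {
  # each voxel gets an independent uniform phase: hypersampled in-band power
  # should shrink towards 1/V of the coherent case
  offs <- derive_slice_offsets(8, 2, 0.8)
  nt <- 120; f <- 1.0
  set.seed(42)
  suppressed <- coherent <- NULL
  for (mode in c("coherent", "incoherent")) {
    data <- array(0, c(4, 4, 8, nt))
    for (s in 1:8) for (i in 1:4) for (j in 1:4) {
      phi <- if (mode == "coherent") 0 else runif(1, 0, 2 * pi)
      tt <- (0:(nt - 1)) * 0.8 + offs[s]
      data[i, j, s, ] <- sin(2 * pi * f * tt + phi)
    }
    scan <- fmri_scan(data, 0.8, offs)
    hs <- hypersample_roi(scan, roi_mask(array(TRUE, c(4, 4, 8))))
    ps <- periodogram_psd(hs$values, 1 / hs$dt_s)
    pw <- bandpower(ps, list(lo_hz = f - 0.15, hi_hz = f + 0.15))
    if (mode == "coherent") coherent <- pw else suppressed <- pw
  }
  expect_lt(suppressed, coherent / 10)      # V = 16 voxels per slice group
})
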