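# Phase-contrast flow pipeline: ROI detection, de-aliasing, background
# correction, cycle segmentation, ensemble averaging and metrics.

test_that("ROI detection finds the cardiac-modulated disk", {
  ph <- snr_series(seed = 1)
  roi <- detect_roi(ph$series)
  expect_gte(dice_coef(roi$mask, ph$truth$roi), 0.8)
  expect_equal(roi$d_pc, 2 * sqrt(roi$area / pi))
  # all-static series: no cardiac power anywhere
  static <- velocity_series(array(3, c(8, 8, 60)), dt = 0.087,
                            pixel_spacing = c(2, 2), venc = 100)
  expect_error(detect_roi(static), "manual ROI")
  # override bypasses detection
  ov <- matrix(FALSE, 32, 32); ov[10:12, 10:12] <- TRUE
  expect_identical(detect_roi(ph$series, override = ov)$mask, ov)
})

test_that("temporal unwrapping inverts venc aliasing", {
  venc <- 100
  # the classic case: true 120 recorded as -80
  expect_equal(dealias(c(90, -80), venc), c(90, 120))
  # series within +/- venc unchanged (idempotence)
  v <- 80 * sin(seq(0, 20, by = 0.25))
  expect_identical(dealias(v, venc), v)
  # sinusoid peaking at 1.5 venc: wrap then unwrap is the identity
  tt <- seq(0, 5, by = 0.087)
  v2 <- 150 * sin(2 * pi * tt / 0.85)
  w <- venc - ((venc - v2) %% (2 * venc))
  expect_lt(max(abs(dealias(w, venc) - v2)), 1e-9)
  expect_error(dealias(v2), "venc")
})

test_that("background correction removes a constant offset exactly", {
  ph <- make_phantom_series(flow_spec(offset = 5))
  roi <- roi_mask(ph$truth$roi, c(2, 2))
  corrected <- background_correct(ph$series, roi)
  expect_equal(attr(corrected, "offset"), 5, tolerance = 1e-9)
  q <- compute_flow_curve(corrected, roi)
  expect_lt(max(abs(q$flow - ph$truth$q_true)), 1e-6)
  # zero offset: series unchanged
  ph0 <- make_phantom_series(flow_spec())
  c0 <- background_correct(ph0$series, roi)
  expect_lt(max(abs(c0$velocities - ph0$series$velocities)), 1e-9)
})

test_that("background offset estimate stays within 3 sd/sqrt(n) under noise", {
  for (seed in 1:25) {
    ph <- make_phantom_series(flow_spec(offset = 2, noise_sd = 1,
                                        seed = seed))
    roi <- roi_mask(ph$truth$roi, c(2, 2))
    corrected <- background_correct(ph$series, roi)
    n_stat <- attr(corrected, "n_stationary")
    err <- abs(attr(corrected, "offset") - 2)
    expect_lt(err, 3 * 1 / sqrt(n_stat * ph$series$n_frames))
  }
})

test_that("flow curve is the pixel-area-weighted velocity sum", {
  v <- array(0, c(4, 4, 3)); v[2, 2, ] <- 10
  ser <- velocity_series(v, dt = 0.1, pixel_spacing = c(2, 2), venc = 100)
  roi <- roi_mask(matrix(c(rep(FALSE, 5), TRUE, rep(FALSE, 10)), 4, 4),
                  c(2, 2))
  expect_equal(compute_flow_curve(ser, roi)$flow, rep(40, 3))
  # parabolic profile over a disk: Q = vmax * pi a^2 / 2
  n <- 200; h <- 0.05; a <- 3; vmax <- 12
  xs <- (0:(n - 1)) * h - (n - 1) * h / 2
  r2 <- outer(xs^2, xs^2, "+")
  prof <- ifelse(r2 <= a^2, vmax * (1 - r2 / a^2), 0)
  ser2 <- velocity_series(array(rep(prof, 2), c(n, n, 2)), dt = 0.1,
                          pixel_spacing = c(h, h), venc = 1000)
  q <- compute_flow_curve(ser2, roi_mask(r2 <= a^2, c(h, h)))$flow[1]
  expect_equal(q, vmax * pi * a^2 / 2, tolerance = 0.01)
  # linearity in the velocities
  ser3 <- ser; ser3$velocities <- 3 * ser$velocities
  expect_equal(compute_flow_curve(ser3, roi)$flow,
               3 * compute_flow_curve(ser, roi)$flow)
  # zero velocities
  expect_true(all(compute_flow_curve(
    velocity_series(array(0, c(4, 4, 3)), 0.1, c(2, 2), 100), roi)$flow == 0))
})

test_that("cycle segmentation cuts at the per-cycle flow minima", {
  tt <- (0:499) * 0.087
  cv <- flow_curve(tt, 100 * sin(2 * pi * tt / 0.85))
  cyc <- segment_cycles(cv)
  expect_length(cyc, floor(max(tt) / 0.85) - 1)
  periods <- vapply(cyc, function(x) x$t1 - x$t0, numeric(1))
  expect_true(all(abs(periods - 0.85) < 0.087))
  # constant curve: no minima
  expect_error(segment_cycles(flow_curve(tt, rep(1, 500)),
                              tc_estimate = 0.85), "constant|minima")
  # respiratory amplitude modulation does not disturb the periods
  q <- (1 + 0.1 * sin(2 * pi * tt / 4.1)) * 100 * sin(2 * pi * tt / 0.85)
  cyc2 <- segment_cycles(flow_curve(tt, q))
  periods2 <- vapply(cyc2, function(x) x$t1 - x$t0, numeric(1))
  expect_true(all(abs(periods2 - 0.85) < 0.087))
  # too-short curve
  expect_error(segment_cycles(flow_curve(tt[1:20], q[1:20]),
                              tc_estimate = 0.85), "three")
})

test_that("ensemble averaging and limits of agreement", {
  base <- 100 * sin(2 * pi * (0:31) / 32)
  # identical cycles: SD identically zero, LOA collapse onto the mean
  ens <- build_ensemble(matrix(rep(base, 5), 5, 32, byrow = TRUE))
  expect_true(all(ens$sd_curve == 0))
  expect_equal(ens$loa_upper, ens$mean_curve)
  # scaled cycles 0.9 / 1.0 / 1.1: pointwise SD = 0.1 |base|
  mat <- rbind(0.9 * base, base, 1.1 * base)
  ens2 <- build_ensemble(mat)
  expect_equal(ens2$sd_curve, 0.1 * abs(base), tolerance = 1e-12)
  expect_equal(ens2$loa_upper - ens2$mean_curve,
               ens2$mean_curve - ens2$loa_lower, tolerance = 1e-9)
  expect_error(build_ensemble(mat[1:2, ]), "three")
  # LOA ordering holds for arbitrary cycle collections
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rnorm(12 * 32), 12, 32)
    e <- build_ensemble(m)
    expect_true(all(e$loa_upper >= e$mean_curve))
    expect_true(all(e$mean_curve >= e$loa_lower))
  }
})

test_that("LOA cover 95% of Gaussian-perturbed cycles", {
  set.seed(101)
  base <- 100 * sin(2 * pi * (0:31) / 32)
  cyc <- t(vapply(1:200, function(i)
    base * (1 + 0.1 * rnorm(1)) + rnorm(32, sd = 5), numeric(32)))
  ens <- build_ensemble(cyc)
  inside <- cyc >= matrix(ens$loa_lower, 200, 32, byrow = TRUE) &
    cyc <= matrix(ens$loa_upper, 200, 32, byrow = TRUE)
  expect_lt(abs(mean(inside) - 0.95), 0.02)
})

test_that("flow metrics decompose cardiac and breathing components", {
  base <- 100 * sin(2 * pi * (0:31) / 32)
  ens <- build_ensemble(matrix(rep(base, 5), 5, 32, byrow = TRUE))
  ens$Tc <- 0.85
  fm <- flow_metrics(ens)
  expect_equal(fm$qc_plus, 100, tolerance = 1e-6)
  expect_equal(fm$qc_minus, 100, tolerance = 1e-6)
  expect_equal(fm$qb, 0)
  expect_equal(fm$sv, 100 * 0.85 / pi, tolerance = 0.01)  # 27.06 mm^3
  expect_equal(fm$q_net, 0, tolerance = 1e-9)
  # vertical offset moves Q-net, not the oscillation decomposition
  ens_off <- build_ensemble(matrix(rep(base + 10, 5), 5, 32, byrow = TRUE))
  ens_off$Tc <- 0.85
  fm_off <- flow_metrics(ens_off)
  expect_equal(fm_off$q_net, 10, tolerance = 1e-9)
  # SV and Q-net invariant to the phase origin
  rot <- c(9:32, 1:8)
  ens_rot <- build_ensemble(matrix(rep(base[rot], 5), 5, 32, byrow = TRUE))
  ens_rot$Tc <- 0.85
  fm_rot <- flow_metrics(ens_rot)
  expect_equal(fm_rot$sv, fm$sv, tolerance = 1e-6)
  expect_equal(fm_rot$q_net, fm$q_net, tolerance = 1e-6)
})

test_that("full pipeline recovers the generated flow decomposition", {
  ph <- snr_series(seed = 1)
  fr <- run_flow(ph$series, verbose = FALSE)
  tr <- ph$truth
  expect_lt(abs(fr$metrics$tc / tr$tc - 1), 0.02)
  expect_lt(abs(fr$metrics$qc / tr$qc - 1), 0.05)
  qb_true <- (tr$qb_plus + tr$qb_minus) / 2
  expect_lt(abs(fr$metrics$qb / qb_true - 1), 0.15)
})

test_that("net flow of the reconstructed cycle is near zero", {
  # noise-free series: only the partial-breathing-window residual remains
  ph <- make_phantom_series(flow_spec())
  fr <- run_flow(ph$series, roi = ph$truth$roi, verbose = FALSE)
  expect_lt(abs(fr$metrics$q_net), 2)
  # noisy series: the estimator mean over seeds stays within the bound
  qn <- vapply(1:10, function(s) {
    run_flow(snr_series(seed = s)$series, verbose = FALSE)$metrics$q_net
  }, numeric(1))
  expect_lt(abs(mean(qn)), 2)
})

test_that("systole/diastole split follows the arterial waveform", {
  tt <- (0:499) * 0.087
  aq <- flow_curve(tt, 100 * sin(2 * pi * tt / 0.85))
  art <- flow_curve(tt, 400 * abs(sin(pi * tt / 0.85)))
  cyc <- segment_cycles(aq)
  ens <- build_ensemble(cyc)
  ph <- cardiac_phase_split(art, ens, cyc)
  # rectified sinusoid: systole is (close to) the rising half
  expect_lt(abs(mean(ph$systole) - 0.5), 0.15)
  expect_true(all(xor(ph$systole, ph$diastole)))
  # displaced volumes partition the net cycle volume
  fm <- flow_metrics(ens)
  expect_equal(ph$vol_systole + ph$vol_diastole, fm$q_net * ens$Tc,
               tolerance = 1e-6)
  # a flat arterial curve carries no phase information
  flat <- flow_curve(tt, rep(5, 500))
  expect_error(cardiac_phase_split(flat, ens, cyc), "pulsation")
  # zero aqueduct flow: both phase volumes vanish
  ens0 <- ens; ens0$mean_curve <- rep(0, 32)
  ph0 <- cardiac_phase_split(art, ens0, cyc)
  expect_equal(ph0$vol_systole, 0)
  expect_equal(ph0$vol_diastole, 0)
})

test_that("respiratory period is recovered from the continuous curve", {
  ph <- make_phantom_series(flow_spec())
  fr <- run_flow(ph$series, roi = ph$truth$roi, verbose = FALSE)
  expect_lt(abs(fr$metrics$tb / ph$truth$tb - 1), 0.15)
})
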