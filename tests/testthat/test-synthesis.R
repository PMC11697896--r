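# Phantom generators and their ground-truth records.

test_that("phantom volume renders the silhouette with partial volume", {
  spec <- geometry_spec(radius_uniform(2), length = 15, curvature = 0)
  ph <- make_phantom_volume(spec)
  vol <- ph$volume
  expect_equal(dim(vol$data)[3], 3L)
  central <- vol$data[, , 2]
  # lumen pixel count ~ silhouette area / pixel area (flat-capped tube)
  n_lumen <- sum(central >= 55)
  expect_lt(abs(n_lumen / (2 * 15 / 0.36) - 1), 0.03)
  # noise-free histogram: background and lumen plateaus plus ramp tail
  expect_gt(mean(central %in% c(10, 100)), 0.6)
  expect_equal(range(central), c(10, 100))
  # MIP keeps the central slice: neighbours are dimmer everywhere
  expect_true(all(vol$data[, , 1] <= central + 1e-12))
})

test_that("phantom volume generation is deterministic given the seed", {
  spec <- geometry_spec(noise_sd = 3, seed = 7L)
  a <- make_phantom_volume(spec)
  b <- make_phantom_volume(spec)
  expect_identical(a$volume$data, b$volume$data)
  c <- make_phantom_volume(geometry_spec(noise_sd = 3, seed = 8L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("under-resolved lumen triggers a warning", {
  expect_warning(make_phantom_volume(geometry_spec(radius_uniform(1))),
                 "under-resolved")
})

test_that("analytic resistance oracle: closed forms and scaling", {
  expect_equal(round(analytic_resistance(
    geometry_spec(radius_uniform(2), length = 15)), 2), 27.12)
  r1 <- analytic_resistance(geometry_spec(radius_uniform(2), length = 16))
  r2 <- analytic_resistance(geometry_spec(radius_uniform(4), length = 16))
  expect_equal(r1 / r2, 16, tolerance = 1e-9)
  # stenosis depth -> 0 approaches the uniform tube value
  r_sten <- analytic_resistance(
    geometry_spec(radius_stenosis(d0 = 2, depth = 1e-6), length = 16))
  r_unif <- analytic_resistance(
    geometry_spec(radius_uniform(2), length = 16))
  expect_equal(r_sten, r_unif, tolerance = 1e-5)
})

test_that("phantom landmarks cross the lumen at the narrowest point", {
  ph <- make_phantom_volume(geometry_spec(radius_stenosis(), length = 16))
  lm <- phantom_landmarks(ph$truth)
  mid <- colMeans(lm$threshold_line)
  k <- which.min(ph$truth$radius)
  expect_lt(sqrt(sum((mid - ph$truth$axis[k, ])^2)), 0.2)
  expect_equal(lm$start_point, ph$truth$start_point)
})

test_that("velocity phantom conserves the true flow exactly before noise", {
  ph <- make_phantom_series(flow_spec())
  q <- compute_flow_curve(ph$series, roi_mask(ph$truth$roi, c(2, 2)))
  expect_equal(q$flow, ph$truth$q_true, tolerance = 1e-9)
})

test_that("a uniform velocity offset shifts the flow by area x pixels", {
  ph0 <- make_phantom_series(flow_spec())
  ph5 <- make_phantom_series(flow_spec(offset = 5))
  roi <- roi_mask(ph0$truth$roi, c(2, 2))
  k <- sum(ph0$truth$roi)
  q0 <- compute_flow_curve(ph0$series, roi)$flow
  q5 <- compute_flow_curve(ph5$series, roi)$flow
  expect_equal(q5 - q0, rep(5 * 4 * k, length(q0)), tolerance = 1e-9)
})

test_that("supra-venc velocities wrap into (-venc, venc]", {
  art <- list(list(center = c(10, 10), radius = 3, peak = 150))
  ph <- make_phantom_series(flow_spec(arteries = art, venc = 100))
  v <- ph$series$velocities
  expect_true(all(v > -100 & v <= 100))
  # the arterial centre truly aliased: stored values fold negative, and
  # temporal unwrapping recovers the supra-venc peak
  xs <- (0:31) * 2
  disk <- outer((xs - 10)^2, (xs - 10)^2, "+") <= 9
  art_v <- apply(v, 3, function(fr) fr[disk][1])
  expect_lt(min(art_v), -40)
  unwrapped <- dealias(art_v, 100)
  expect_gt(max(unwrapped), 130)
  expect_lte(max(unwrapped), 150 + 1e-9)
})

test_that("velocity phantom is deterministic given the seed", {
  a <- make_phantom_series(flow_spec(noise_sd = 2, seed = 3L))
  b <- make_phantom_series(flow_spec(noise_sd = 2, seed = 3L))
  expect_identical(a$series$velocities, b$series$velocities)
})

test_that("ground-truth record carries the decomposition the paper defines", {
  sp <- flow_spec()
  ph <- make_phantom_series(sp)
  tr <- ph$truth
  expect_equal(tr$qc_plus, sp$qc_plus, tolerance = 1e-6)
  expect_gt(tr$qc_minus, tr$qc_plus)   # biphasic trough deeper than peak
  # LOA-based breathing peaks: 1.96 * (m Qpeak + b) / sqrt(2)
  expect_equal(tr$qb_plus,
               1.96 * (sp$mod_scale * tr$qc_plus + sp$mod_shift) / sqrt(2),
               tolerance = 1e-9)
  expect_gt(tr$sv, 0)
  expect_equal(tr$q_net, 0)
})
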