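# Morphological pipeline: projection, binarization, centerline, elements,
# resistance profile, endpoint trimming.

test_that("maximum-intensity projection has max semantics", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 1; arr[, , 2] <- 1   # identical slices
  vol <- morph_volume(arr, c(0.6, 0.6, 1.2))
  expect_equal(mip_project(vol, c(1, 2))$data, arr[, , 1])
  # disjoint bright halves -> union
  arr2 <- array(0, c(4, 4, 2))
  arr2[1:2, , 1] <- 9; arr2[3:4, , 2] <- 9
  vol2 <- morph_volume(arr2, c(1, 1, 1))
  expect_true(all(mip_project(vol2, c(1, 2))$data == 9))
  expect_error(mip_project(vol, c(1, 5)), "out of range")
  expect_error(mip_project(vol, 1), "2 or 3")
})

test_that("bilinear resampling reproduces constants and linear ramps", {
  const <- projection_image(matrix(7, 5, 5), c(0.6, 0.6))
  expect_true(all(abs(resample_image(const)$data - 7) < 1e-12))
  xs <- (0:9) * 0.6; ys <- (0:7) * 0.6
  ramp <- projection_image(outer(xs, ys, function(x, y) 3 * x - 2 * y + 1),
                           c(0.6, 0.6))
  fine <- resample_image(ramp, 0.03)
  xf <- (0:(nrow(fine$data) - 1)) * 0.03
  yf <- (0:(ncol(fine$data) - 1)) * 0.03
  expect_lt(max(abs(fine$data - outer(xf, yf, function(x, y)
    3 * x - 2 * y + 1))), 1e-9)
  # 0.6 -> 0.03 gives a 20x denser grid over the same extent
  expect_equal(nrow(fine$data), (10 - 1) * 20 + 1)
  expect_warning(resample_image(ramp, 0.005), "exceeds 100")
  expect_error(resample_image(ramp, 0.7), "exceed")
})

test_that("gradient threshold finds the lumen edge transition", {
  # ideal step edge 10 -> 100: binarization boundary lands at the step
  step_img <- projection_image(
    cbind(matrix(10, 20, 10), matrix(100, 20, 10)), c(0.03, 0.03))
  line <- rbind(c(0.3, 0.03), c(0.3, 0.57))
  thr <- gradient_threshold(step_img, line)
  bin <- binarize(step_img, thr)
  expect_equal(unname(bin$data[1, ]), c(rep(0, 10), rep(1, 10)))
  # global monotone ramp: falls back to the first maximal-gradient sample
  ramp_img <- projection_image(
    matrix(rep(seq(0, 100, length.out = 30), each = 10), 10, 30,
           byrow = FALSE), c(0.03, 0.03))
  thr2 <- gradient_threshold(ramp_img, rbind(c(0.15, 0), c(0.15, 29 * 0.03)))
  expect_lt(thr2, 20)  # tie broken at the first interior sample
  # flat profile has no edge
  flat <- projection_image(matrix(5, 10, 10), c(0.03, 0.03))
  expect_error(gradient_threshold(flat, rbind(c(0, 0.15), c(0.27, 0.15))),
               "no edge")
})

test_that("gradient threshold returns the half-height on phantom edges", {
  mb <- morpho_binary("uniform")
  expect_lt(abs(mb$threshold - 55), 1)
})

test_that("binarization applies threshold and exclusion mask", {
  img <- projection_image(matrix(runif(100, 1, 9), 10, 10), c(1, 1))
  expect_true(all(binarize(img, min(img$data))$data == 1))
  expect_error(binarize(img, min(img$data),
                        mask = matrix(TRUE, 10, 10)), "empty lumen")
  expect_error(binarize(img, 99), "intensity range")
  # bright distractor blob removed by a polygon mask
  img2 <- matrix(10, 40, 40)
  img2[5:15, 5:15] <- 100    # tube stand-in
  img2[25:35, 25:35] <- 100  # distractor
  pi2 <- projection_image(img2, c(1, 1))
  poly <- rbind(c(22, 22), c(38, 22), c(38, 38), c(22, 38))
  bin <- binarize(pi2, 55, mask = poly)
  expect_equal(sum(bin$data), 11 * 11)
  expect_true(all(which(bin$data == 1, arr.ind = TRUE) <= 16))
})

test_that("centerline follows the axis of straight and curved tubes", {
  mb <- morpho_binary("straight")
  y0 <- mb$phantom$truth$axis[1, 2]
  expect_lt(max(abs(mb$path$y - y0)), 0.03)   # within one working pixel
  mbc <- morpho_binary("cshape")
  tr <- mbc$phantom$truth
  s_f <- seq(0, tr$length, by = 0.005)
  axf <- aqueduct:::phantom_axis(s_f, tr$spec$curvature)$xy
  axf <- sweep(axf, 2, tr$axis[1, ] - axf[1, ], "+")
  dev <- vapply(seq_len(nrow(mbc$path)), function(i)
    min(sqrt((axf[, 1] - mbc$path$x[i])^2 +
               (axf[, 2] - mbc$path$y[i])^2)), numeric(1))
  expect_lt(mean(dev), 0.015)                 # < 0.5 working pixels
  expect_true(all(diff(mbc$path$s) > 0))
  expect_error(extract_centerline(mbc$bin, tr$start_point,
                                  tr$start_point), "distinct")
})

test_that("disconnected lumen components are rejected or discarded", {
  bin <- matrix(0, 60, 20)
  bin[5:25, 8:12] <- 1
  bin[35:55, 8:12] <- 1   # second component, not connected
  img <- projection_image(bin, c(0.03, 0.03))
  expect_error(extract_centerline(img, c(10, 10) * 0.03, c(45, 10) * 0.03),
               "not connected")
})

test_that("element diameters recover the generating radius profile", {
  mb <- morpho_binary("straight")
  el <- build_elements(mb$bin, mb$path, 50)
  expect_true(all(abs(el$diameter - 2) < 2 * 0.03))
  # equal-arc-length partition
  el2 <- build_elements(mb$bin, mb$path, 2)
  expect_equal(el2$length[1], el2$length[2])
  expect_equal(sum(el2$length), max(mb$path$s), tolerance = 1e-6)
  # tapering phantom: measured profile decreases monotonically (small
  # tolerance for chord-phase noise)
  spec <- geometry_spec(radius_taper(2.5, 1.0), length = 16)
  ph <- suppressWarnings(make_phantom_volume(spec))
  lm <- phantom_landmarks(ph$truth, line_at = 4)
  fine <- resample_image(mip_project(ph$volume, 1:3))
  bin <- binarize(fine, gradient_threshold(fine, lm$threshold_line))
  path <- extract_centerline(bin, lm$start_point, lm$end_point)
  elt <- build_elements(bin, path, 40)
  expect_true(all(diff(elt$diameter) < 0.08))  # chord-phase noise bound
  expect_lt(cor(elt$s_mid, elt$diameter, method = "spearman"), -0.95)
  expect_lt(elt$diameter[40], elt$diameter[1] - 0.7)
})

test_that("resistance profile accumulates element resistances", {
  el <- data.frame(length = rep(15 / 100, 100), diameter = rep(2, 100))
  pr <- resistance_profile(el)
  expect_equal(round(pr$total_r, 2), 27.12)
  expect_equal(pr$cumulative_r, cumsum(pr$elements$r))
  one <- resistance_profile(data.frame(length = 1, diameter = 1))
  expect_equal(one$cumulative_r, one$total_r)
  # midpoint discretization converges to the quadrature oracle
  spec <- geometry_spec(radius_stenosis(), length = 16)
  oracle <- analytic_resistance(spec)
  errs <- vapply(c(25, 50, 100, 200), function(n) {
    smid <- (seq_len(n) - 0.5) * spec$length / n
    eln <- data.frame(length = rep(spec$length / n, n),
                      diameter = 2 * spec$rfun(smid))
    abs(resistance_profile(eln)$total_r / oracle - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("95% endpoint trimming follows the cumulative resistance", {
  # uniform elements: endpoint at element 95, R = 0.95 x total
  el <- data.frame(length = rep(0.16, 100), diameter = rep(2, 100))
  pr <- resistance_profile(el)
  path <- structure(data.frame(x = seq(0, 16, by = 0.03), y = 0,
                               s = seq(0, 16, by = 0.03)),
                    class = c("centerline_path", "data.frame"))
  model <- trim_endpoint_95(pr, path)
  expect_equal(model$endpoint_index_95, 95L)
  expect_equal(model$R, 0.95 * pr$total_r, tolerance = 1e-12)
  expect_equal(model$L, 0.95 * 16, tolerance = 1e-9)
  # all resistance concentrated in the first element
  el2 <- data.frame(length = rep(0.16, 10),
                    diameter = c(0.3, rep(3, 9)))
  model2 <- trim_endpoint_95(resistance_profile(el2), path)
  expect_equal(model2$endpoint_index_95, 1L)
  # distal flare: trimmed length well short of the defined length, R in
  # the prefix-sum bracket
  fl <- morpho_run("flare")
  m <- fl$model
  expect_lt(m$L, m$L_defined)
  total <- m$profile$total_r
  rmax <- max(m$profile$elements$r)
  expect_gte(m$R, 0.95 * total - 1e-9)
  expect_lte(m$R, 0.95 * total + rmax + 1e-9)
  expect_lte(m$D_min, m$D_mean)
  expect_gte(m$tortuosity, 1)
})

test_that("summary morphometrics fill the dimensionless numbers", {
  el <- data.frame(length = rep(0.16, 100), diameter = rep(1.9, 100))
  pr <- resistance_profile(el)
  path <- structure(data.frame(x = seq(0, 16, by = 0.03), y = 0,
                               s = seq(0, 16, by = 0.03)),
                    class = c("centerline_path", "data.frame"))
  model <- summarize_morphology(trim_endpoint_95(pr, path), 0.85, 177)
  expect_equal(round(model$womersley_mean, 1), 3.1)
  expect_equal(model$reynolds_max, reynolds_number(177, 1.9))
  m0 <- summarize_morphology(trim_endpoint_95(pr, path), 0.85, 0)
  expect_equal(m0$reynolds_max, 0)
  # Reynolds-max is attained at the minimum diameter
  el2 <- data.frame(length = rep(0.16, 100),
                    diameter = seq(2.4, 1.2, length.out = 100))
  m2 <- summarize_morphology(trim_endpoint_95(resistance_profile(el2), path),
                             0.85, 177)
  kept <- m2$profile$elements[seq_len(m2$endpoint_index_95), ]
  expect_equal(m2$reynolds_max, reynolds_number(177, min(kept$diameter)))
})

test_that("splitting an element leaves the total resistance unchanged", {
  el <- data.frame(length = c(2, 3, 5), diameter = c(2, 1.7, 2.2))
  total <- resistance_profile(el)$total_r
  el_split <- data.frame(length = c(2, 1.5, 1.5, 5),
                         diameter = c(2, 1.7, 1.7, 2.2))
  expect_equal(resistance_profile(el_split)$total_r, total,
               tolerance = 1e-12)
})
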