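# Shared fixtures: phantoms are generated in code and cached for the test
# session so expensive pipelines run once.

.aq_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .aq_cache))
    assign(key, force(expr), envir = .aq_cache)
  get(key, envir = .aq_cache)
}

morpho_spec <- function(name) {
  switch(name,
         uniform = geometry_spec(radius_uniform(2), length = 16),
         taper = geometry_spec(radius_taper(), length = 16),
         stenosis = geometry_spec(radius_stenosis(), length = 16),
         straight = geometry_spec(radius_uniform(2), length = 16,
                                  curvature = 0),
         cshape = geometry_spec(radius_uniform(2), length = 16,
                                curvature = 0.12),
         flare = geometry_spec(radius_flare(), length = 16),
         stop("unknown phantom: ", name))
}

# Full morphology pipeline on a named phantom, cached.
morpho_run <- function(name) {
  cached(paste0("morpho_", name), {
    spec <- morpho_spec(name)
    ph <- suppressWarnings(make_phantom_volume(spec))
    lm <- phantom_landmarks(ph$truth)
    model <- run_morpho(ph$volume, lm, slice_indices = c(1, 2, 3),
                        verbose = FALSE)
    list(spec = spec, phantom = ph, landmarks = lm, model = model)
  })
}

# Binarized projection + centerline for a named phantom, cached.
morpho_binary <- function(name) {
  cached(paste0("binary_", name), {
    spec <- morpho_spec(name)
    ph <- suppressWarnings(make_phantom_volume(spec))
    lm <- phantom_landmarks(ph$truth)
    fine <- resample_image(mip_project(ph$volume, 1:3))
    thr <- gradient_threshold(fine, lm$threshold_line)
    bin <- binarize(fine, thr)
    path <- extract_centerline(bin, lm$start_point, lm$end_point)
    list(spec = spec, phantom = ph, landmarks = lm, fine = fine,
         threshold = thr, bin = bin, path = path)
  })
}

# Velocity-series phantom at flow-curve SNR 10 (noise_sd derived from the
# peak cardiac flow, the pixel area and the ROI pixel count).
snr_series <- function(seed, snr = 10, offset = 2) {
  geom <- roi_geometry()
  n_roi <- cached("n_roi_default", {
    sum(make_phantom_series(flow_spec(), geom)$truth$roi)
  })
  sp0 <- flow_spec()
  noise_sd <- sp0$qc_plus / (snr * prod(geom$pixel_spacing) * sqrt(n_roi))
  make_phantom_series(flow_spec(noise_sd = noise_sd, offset = offset,
                                seed = seed), geom)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
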