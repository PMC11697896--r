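#' Radius profiles for synthetic aqueduct phantoms
#'
#' Parametric families of lumen radius as a function of arc position. Each
#' constructor returns an object that [geometry_spec()] resolves against the
#' phantom length into a function `r(s)` (mm).
#'
#' @param diameter,d_start,d_end,d0 Lumen diameters, mm.
#' @param depth Diameter reduction at the stenosis centre, mm.
#' @param width Gaussian width (SD) of the stenosis, mm.
#' @param center Stenosis centre as arc position, mm; `NULL` = mid-length.
#' @param flare_start Fraction of the length at which the distal flare
#'   begins.
#' @return An object of class `radius_profile`.
#' @name radius_profiles
NULL

#' @rdname radius_profiles
#' @export
radius_uniform <- function(diameter = 2) {
  stopifnot(diameter > 0)
  structure(list(kind = "uniform",
                 make = function(length) function(s) rep(diameter / 2,
                                                        length(s))),
            class = "radius_profile")
}

#' @rdname radius_profiles
#' @export
radius_taper <- function(d_start = 2.5, d_end = 1.5) {
  stopifnot(d_start > 0, d_end > 0)
  structure(list(kind = "taper",
                 make = function(length) function(s)
                   (d_start + (d_end - d_start) * s / length) / 2),
            class = "radius_profile")
}

#' @rdname radius_profiles
#' @export
radius_stenosis <- function(d0 = 2.2, depth = 0.5, width = 2,
                            center = NULL) {
  stopifnot(d0 > 0, depth >= 0, depth < d0, width > 0)
  structure(list(kind = "stenosis",
                 make = function(length) {
                   ctr <- if (is.null(center)) length / 2 else center
                   function(s)
                     (d0 - depth * exp(-((s - ctr) / width)^2)) / 2
                 }),
            class = "radius_profile")
}

#' @rdname radius_profiles
#' @export
radius_flare <- function(d0 = 1.8, d_end = 3.4, flare_start = 0.75) {
  stopifnot(d0 > 0, d_end > 0, flare_start > 0, flare_start < 1)
  structure(list(kind = "flare",
                 make = function(length) {
                   s0 <- flare_start * length
                   function(s) {
                     u <- pmax(s - s0, 0) / (length - s0)
                     (d0 + (d_end - d0) * u^2) / 2
                   }
                 }),
            class = "radius_profile")
}

#' Specification of a synthetic aqueduct phantom volume
#'
#' Describes a planar curved tube of known radius profile, rendered into a
#' morphological volume with in-plane partial volume (supersampled coverage
#' fractions) and optional Rician intensity noise. The tube axis lies in the
#' plane of the central slice; neighbouring slices receive a dimmed copy so
#' that maximum-intensity projection across 2-3 slices reconstructs the
#' silhouette. Defaults reproduce a typical healthy-adult aqueduct: length
#' 16 mm, diameter about 2 mm, path-to-chord ratio about 1.05, acquisition
#' voxels 0.6 x 0.6 x 1.2 mm.
#'
#' @param profile A [radius_profiles] object.
#' @param length Tube length along the axis, mm.
#' @param curvature Axis curvature, 1/mm; 0 gives a straight tube.
#' @param spacing Voxel size triple, mm.
#' @param lumen,background Rendered intensities of lumen and background.
#' @param noise_sd Rician noise SD in intensity units (0 = noise-free).
#' @param supersample Rendering subdivisions per in-plane voxel.
#' @param margin Background margin around the tube silhouette, mm.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(profile = radius_uniform(2), length = 16,
                          curvature = 0.069, spacing = c(0.6, 0.6, 1.2),
                          lumen = 100, background = 10, noise_sd = 0,
                          supersample = 20, margin = 2.5, seed = 1L) {
  stopifnot(inherits(profile, "radius_profile"), length > 0,
            curvature >= 0, all(spacing > 0), lumen > background,
            noise_sd >= 0, supersample >= 2, margin > 0)
  rfun <- profile$make(length)
  s_chk <- seq(0, length, length.out = 1001L)
  if (any(rfun(s_chk) <= 0))
    stop("radius profile must be positive everywhere")
  structure(list(profile = profile, rfun = rfun, length = length,
                 curvature = curvature, spacing = as.numeric(spacing),
                 lumen = lumen, background = background, noise_sd = noise_sd,
                 supersample = as.integer(supersample), margin = margin,
                 seed = as.integer(seed)),
            class = "geometry_spec")
}

# Planar axis of the phantom: starts at the origin heading along +x, bends
# with constant curvature. Returns positions and unit tangents at arc
# positions s.
phantom_axis <- function(s, curvature) {
  if (curvature == 0) {
    list(xy = cbind(s, rep(0, length(s))),
         tangent = cbind(rep(1, length(s)), rep(0, length(s))))
  } else {
    a <- curvature * s
    list(xy = cbind(sin(a) / curvature, (1 - cos(a)) / curvature),
         tangent = cbind(cos(a), sin(a)))
  }
}

#' Render a synthetic phantom volume
#'
#' Renders the tube described by a [geometry_spec()] into a 3-slice
#' [morph_volume()]. Voxel intensities on the central slice are
#' `background + (lumen - background) * coverage`, where coverage is the
#' in-plane area fraction of the voxel inside the tube silhouette, computed
#' on a supersampled subgrid. Neighbouring slices carry the same silhouette
#' at 45% coverage so that the central slice dominates a maximum-intensity
#' projection. Optional Rician noise is added with the stored seed.
#'
#' @param spec A [geometry_spec()].
#' @return A list with components `volume` (a [morph_volume()]) and `truth`
#'   (axis polyline, radius profile, landmark coordinates, narrowest point,
#'   all in the volume's mm coordinate frame).
#' @export
make_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  sx <- spec$spacing[1]; sy <- spec$spacing[2]
  if (min(spec$rfun(seq(0, spec$length, length.out = 501L))) * 2 <
      2 * sx)
    warning("minimum phantom diameter is below two in-plane voxels; ",
            "the lumen is under-resolved")

  ds <- 0.05
  s_ax <- seq(0, spec$length, by = ds)
  if (s_ax[length(s_ax)] < spec$length) s_ax <- c(s_ax, spec$length)
  ax <- phantom_axis(s_ax, spec$curvature)
  r_ax <- spec$rfun(s_ax)
  pad <- spec$margin + max(r_ax)
  shift <- c(pad - min(ax$xy[, 1]), pad - min(ax$xy[, 2]))
  axis_mm <- sweep(ax$xy, 2, shift, "+")

  nx <- ceiling((max(axis_mm[, 1]) + pad) / sx) + 1L
  ny <- ceiling((max(axis_mm[, 2]) + pad) / sy) + 1L
  ss <- spec$supersample
  step_x <- sx / ss; step_y <- sy / ss
  # subgrid cell centres tiling the pixel footprints
  xs <- -sx / 2 + step_x / 2 + (0:(nx * ss - 1L)) * step_x
  ys <- -sy / 2 + step_y / 2 + (0:(ny * ss - 1L)) * step_y

  inside <- matrix(FALSE, length(xs), length(ys))
  for (k in seq_along(s_ax)) {
    r <- r_ax[k]
    ix <- which(abs(xs - axis_mm[k, 1]) <= r)
    iy <- which(abs(ys - axis_mm[k, 2]) <= r)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((xs[ix] - axis_mm[k, 1])^2, (ys[iy] - axis_mm[k, 2])^2, "+")
    inside[ix, iy] <- inside[ix, iy] | (d2 <= r * r)
  }
  cov4 <- array(inside + 0, c(ss, nx, ss, ny))
  coverage <- apply(cov4, c(2L, 4L), mean)

  base <- spec$background + (spec$lumen - spec$background) * coverage
  dim_side <- spec$background +
    (spec$lumen - spec$background) * 0.45 * coverage
  vol <- array(spec$background, c(nx, ny, 3L))
  vol[, , 1L] <- dim_side
  vol[, , 2L] <- base
  vol[, , 3L] <- dim_side
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    n1 <- array(stats::rnorm(length(vol), sd = spec$noise_sd), dim(vol))
    n2 <- array(stats::rnorm(length(vol), sd = spec$noise_sd), dim(vol))
    vol <- sqrt((vol + n1)^2 + n2^2)
  }

  truth <- list(axis = axis_mm, s = s_ax, radius = r_ax, rfun = spec$rfun,
                length = spec$length,
                start_point = axis_mm[1, ],
                end_point = axis_mm[nrow(axis_mm), ],
                narrowest_s = s_ax[which.min(r_ax)],
                slice_indices = c(1L, 2L, 3L), center_slice = 2L,
                spec = spec)
  list(volume = morph_volume(vol, spec$spacing), truth = truth)
}

#' Landmarks derived from a phantom's ground truth
#'
#' Builds the manual inputs an operator would supply: a line crossing the
#' lumen perpendicular to the axis (at the narrowest point by default) and
#' the axis endpoints as start/end points.
#'
#' @param truth The `truth` component returned by [make_phantom_volume()].
#' @param line_at Arc position (mm) at which to draw the threshold line;
#'   default is the narrowest point.
#' @param line_margin Extra line length beyond the lumen edge on each side,
#'   mm.
#' @return An [aq_landmarks()] object (coordinates in mm).
#' @export
phantom_landmarks <- function(truth, line_at = NULL, line_margin = 1.2) {
  s0 <- if (is.null(line_at)) truth$narrowest_s else line_at
  # keep the profile line on the tube body, away from the end caps
  s0 <- min(max(s0, 1.5), truth$length - 1.5)
  k <- which.min(abs(truth$s - s0))
  ax <- phantom_axis(truth$s, truth$spec$curvature)
  nvec <- c(-ax$tangent[k, 2], ax$tangent[k, 1])
  p <- truth$axis[k, ]
  half <- truth$radius[k] + line_margin
  aq_landmarks(threshold_line = rbind(p + half * nvec, p - half * nvec),
               start_point = truth$start_point,
               end_point = truth$end_point)
}

#' Analytic hydraulic resistance of a phantom radius profile
#'
#' Fine-quadrature (trapezoidal) integral of 128µ / (π·D(s)⁴) along the
#' tube; the independent oracle for the morphology pipeline.
#'
#' @param spec A [geometry_spec()], or a phantom `truth` record.
#' @param const A [fluid_constants()] object.
#' @param n Number of quadrature points (>= 1e5 by default).
#' @param s_max Integrate over arc positions `[0, s_max]`; default the full
#'   length.
#' @return Resistance in mPa·s/mm³.
#' @examples
#' analytic_resistance(geometry_spec(radius_uniform(2), length = 15))  # 27.12
#' @export
analytic_resistance <- function(spec, const = fluid_constants(), n = 1e5,
                                s_max = NULL) {
  const <- as_fluid_constants(const)
  if (!is.null(spec$rfun) && !inherits(spec, "geometry_spec")) {
    rfun <- spec$rfun; len <- spec$length
  } else {
    stopifnot(inherits(spec, "geometry_spec"))
    rfun <- spec$rfun; len <- spec$length
  }
  if (is.null(s_max)) s_max <- len
  s <- seq(0, s_max, length.out = max(2L, as.integer(n)))
  integrand <- 128 * const$mu / (pi * (2 * rfun(s))^4)
  h <- s[2] - s[1]
  h * (sum(integrand) - (integrand[1] + integrand[length(integrand)]) / 2)
}

#' Specification of a synthetic phase-contrast velocity series
#'
#' Describes the flow model laid onto the synthetic series: a periodic
#' cardiac waveform whose amplitude is scaled and whose baseline is shifted
#' by a slower respiratory sinusoid, a static-tissue velocity offset,
#' optional aliased arterial disks, and Gaussian velocity noise. Defaults
#' follow typical healthy-adult values (cardiac period 0.85 s, breathing
#' period 4.1 s, peak cardiac-driven flow about 170-190 mm³/s, breath-driven
#' peaks about 70% of cardiac) and the acquisition parameters of real-time
#' phase contrast (87 ms per frame, venc 100 mm/s, 300 frames).
#'
#' @param tc,tb Cardiac and breathing periods, s (`tc < tb`).
#' @param qc_plus Peak cardiac-driven flow toward the 3rd ventricle, mm³/s.
#' @param waveform `"biphasic"` (fast systolic peak, slower return) or
#'   `"sine"`.
#' @param mod_scale Respiratory amplitude-modulation depth (dimensionless).
#' @param mod_shift Respiratory baseline-shift amplitude, mm³/s.
#' @param offset Static-tissue velocity offset applied to every pixel, mm/s.
#' @param noise_sd Gaussian velocity noise SD, mm/s.
#' @param n_frames,dt Number of frames and frame interval, s.
#' @param venc Velocity-encoding limit, mm/s; stored velocities wrap into
#'   `(-venc, venc]`.
#' @param arteries Optional list of disks, each
#'   `list(center = c(x, y) mm, radius = mm, peak = mm/s)`, rendered as
#'   pulsatile supra-venc velocities that alias.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(tc = 0.85, tb = 4.1, qc_plus = 170,
                      waveform = c("biphasic", "sine"),
                      mod_scale = 0.45, mod_shift = 13.5, offset = 0,
                      noise_sd = 0, n_frames = 300, dt = 0.087, venc = 100,
                      arteries = NULL, seed = 1L) {
  waveform <- match.arg(waveform)
  stopifnot(tc > 0, tb > tc, qc_plus > 0, mod_scale >= 0, mod_scale < 1,
            mod_shift >= 0, noise_sd >= 0, n_frames >= 2, dt > 0, venc > 0)
  if (n_frames * dt <= 3 * tb)
    stop("the series must span more than three breathing cycles ",
         "(n_frames * dt > 3 * tb)")
  structure(list(tc = tc, tb = tb, qc_plus = qc_plus, waveform = waveform,
                 mod_scale = mod_scale, mod_shift = mod_shift,
                 offset = offset, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames), dt = dt, venc = venc,
                 arteries = arteries, seed = as.integer(seed)),
            class = "flow_spec")
}

# Cardiac waveform shape on phase theta in [0, 2pi); zero-mean, unit-free.
cardiac_shape <- function(theta, waveform = "biphasic") {
  switch(waveform,
         biphasic = sin(theta) + 0.25 * sin(2 * theta + 0.9),
         sine = sin(theta),
         stop("unknown waveform"))
}

#' Geometry of the synthetic phase-contrast acquisition plane
#'
#' @param dim Image dimensions in pixels.
#' @param pixel_spacing Pixel size pair, mm.
#' @param center Aqueduct disk centre (x, y), mm; `NULL` = image centre.
#' @param radius Aqueduct disk radius, mm.
#' @return An object of class `roi_geometry`.
#' @export
roi_geometry <- function(dim = c(32L, 32L), pixel_spacing = c(2, 2),
                         center = NULL, radius = 3) {
  stopifnot(all(dim >= 4), all(pixel_spacing > 0), radius > 0)
  if (is.null(center))
    center <- (dim - 1) / 2 * pixel_spacing
  structure(list(dim = as.integer(dim),
                 pixel_spacing = as.numeric(pixel_spacing),
                 center = as.numeric(center), radius = radius),
            class = "roi_geometry")
}

#' Render a synthetic phase-contrast velocity series
#'
#' The true flow rate is
#' `Q(t) = (1 + m sin(2 pi t / Tb)) * c(t) + b sin(2 pi t / Tb)` with `c(t)`
#' the periodic cardiac waveform. Velocities are laid onto a parabolic
#' profile inside the aqueduct disk and scaled so that the pixel-area
#' weighted sum reproduces `Q(t)` exactly before offset, aliasing and noise.
#'
#' The ground-truth breath-driven peaks are recorded in the
#' limits-of-agreement sense in which they are measured: for sinusoidal
#' modulation the per-cycle extreme deviations have SD `(m·Qpeak + b)/sqrt(2)`,
#' so `Qb_true = 1.96 (m·Qpeak + b)/sqrt(2)`.
#'
#' @param spec A [flow_spec()].
#' @param geom A [roi_geometry()].
#' @return A list with components `series` (a [velocity_series()]) and
#'   `truth` (true flow curve, periods, cardiac/breath-driven peaks, stroke
#'   volume, ROI mask, offset).
#' @export
make_phantom_series <- function(spec, geom = roi_geometry()) {
  stopifnot(inherits(spec, "flow_spec"), inherits(geom, "roi_geometry"))
  nx <- geom$dim[1]; ny <- geom$dim[2]
  px <- geom$pixel_spacing
  xs <- (0:(nx - 1)) * px[1]
  ys <- (0:(ny - 1)) * px[2]
  d2 <- outer((xs - geom$center[1])^2, (ys - geom$center[2])^2, "+")
  roi <- d2 <= geom$radius^2
  n_roi <- sum(roi)
  if (n_roi < 1L) stop("aqueduct disk smaller than one pixel")
  w <- ifelse(roi, 1 - d2 / geom$radius^2, 0)
  # guard against an all-boundary disk with zero parabolic weight
  if (sum(w) <= 0) w <- roi + 0
  pixel_area <- prod(px)
  w_norm <- w / (sum(w) * pixel_area)   # so sum(v * area) = Q

  t <- (0:(spec$n_frames - 1)) * spec$dt
  shape <- cardiac_shape(2 * pi * t / spec$tc, spec$waveform)
  th <- seq(0, 2 * pi, length.out = 10001L)
  sh <- cardiac_shape(th, spec$waveform)
  alpha <- spec$qc_plus / max(sh)
  cwave <- alpha * shape
  resp <- sin(2 * pi * t / spec$tb)
  q_true <- (1 + spec$mod_scale * resp) * cwave + spec$mod_shift * resp

  v <- array(0, c(nx, ny, spec$n_frames))
  for (k in seq_len(spec$n_frames))
    v[, , k] <- w_norm * q_true[k]
  v <- v + spec$offset
  if (!is.null(spec$arteries)) {
    pulse <- pmax(sin(2 * pi * t / spec$tc - 0.4), 0)^2
    for (art in spec$arteries) {
      a2 <- outer((xs - art$center[1])^2, (ys - art$center[2])^2, "+")
      disk <- a2 <= art$radius^2
      if (!any(disk)) stop("arterial disk smaller than one pixel")
      for (k in seq_len(spec$n_frames))
        v[, , k][disk] <- v[, , k][disk] + art$peak * pulse[k]
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    v <- v + array(stats::rnorm(length(v), sd = spec$noise_sd), dim(v))
  }
  v <- spec$venc - ((spec$venc - v) %% (2 * spec$venc))  # wrap to (-venc, venc]

  qc_plus_true <- alpha * max(sh)
  qc_minus_true <- -alpha * min(sh)
  dev_plus <- spec$mod_scale * qc_plus_true + spec$mod_shift
  dev_minus <- abs(-spec$mod_scale * qc_minus_true + spec$mod_shift)
  pos <- pmax(alpha * sh, 0); neg <- pmax(-alpha * sh, 0)
  sv_true <- 0.5 * (mean(pos) + mean(neg)) * spec$tc

  truth <- list(q_true = q_true, times = t, tc = spec$tc, tb = spec$tb,
                qc_plus = qc_plus_true, qc_minus = qc_minus_true,
                qc = (qc_plus_true + qc_minus_true) / 2,
                qb_plus = 1.96 * dev_plus / sqrt(2),
                qb_minus = 1.96 * dev_minus / sqrt(2),
                sv = sv_true, q_net = 0,
                offset = spec$offset, roi = roi, weights = w_norm,
                spec = spec)
  list(series = velocity_series(v, spec$dt, px, spec$venc), truth = truth)
}
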