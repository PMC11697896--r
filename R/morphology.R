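# Morphological pipeline: from a 3D volume plus operator landmarks to a
# finite-element aqueduct model with element-wise and cumulative hydraulic
# resistance.

# Bilinear interpolation of a matrix at physical coordinates (mm).
# Pixel i (1-based) sits at (i - 1) * spacing; queries are clamped to the
# grid hull.
bilinear_sample <- function(data, spacing, x, y) {
  fx <- pmin(pmax(x / spacing[1], 0), nrow(data) - 1)
  fy <- pmin(pmax(y / spacing[2], 0), ncol(data) - 1)
  i0 <- pmin(floor(fx), nrow(data) - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), ncol(data) - 2); j0 <- pmax(j0, 0)
  if (nrow(data) == 1L) i0 <- rep(0, length(fx))
  if (ncol(data) == 1L) j0 <- rep(0, length(fy))
  tx <- fx - i0; ty <- fy - j0
  n <- nrow(data)
  idx <- function(i, j) i + j * n + 1L
  i1 <- pmin(i0 + 1, nrow(data) - 1); j1 <- pmin(j0 + 1, ncol(data) - 1)
  v00 <- data[idx(i0, j0)]; v10 <- data[idx(i1, j0)]
  v01 <- data[idx(i0, j1)]; v11 <- data[idx(i1, j1)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Maximum-intensity projection of selected slices
#'
#' Pixel-wise maximum across 2-3 selected slices of a morphological volume,
#' rendering the full (slightly curved) aqueduct in a single 2D image.
#'
#' @param volume A [morph_volume()].
#' @param slice_indices 2 or 3 slice indices (1-based).
#' @return A [projection_image()] with the in-plane voxel spacing.
#' @export
mip_project <- function(volume, slice_indices) {
  stopifnot(inherits(volume, "morph_volume"))
  slice_indices <- as.integer(slice_indices)
  if (length(slice_indices) < 2L || length(slice_indices) > 3L)
    stop("`slice_indices` must select 2 or 3 slices")
  nz <- dim(volume$data)[3]
  if (any(slice_indices < 1L) || any(slice_indices > nz))
    stop("slice index out of range (volume has ", nz, " slices)")
  proj <- volume$data[, , slice_indices[1]]
  for (k in slice_indices[-1])
    proj <- pmax(proj, volume$data[, , k])
  projection_image(proj, volume$spacing[1:2])
}

#' Resample a projection image onto a finer grid
#'
#' Bilinear interpolation onto an isotropic grid, by default 0.03 mm, the
#' working resolution of all subsequent boundary and diameter measurements.
#'
#' @param img A [projection_image()].
#' @param target_spacing Target pixel size, mm (must not exceed the source
#'   spacing).
#' @return A [projection_image()] at the target spacing covering the same
#'   physical extent (pixel-centre hull) as the source.
#' @export
resample_image <- function(img, target_spacing = 0.03) {
  stopifnot(inherits(img, "projection_image"))
  h <- as.numeric(target_spacing)
  if (length(h) == 1L) h <- c(h, h)
  if (any(h <= 0) || any(h > img$spacing))
    stop("`target_spacing` must be positive and not exceed the source spacing")
  if (any(img$spacing / h > 100))
    warning("resampling factor exceeds 100; the output image will be large")
  ext <- (dim(img$data) - 1) * img$spacing
  nx <- floor(ext[1] / h[1]) + 1L
  ny <- floor(ext[2] / h[2]) + 1L
  xs <- (0:(nx - 1)) * h[1]
  ys <- (0:(ny - 1)) * h[2]
  grid <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  out <- bilinear_sample(img$data, img$spacing, grid[, 1], grid[, 2])
  projection_image(matrix(out, nx, ny), h)
}

#' Binarization threshold from the intensity profile across the lumen edge
#'
#' Samples the image along an operator-drawn line crossing the lumen (one
#' sample per pixel, bilinear) and locates the steepest intensity
#' transition. The returned threshold is the half-height of that
#' transition: the mean of the plateau intensities flanking the contiguous
#' high-gradient run around the maximum-gradient sample. For an ideal
#' symmetric edge this equals the intensity at the maximum gradient, but it
#' is robust to where the edge falls relative to the sampling grid. When
#' the profile has no flanking plateaus (a single global ramp) the
#' intensity at the first maximum-gradient sample is returned.
#'
#' @param img A (resampled) [projection_image()].
#' @param line 2x2 matrix, endpoints (x, y) in mm of the profile line.
#' @return The threshold intensity (scalar), with attributes `profile` and
#'   `edge_index`.
#' @export
gradient_threshold <- function(img, line) {
  stopifnot(inherits(img, "projection_image"))
  line <- rbind(line)
  if (nrow(line) != 2L || ncol(line) != 2L)
    stop("`line` must be a 2x2 matrix of endpoints (mm)")
  step <- min(img$spacing)
  len <- sqrt(sum((line[2, ] - line[1, ])^2))
  if (len <= step) stop("profile line is shorter than one pixel")
  n <- max(8L, ceiling(len / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  px <- line[1, 1] + tt * (line[2, 1] - line[1, 1])
  py <- line[1, 2] + tt * (line[2, 2] - line[1, 2])
  prof <- bilinear_sample(img$data, img$spacing, px, py)
  d <- diff(prof)
  g <- abs(d)
  gmax <- max(g)
  if (gmax == 0) stop("no edge found: the intensity profile is flat")
  # smooth |gradient| lightly to locate the edge under noise
  k <- stats::filter(g, rep(1 / 5, 5), sides = 2)
  k[is.na(k)] <- g[is.na(k)]
  i_star <- which(g >= gmax * (1 - 1e-9))[1]   # first of the (near-)ties
  i_loc <- which.max(k)
  # contiguous high-gradient run around the located edge
  keep <- k >= 0.05 * max(k)
  lo <- i_loc; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- i_loc; while (hi < length(g) && keep[hi + 1L]) hi <- hi + 1L
  if (lo <= 1L && hi >= length(g)) {
    thr <- prof[i_star + 1L]   # global ramp: first maximal-gradient sample
  } else {
    # plateau on each side: walk outward while the gradient stays low
    # (stop at the next edge), collecting up to 25 samples
    collect <- function(from, dir) {
      out <- numeric(0); i <- from
      while (i >= 1L && i <= length(g) && length(out) < 25L &&
             k[i] < 0.05 * max(k)) {
        out <- c(out, prof[i + (dir > 0)])
        i <- i + dir
      }
      if (!length(out))
        out <- prof[min(max(from + (dir > 0), 1L), length(prof))]
      out
    }
    side_lo <- collect(lo - 1L, -1L)
    side_hi <- collect(hi + 1L, +1L)
    thr <- (stats::median(side_lo) + stats::median(side_hi)) / 2
  }
  attr(thr, "profile") <- prof
  attr(thr, "edge_index") <- i_star
  thr
}

# Rasterise a polygon (mm coordinates) onto an image grid; returns a logical
# matrix, TRUE inside.
polygon_mask <- function(poly, dims, spacing) {
  xs <- (0:(dims[1] - 1)) * spacing[1]
  ys <- (0:(dims[2] - 1)) * spacing[2]
  pts <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
  matrix(inside, dims[1], dims[2])
}

#' Binarize a projection image
#'
#' A pixel belongs to the lumen iff its intensity is >= `threshold` (CSF is
#' bright on balanced steady-state images) and it is not excluded by the
#' mask.
#'
#' @param img A [projection_image()].
#' @param threshold Intensity threshold, from [gradient_threshold()].
#' @param mask Optional exclusion region: a logical matrix of the image's
#'   dimensions, or a polygon (n x 2 matrix of mm coordinates).
#' @return A [projection_image()] whose data are 0/1.
#' @export
binarize <- function(img, threshold, mask = NULL) {
  stopifnot(inherits(img, "projection_image"))
  rng <- range(img$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop("threshold lies outside the image intensity range")
  bin <- img$data >= as.numeric(threshold)
  if (!is.null(mask)) {
    if (is.matrix(mask) && is.logical(mask)) {
      if (!all(dim(mask) == dim(img$data)))
        stop("logical mask dimensions must match the image")
      excl <- mask
    } else {
      excl <- polygon_mask(rbind(mask), dim(img$data), img$spacing)
    }
    bin <- bin & !excl
  }
  if (!any(bin))
    stop("empty lumen: no pixel is above threshold after masking")
  projection_image(bin + 0, img$spacing)
}

# Snap a physical point onto the lumen; returns 1-based pixel indices.
snap_to_lumen <- function(bin, point, spacing, snap_radius = 5L) {
  i <- round(point[1] / spacing[1]) + 1L
  j <- round(point[2] / spacing[2]) + 1L
  i <- min(max(i, 1L), nrow(bin)); j <- min(max(j, 1L), ncol(bin))
  if (bin[i, j] > 0) return(c(i, j))
  r <- as.integer(snap_radius)
  ii <- max(1L, i - r):min(nrow(bin), i + r)
  jj <- max(1L, j - r):min(ncol(bin), j + r)
  sub <- bin[ii, jj, drop = FALSE]
  if (!any(sub > 0))
    stop("landmark point is more than ", r, " pixels away from the lumen")
  d2 <- outer((ii - i)^2, (jj - j)^2, "+")
  d2[sub <= 0] <- Inf
  k <- arrayInd(which.min(d2), dim(d2))
  c(ii[k[1]], jj[k[2]])
}

#' Extract the lumen centerline between two landmarks
#'
#' Restricts the lumen to the connected component containing the start
#' point, then finds the path from start to end that maximises the distance
#' to the lumen boundary: a shortest path over the lumen pixels with
#' per-pixel cost 1/(1 + d²), d the Euclidean distance transform. The raw
#' pixel path is resampled at the pixel pitch and smoothed with a moving
#' average (window 11) so the tangent direction is continuous.
#'
#' @param bin Binary lumen image from [binarize()].
#' @param start_point,end_point Landmark coordinates (x, y), mm. Points up
#'   to `snap_radius` pixels outside the lumen are snapped onto it.
#' @param snap_radius Snap search radius, pixels.
#' @param smooth_window Moving-average window (odd, in resampled points).
#' @return A data frame of class `centerline_path` with columns `x`, `y`
#'   (mm) and `s` (cumulative arc length, mm).
#' @export
extract_centerline <- function(bin, start_point, end_point,
                               snap_radius = 5L, smooth_window = 11L) {
  stopifnot(inherits(bin, "projection_image"))
  if (isTRUE(all.equal(as.numeric(start_point), as.numeric(end_point))))
    stop("start and end points must be distinct")
  sp <- bin$spacing
  b <- bin$data > 0
  p0 <- snap_to_lumen(b, start_point, sp, snap_radius)
  labels <- EBImage::bwlabel(b + 0)
  comp <- labels == labels[p0[1], p0[2]]
  p1 <- tryCatch(snap_to_lumen(comp, end_point, sp, snap_radius),
                 error = function(e)
                   stop("start and end points are not connected within ",
                        "the lumen (end point lies outside the start's ",
                        "component)", call. = FALSE))
  if (!comp[p1[1], p1[2]])
    stop("start and end points are not connected within the lumen")

  d <- EBImage::distmap(comp + 0)
  cost <- 1 / (1 + d^2)
  nodes <- which(comp)
  m <- length(nodes)
  nr <- nrow(comp); nc <- ncol(comp)
  id <- matrix(NA_integer_, nr, nc); id[nodes] <- seq_len(m)
  ij <- arrayInd(nodes, dim(comp))
  edge_list <- list(); wt_list <- list(); e <- 0L
  for (off in list(c(1L, 0L, 1), c(0L, 1L, 1),
                   c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))) {
    i2 <- ij[, 1] + off[1]; j2 <- ij[, 2] + off[2]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    tgt <- rep(NA_integer_, m)
    tgt[ok] <- id[cbind(i2[ok], j2[ok])]
    ok <- ok & !is.na(tgt)
    if (!any(ok)) next
    e <- e + 1L
    edge_list[[e]] <- rbind(seq_len(m)[ok], tgt[ok])
    wt_list[[e]] <- off[3] * (cost[nodes[ok]] + cost[nodes[tgt[ok]]]) / 2
  }
  edges <- do.call(cbind, edge_list)
  g <- igraph::make_graph(as.vector(edges), n = m, directed = FALSE)
  igraph::E(g)$weight <- unlist(wt_list)
  v0 <- id[(p0[2] - 1L) * nr + p0[1]]
  v1 <- id[(p1[2] - 1L) * nr + p1[1]]
  sp_out <- igraph::shortest_paths(g, from = v0, to = v1, mode = "all")
  vp <- as.integer(sp_out$vpath[[1]])
  if (length(vp) < 2L)
    stop("start and end points are not connected within the lumen")
  path_px <- ij[vp, , drop = FALSE]
  xy <- cbind((path_px[, 1] - 1) * sp[1], (path_px[, 2] - 1) * sp[2])

  # resample at the pixel pitch, then moving-average smooth
  seg <- sqrt(rowSums(diff(xy)^2))
  cs <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(cs) > 0)
  cs <- cs[keep]; xy <- xy[keep, , drop = FALSE]
  step <- min(sp)
  s_new <- seq(0, max(cs), by = step)
  if (s_new[length(s_new)] < max(cs)) s_new <- c(s_new, max(cs))
  xr <- stats::approx(cs, xy[, 1], xout = s_new)$y
  yr <- stats::approx(cs, xy[, 2], xout = s_new)$y
  w <- as.integer(smooth_window)
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && length(xr) > w) {
    half <- (w - 1L) %/% 2L
    pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
    ker <- rep(1 / w, w)
    xr <- stats::filter(pad(xr), ker, sides = 2)[(half + 1):(half + length(xr))]
    yr <- stats::filter(pad(yr), ker, sides = 2)[(half + 1):(half + length(yr))]
  }
  # recentre: move each point to the midpoint of its perpendicular
  # boundary chord, so the path is locally equidistant from the boundary
  # (the shortest path tends to cut the inside of bends slightly)
  bin_img <- projection_image(comp + 0, sp)
  for (pass in 1:2) {
    n_p <- length(xr)
    txv <- c(xr[2] - xr[1], xr[3:n_p] - xr[1:(n_p - 2)],
             xr[n_p] - xr[n_p - 1])
    tyv <- c(yr[2] - yr[1], yr[3:n_p] - yr[1:(n_p - 2)],
             yr[n_p] - yr[n_p - 1])
    nrm <- sqrt(txv^2 + tyv^2); nrm[nrm == 0] <- 1
    nxv <- -tyv / nrm; nyv <- txv / nrm
    for (i in seq_len(n_p)) {
      dp <- chord_half_width(bin_img, xr[i], yr[i], nxv[i], nyv[i],
                             step / 2, 6)
      dm <- chord_half_width(bin_img, xr[i], yr[i], -nxv[i], -nyv[i],
                             step / 2, 6)
      if (!is.na(dp) && !is.na(dm)) {
        shift <- (dp - dm) / 2
        xr[i] <- xr[i] + shift * nxv[i]
        yr[i] <- yr[i] + shift * nyv[i]
      }
    }
    if (w > 1L && length(xr) > w) {
      half <- (w - 1L) %/% 2L
      pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
      ker <- rep(1 / w, w)
      xr <- stats::filter(pad(xr), ker,
                          sides = 2)[(half + 1):(half + length(xr))]
      yr <- stats::filter(pad(yr), ker,
                          sides = 2)[(half + 1):(half + length(yr))]
    }
  }
  # final pass: smoothing spline in arc length (suppresses the residual
  # chord-phase wobble without the end-shortening of a wide moving average)
  s_tmp <- c(0, cumsum(sqrt(diff(xr)^2 + diff(yr)^2)))
  if (length(xr) > 10L) {
    df <- max(8, ceiling(max(s_tmp) / 1.25))
    xr <- stats::predict(stats::smooth.spline(s_tmp, xr, df = df), s_tmp)$y
    yr <- stats::predict(stats::smooth.spline(s_tmp, yr, df = df), s_tmp)$y
  }
  seg <- sqrt(diff(xr)^2 + diff(yr)^2)
  out <- data.frame(x = xr, y = yr, s = c(0, cumsum(seg)))
  class(out) <- c("centerline_path", "data.frame")
  out
}

# Interpolate centerline position and unit tangent at arc positions s.
centerline_at <- function(path, s, tangent_h = 0.15) {
  x <- stats::approx(path$s, path$x, xout = s, rule = 2)$y
  y <- stats::approx(path$s, path$y, xout = s, rule = 2)$y
  smax <- max(path$s)
  s_a <- pmax(s - tangent_h, 0); s_b <- pmin(s + tangent_h, smax)
  tx <- stats::approx(path$s, path$x, xout = s_b)$y -
    stats::approx(path$s, path$x, xout = s_a)$y
  ty <- stats::approx(path$s, path$y, xout = s_b)$y -
    stats::approx(path$s, path$y, xout = s_a)$y
  nrm <- sqrt(tx^2 + ty^2)
  list(x = x, y = y, tx = tx / nrm, ty = ty / nrm)
}

# March from (x0, y0) along (dx, dy) until the interpolated binary image
# drops below 0.5; returns the sub-pixel crossing distance (mm).
chord_half_width <- function(bin, x0, y0, dx, dy, step, max_dist) {
  tvals <- seq(0, max_dist, by = step)
  vals <- bilinear_sample(bin$data, bin$spacing,
                          x0 + tvals * dx, y0 + tvals * dy)
  below <- which(vals < 0.5)
  if (!length(below)) return(NA_real_)
  k <- below[1]
  if (k == 1L) return(0)
  v0 <- vals[k - 1L]; v1 <- vals[k]
  tvals[k - 1L] + (v0 - 0.5) / (v0 - v1) * step
}

#' Partition the centerline into finite elements and measure diameters
#'
#' Divides the path into `n_elements` contiguous segments of equal arc
#' length. Each element's diameter is the chord through its midpoint,
#' perpendicular to the local tangent, between the two sub-pixel lumen
#' boundary crossings (linear interpolation of the binary edge).
#'
#' @param bin Binary lumen image.
#' @param path A `centerline_path` from [extract_centerline()].
#' @param n_elements Number of elements (>= 2; default 100).
#' @param max_chord Maximum half-chord search distance, mm.
#' @return A data frame of class `element_table` with columns `element`,
#'   `s_mid` (mm), `length` (mm), `diameter` (mm) and `angle` (tangent
#'   direction vs the image x-axis, degrees).
#' @export
build_elements <- function(bin, path, n_elements = 100L, max_chord = 6) {
  stopifnot(inherits(bin, "projection_image"))
  n_elements <- as.integer(n_elements)
  if (n_elements < 2L) stop("`n_elements` must be at least 2")
  total <- max(path$s)
  if (total <= 0) stop("centerline has zero arc length")
  el_len <- total / n_elements
  s_mid <- (seq_len(n_elements) - 0.5) * el_len
  ct <- centerline_at(path, s_mid)
  nx <- -ct$ty; ny <- ct$tx
  step <- min(bin$spacing) / 4
  diam <- numeric(n_elements)
  for (i in seq_len(n_elements)) {
    d_pos <- chord_half_width(bin, ct$x[i], ct$y[i], nx[i], ny[i],
                              step, max_chord)
    d_neg <- chord_half_width(bin, ct$x[i], ct$y[i], -nx[i], -ny[i],
                              step, max_chord)
    if (is.na(d_pos) || is.na(d_neg) || (d_pos + d_neg) <= 0)
      stop("element ", i, ": perpendicular chord did not reach the lumen ",
           "boundary (masked hole or open boundary?)")
    diam[i] <- d_pos + d_neg
  }
  out <- data.frame(element = seq_len(n_elements), s_mid = s_mid,
                    length = rep(el_len, n_elements), diameter = diam,
                    angle = atan2(ct$ty, ct$tx) * 180 / pi)
  class(out) <- c("element_table", "data.frame")
  out
}

#' Element-wise and cumulative resistance profile
#'
#' @param elements An `element_table` from [build_elements()] (or any data
#'   frame with `length` and `diameter` columns in mm).
#' @param const A [fluid_constants()] object.
#' @return A list of class `resistance_profile`: the element table with a
#'   resistance column `r` (mPa·s/mm³), the running sum `cumulative_r`, and
#'   `total_r`.
#' @export
resistance_profile <- function(elements, const = fluid_constants()) {
  if (!is.data.frame(elements) || nrow(elements) == 0L)
    stop("`elements` must be a non-empty element table")
  r <- element_resistance(elements$length, elements$diameter, const)
  structure(list(elements = cbind(as.data.frame(elements), r = r),
                 cumulative_r = cumsum(r), total_r = sum(r),
                 const = as_fluid_constants(const)),
            class = "resistance_profile")
}

#' Trim the distal end at 95% of total resistance
#'
#' The terminal end of the aqueduct (entrance to the 4th ventricle)
#' contributes almost no resistance; to standardise the effective length,
#' the endpoint is redefined as the first element at which the cumulative
#' resistance reaches 95% of the total. All summary morphometrics are
#' computed over the retained elements; the operator-defined length is kept
#' as `L_defined`.
#'
#' @param profile A [resistance_profile()].
#' @param path The `centerline_path` the elements were built on.
#' @return A list of class `aqueduct_model` with fields `endpoint_index_95`,
#'   `R` (mPa·s/mm³), `L`, `Ls`, `L_defined`, `tortuosity` (L/Ls), `D_mean`,
#'   `D_min` (mm), the retained `profile`, and empty slots for the
#'   dimensionless numbers filled by [summarize_morphology()].
#' @export
trim_endpoint_95 <- function(profile, path) {
  stopifnot(inherits(profile, "resistance_profile"))
  cum <- profile$cumulative_r
  idx <- which(cum >= 0.95 * profile$total_r)[1]
  el <- profile$elements
  kept <- el[seq_len(idx), , drop = FALSE]
  L <- sum(kept$length)
  ct <- centerline_at(path, c(0, L))
  Ls <- sqrt(diff(ct$x)^2 + diff(ct$y)^2)
  structure(list(profile = profile, endpoint_index_95 = idx,
                 R = cum[idx], L = L, Ls = Ls, L_defined = max(path$s),
                 tortuosity = L / Ls,
                 D_mean = mean(kept$diameter), D_min = min(kept$diameter),
                 womersley_mean = NA_real_, reynolds_max = NA_real_,
                 cardiac_period = NA_real_, peak_flow = NA_real_),
            class = "aqueduct_model")
}

#' Fill in the dimensionless flow numbers of an aqueduct model
#'
#' Womersley-mean is the mean Womersley number over the retained elements at
#' the given cardiac period; Reynold-max is the maximum Reynolds number over
#' the retained elements at the given peak flow (attained at the minimum
#' diameter).
#'
#' @param model An [trim_endpoint_95()] result.
#' @param cardiac_period Cardiac period, s.
#' @param peak_flow Peak flow rate, mm³/s.
#' @param const A [fluid_constants()] object.
#' @return The model with `womersley_mean` and `reynolds_max` filled.
#' @export
summarize_morphology <- function(model, cardiac_period, peak_flow,
                                 const = fluid_constants()) {
  stopifnot(inherits(model, "aqueduct_model"))
  if (cardiac_period <= 0) stop("`cardiac_period` must be positive")
  if (peak_flow < 0) stop("`peak_flow` must be non-negative")
  kept <- model$profile$elements[seq_len(model$endpoint_index_95), ]
  model$womersley_mean <-
    mean(womersley_number(kept$diameter, cardiac_period, const))
  model$reynolds_max <-
    max(reynolds_number(peak_flow, kept$diameter, const))
  model$cardiac_period <- cardiac_period
  model$peak_flow <- peak_flow
  model
}

#' @export
print.aqueduct_model <- function(x, ...) {
  cat("Aqueduct finite-element model\n")
  cat(sprintf("  elements retained : %d of %d (95%% resistance endpoint)\n",
              x$endpoint_index_95, nrow(x$profile$elements)))
  cat(sprintf("  R                 : %.1f mPa·s/mm³\n", x$R))
  cat(sprintf("  L / Ls / L-defined: %.1f / %.1f / %.1f mm (L/Ls = %.3f)\n",
              x$L, x$Ls, x$L_defined, x$tortuosity))
  cat(sprintf("  D-mean / D-min    : %.2f / %.2f mm\n", x$D_mean, x$D_min))
  if (is.finite(x$womersley_mean))
    cat(sprintf("  Womersley-mean    : %.1f\n", x$womersley_mean))
  if (is.finite(x$reynolds_max))
    cat(sprintf("  Reynold-max       : %.1f\n", x$reynolds_max))
  invisible(x)
}
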