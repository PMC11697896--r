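#' Morphological image volume
#'
#' A 3D scalar intensity grid with physical voxel spacing. The first two
#' array dimensions are in-plane (x, y), the third indexes slices.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric triple, voxel size in mm (in-plane x, in-plane y,
#'   slice thickness).
#' @return An object of class `morph_volume`.
#' @export
morph_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("`data` must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (mm)")
  structure(list(data = data, spacing = spacing), class = "morph_volume")
}

#' @export
print.morph_volume <- function(x, ...) {
  cat(sprintf("morph_volume: %s voxels @ %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' 2D projection image
#'
#' @param data 2D numeric matrix of intensities; first dimension is x.
#' @param spacing Numeric pair, pixel size in mm.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(data, spacing) {
  if (!is.matrix(data) || any(dim(data) < 1L))
    stop("`data` must be a non-empty matrix")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be two positive pixel sizes (mm)")
  structure(list(data = data, spacing = spacing), class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("projection_image: %d x %d px @ %s mm\n",
              nrow(x$data), ncol(x$data),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Manual landmarks for aqueduct morphometry
#'
#' All coordinates are physical, in mm, measured from the centre of the
#' first pixel of the projection image (pixel index i, 0-based, sits at
#' i * spacing mm).
#'
#' @param threshold_line 2x2 matrix; rows are the two endpoints (x, y) in mm
#'   of the line drawn across the lumen at its narrowest point.
#' @param start_point,end_point Numeric pairs (x, y) in mm: user-defined
#'   aqueduct start and end.
#' @param exclusion_mask Optional polygon (n x 2 matrix, mm) of a region to
#'   exclude before segmentation, or `NULL`.
#' @return An object of class `aq_landmarks`.
#' @export
aq_landmarks <- function(threshold_line, start_point, end_point,
                         exclusion_mask = NULL) {
  threshold_line <- rbind(threshold_line)
  if (!is.matrix(threshold_line) || nrow(threshold_line) != 2L ||
      ncol(threshold_line) != 2L)
    stop("`threshold_line` must be a 2x2 matrix of endpoint coordinates")
  if (isTRUE(all.equal(threshold_line[1, ], threshold_line[2, ])))
    stop("`threshold_line` endpoints must be distinct")
  start_point <- as.numeric(start_point); end_point <- as.numeric(end_point)
  if (length(start_point) != 2L || length(end_point) != 2L)
    stop("start/end points must be (x, y) pairs in mm")
  if (isTRUE(all.equal(start_point, end_point)))
    stop("start and end points must be distinct")
  if (!is.null(exclusion_mask)) {
    exclusion_mask <- rbind(exclusion_mask)
    if (ncol(exclusion_mask) != 2L || nrow(exclusion_mask) < 3L)
      stop("`exclusion_mask` must be a polygon with at least 3 vertices")
  }
  structure(list(threshold_line = threshold_line, start_point = start_point,
                 end_point = end_point, exclusion_mask = exclusion_mask),
            class = "aq_landmarks")
}

#' 2D+time velocity-encoded image series
#'
#' @param velocities 3D array (x, y, time) of signed velocities in mm/s;
#'   positive is the 4th-to-3rd-ventricle direction.
#' @param dt Frame interval, s.
#' @param pixel_spacing Numeric pair, in-plane pixel size in mm.
#' @param venc Velocity-encoding limit, mm/s; stored velocities lie in
#'   (-venc, venc].
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(velocities, dt, pixel_spacing, venc) {
  if (!is.array(velocities) || length(dim(velocities)) != 3L)
    stop("`velocities` must be a 3D array (x, y, time)")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive frame interval (s)")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be two positive pixel sizes (mm)")
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    stop("`venc` must be positive (mm/s)")
  if (dim(velocities)[3] < 2L)
    stop("the series must contain at least two frames")
  structure(list(velocities = velocities, dt = dt,
                 pixel_spacing = pixel_spacing, venc = venc,
                 n_frames = dim(velocities)[3],
                 pixel_area = prod(pixel_spacing)),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$velocities)
  cat(sprintf(
    "velocity_series: %d x %d px, %d frames @ %.3f s (venc %g mm/s)\n",
    d[1], d[2], d[3], x$dt, x$venc))
  invisible(x)
}

#' Continuous flow curve
#'
#' @param times Frame times, s (strictly increasing, constant step).
#' @param flow Flow rate per frame, mm³/s.
#' @return A data frame of class `flow_curve` with columns `time` and `flow`.
#' @export
flow_curve <- function(times, flow) {
  if (length(times) != length(flow))
    stop("`times` and `flow` must have equal length")
  if (length(times) >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("`times` must have a constant step")
  }
  structure(data.frame(time = times, flow = flow),
            class = c("flow_curve", "data.frame"))
}
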