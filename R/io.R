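# Readers and writers: NIfTI images, JSON landmark sidecars, and JSON /
# tabular result reports with provenance.

#' Read a morphological volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param spacing Optional voxel-size override (mm); default from the
#'   header.
#' @return A [morph_volume()].
#' @export
read_morph_volume <- function(path, spacing = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  if (is.null(spacing)) {
    spacing <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("invalid voxel sizes in the NIfTI header; pass `spacing`")
  }
  morph_volume(arr, spacing)
}

#' Read a velocity-encoded series from a NIfTI file
#'
#' The third array dimension is time. Values must already be velocities;
#' use `unit = "cm/s"` if they are stored in cm/s.
#'
#' @param path Path to a `.nii` / `.nii.gz` file (3D: x, y, time).
#' @param dt Frame interval, s.
#' @param venc Velocity-encoding limit, in the same unit as the data.
#' @param pixel_spacing Optional in-plane pixel size (mm); default from the
#'   header.
#' @param unit `"mm/s"` (default) or `"cm/s"`.
#' @return A [velocity_series()] in mm/s.
#' @export
read_velocity_series <- function(path, dt, venc, pixel_spacing = NULL,
                                 unit = c("mm/s", "cm/s")) {
  unit <- match.arg(unit)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[3] == 1L)
    arr <- arr[, , 1, , drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D (x, y, time) series")
  if (is.null(pixel_spacing)) {
    pixel_spacing <- RNifti::pixdim(img)[1:2]
    if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
      stop("invalid pixel sizes in the NIfTI header; pass `pixel_spacing`")
  }
  scale <- if (unit == "cm/s") 10 else 1
  velocity_series(arr * scale, dt = dt, pixel_spacing = pixel_spacing,
                  venc = venc * scale)
}

#' Write a volume or series to NIfTI
#'
#' @param x A [morph_volume()] or [velocity_series()].
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "morph_volume")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- x$spacing
  } else if (inherits(x, "velocity_series")) {
    img <- RNifti::asNifti(x$velocities)
    RNifti::pixdim(img) <- c(x$pixel_spacing, x$dt)
  } else stop("cannot write object of class ", class(x)[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read landmarks from a JSON sidecar
#'
#' The sidecar stores pixel coordinates on the resampled projection grid
#' with an explicit `"indexing": "0-based"` field and the grid's
#' `pixel_spacing_mm`, which converts them to the mm coordinates used by
#' the package (position = index * spacing).
#'
#' @param path Path to the JSON sidecar.
#' @return An [aq_landmarks()] object (mm coordinates), with attribute
#'   `slice_indices` (1-based) when the sidecar provides them.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$indexing, "0-based"))
    stop("landmark sidecar must declare \"indexing\": \"0-based\"")
  sp <- as.numeric(j$pixel_spacing_mm)
  if (length(sp) == 1L) sp <- c(sp, sp)
  to_mm <- function(p) {
    p <- rbind(p)
    sweep(p, 2L, sp, "*")
  }
  lm <- aq_landmarks(threshold_line = to_mm(j$threshold_line),
                     start_point = as.numeric(j$start_point) * sp,
                     end_point = as.numeric(j$end_point) * sp,
                     exclusion_mask = if (!is.null(j$exclusion_polygon))
                       to_mm(j$exclusion_polygon) else NULL)
  if (!is.null(j$slice_indices))
    attr(lm, "slice_indices") <- as.integer(j$slice_indices) + 1L
  lm
}

#' Write landmarks to a JSON sidecar
#'
#' @param landmarks An [aq_landmarks()] object (mm coordinates).
#' @param path Output path.
#' @param pixel_spacing Grid spacing (mm) used to express the pixel
#'   coordinates (default 0.03, the resampled grid).
#' @param slice_indices Optional 1-based slice indices for the projection
#'   (stored 0-based).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, pixel_spacing = 0.03,
                            slice_indices = NULL) {
  stopifnot(inherits(landmarks, "aq_landmarks"))
  sp <- rep(as.numeric(pixel_spacing), length.out = 2L)
  to_px <- function(p) sweep(rbind(p), 2L, sp, "/")
  j <- list(indexing = "0-based", pixel_spacing_mm = sp,
            threshold_line = to_px(landmarks$threshold_line),
            start_point = as.numeric(landmarks$start_point) / sp,
            end_point = as.numeric(landmarks$end_point) / sp)
  if (!is.null(landmarks$exclusion_mask))
    j$exclusion_polygon <- to_px(landmarks$exclusion_mask)
  if (!is.null(slice_indices))
    j$slice_indices <- as.integer(slice_indices) - 1L
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Provenance header embedded in every report.
report_provenance <- function(config = NULL) {
  list(package = "aqueduct",
       version = as.character(utils::packageVersion("aqueduct")),
       config = config)
}

#' Write a morphology report (JSON + tab-delimited text)
#'
#' @param model An [summarize_morphology()] / [trim_endpoint_95()] result.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param config Optional run configuration embedded for provenance.
#' @return Named character vector of the files written, invisibly.
#' @export
write_morphology_report <- function(model, dir, prefix = "morpho",
                                    config = NULL) {
  stopifnot(inherits(model, "aqueduct_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- model$profile$elements
  el$cumulative_r <- model$profile$cumulative_r
  summary <- list(R = model$R, L = model$L, Ls = model$Ls,
                  L_over_Ls = model$tortuosity, L_defined = model$L_defined,
                  D_mean = model$D_mean, D_min = model$D_min,
                  womersley_mean = model$womersley_mean,
                  reynolds_max = model$reynolds_max,
                  endpoint_index_95 = model$endpoint_index_95,
                  n_elements = nrow(el))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(provenance = report_provenance(config),
                            summary = summary, elements = el),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  txt_path <- file.path(dir, paste0(prefix, ".txt"))
  con <- file(txt_path, "w")
  writeLines(c("Aqueduct morphology report",
               sprintf("R (mPa·s/mm³)\t%.2f", model$R),
               sprintf("L (mm)\t%.2f", model$L),
               sprintf("Ls (mm)\t%.2f", model$Ls),
               sprintf("L/Ls\t%.3f", model$tortuosity),
               sprintf("L-defined (mm)\t%.2f", model$L_defined),
               sprintf("D-mean (mm)\t%.2f", model$D_mean),
               sprintf("D-min (mm)\t%.2f", model$D_min),
               sprintf("Womersley-mean\t%.2f", model$womersley_mean),
               sprintf("Reynold-max\t%.1f", model$reynolds_max),
               ""), con)
  suppressWarnings(utils::write.table(format(el, digits = 6), con,
                                      sep = "\t", row.names = FALSE,
                                      quote = FALSE))
  close(con)
  invisible(c(json = json_path, txt = txt_path))
}

#' Write a flow report (JSON + CSV curves)
#'
#' @param metrics A [flow_metrics()] result.
#' @param ensemble The [build_ensemble()] result.
#' @param curve The continuous [flow_curve()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param config Optional run configuration embedded for provenance.
#' @return Named character vector of the files written, invisibly.
#' @export
write_flow_report <- function(metrics, ensemble, curve, dir,
                              prefix = "flow", config = NULL) {
  stopifnot(inherits(metrics, "flow_metrics"),
            inherits(ensemble, "cycle_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(provenance = report_provenance(config),
                            metrics = unclass(metrics)),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  curve_path <- file.path(dir, paste0(prefix, "_curve.csv"))
  utils::write.csv(as.data.frame(curve), curve_path, row.names = FALSE)
  ens_path <- file.path(dir, paste0(prefix, "_cycle.csv"))
  utils::write.csv(data.frame(phase = ensemble$phase,
                              mean = ensemble$mean_curve,
                              sd = ensemble$sd_curve,
                              loa_upper = ensemble$loa_upper,
                              loa_lower = ensemble$loa_lower),
                   ens_path, row.names = FALSE)
  invisible(c(json = json_path, curve = curve_path, cycle = ens_path))
}

#' Write a pressure report (JSON + gradient-curve CSV)
#'
#' @param pm A [compute_pressure_metrics()] result.
#' @param gradient Optional [pressure_gradient_curve()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param config Optional run configuration embedded for provenance.
#' @return Named character vector of the files written, invisibly.
#' @export
write_pressure_report <- function(pm, gradient = NULL, dir,
                                  prefix = "deltap", config = NULL) {
  stopifnot(inherits(pm, "pressure_metrics"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(provenance = report_provenance(config),
                            pressure = unclass(pm)),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  out <- c(json = json_path)
  if (!is.null(gradient)) {
    gpath <- file.path(dir, paste0(prefix, "_gradient.csv"))
    utils::write.csv(as.data.frame(gradient), gpath, row.names = FALSE)
    out <- c(out, gradient = gpath)
  }
  invisible(out)
}
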