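# End-to-end pipelines tying the modules together. These are what the
# command-line tool (inst/cli/aqueduct.R) calls.

log_stage <- function(verbose, ...) if (verbose) message("[aqueduct] ", ...)

#' Run the full morphology pipeline
#'
#' Projection (MIP) of the selected slices, resampling to the working
#' resolution, gradient-based binarization with optional exclusion mask,
#' centerline extraction, finite-element diameter measurement, resistance
#' profile, 95% endpoint trimming and summary morphometrics.
#'
#' @param volume A [morph_volume()] or a NIfTI path.
#' @param landmarks An [aq_landmarks()] object or a JSON sidecar path.
#' @param slice_indices 2-3 slice indices (1-based) for the projection;
#'   defaults to the sidecar's, if present.
#' @param n_elements Number of finite elements (default 100).
#' @param target_spacing Working resolution after resampling, mm.
#' @param cardiac_period,peak_flow Optional: fill the dimensionless numbers
#'   ([summarize_morphology()]).
#' @param const A [fluid_constants()] object.
#' @param output_dir Optional directory for the JSON/.txt report.
#' @param verbose Log each stage.
#' @return The [trim_endpoint_95()] model (with dimensionless numbers when
#'   the periods were given), with the resistance profile and centerline
#'   attached.
#' @export
run_morpho <- function(volume, landmarks, slice_indices = NULL,
                       n_elements = 100L, target_spacing = 0.03,
                       cardiac_period = NULL, peak_flow = NULL,
                       const = fluid_constants(), output_dir = NULL,
                       verbose = TRUE) {
  if (is.character(volume)) volume <- read_morph_volume(volume)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (!inherits(landmarks, "aq_landmarks"))
    stop("landmark validation failed: supply an aq_landmarks object or ",
         "a JSON sidecar path")
  if (is.null(slice_indices))
    slice_indices <- attr(landmarks, "slice_indices")
  if (is.null(slice_indices))
    stop("`slice_indices` must select the 2-3 slices to project")
  if (n_elements < 10L)
    warning("n_elements = ", n_elements,
            ": discretization is coarse; resistance may be biased")
  log_stage(verbose, "MIP over slices ",
            paste(slice_indices, collapse = ", "))
  proj <- mip_project(volume, slice_indices)
  log_stage(verbose, "resampling to ", target_spacing, " mm")
  fine <- resample_image(proj, target_spacing)
  log_stage(verbose, "gradient threshold along the drawn line")
  thr <- gradient_threshold(fine, landmarks$threshold_line)
  log_stage(verbose, "binarizing at intensity ", signif(thr, 5))
  bin <- binarize(fine, thr, mask = landmarks$exclusion_mask)
  log_stage(verbose, "extracting centerline")
  path <- extract_centerline(bin, landmarks$start_point,
                             landmarks$end_point)
  log_stage(verbose, "measuring ", n_elements, " elements")
  elements <- build_elements(bin, path, n_elements)
  profile <- resistance_profile(elements, const)
  model <- trim_endpoint_95(profile, path)
  if (!is.null(cardiac_period) && !is.null(peak_flow))
    model <- summarize_morphology(model, cardiac_period, peak_flow, const)
  model$centerline <- path
  model$threshold <- as.numeric(thr)
  if (!is.null(output_dir)) {
    cfg <- list(slice_indices = slice_indices, n_elements = n_elements,
                target_spacing = target_spacing,
                cardiac_period = cardiac_period, peak_flow = peak_flow,
                mu = const$mu, rho = const$rho)
    files <- write_morphology_report(model, output_dir, config = cfg)
    log_stage(verbose, "report written to ", files[["json"]])
  }
  model
}

#' Run the full flow pipeline
#'
#' ROI detection (or manual override), per-pixel de-aliasing, stationary-
#' tissue background correction, continuous flow curve, cardiac-cycle
#' segmentation, 32-point ensemble averaging with limits of agreement, and
#' flow metrics.
#'
#' @param series A [velocity_series()] or a NIfTI path.
#' @param dt,venc Frame interval (s) and encoding limit (mm/s); required
#'   when `series` is a path.
#' @param pixel_spacing Pixel size (mm) override for path input.
#' @param roi Optional logical matrix: manual ROI.
#' @param cardiac_band,resp_band Frequency bands, Hz.
#' @param n_phase Phase samples per cycle (default 32).
#' @param arterial_roi Optional logical matrix over the artery edge; adds a
#'   systole/diastole split to the result.
#' @param output_dir Optional directory for the JSON/CSV report.
#' @param verbose Log each stage.
#' @return A list of class `flow_result`: `metrics`, `ensemble`, `curve`,
#'   `roi`, `cycles`, and `phases` (when an arterial ROI was given).
#' @export
run_flow <- function(series, dt = NULL, venc = NULL, pixel_spacing = NULL,
                     roi = NULL, cardiac_band = c(0.7, 2.5),
                     resp_band = c(0.1, 0.5), n_phase = 32L,
                     arterial_roi = NULL, output_dir = NULL,
                     verbose = TRUE) {
  if (is.character(series)) {
    if (is.null(dt) || is.null(venc))
      stop("config error: `dt` and `venc` are required with a file input")
    series <- read_velocity_series(series, dt = dt, venc = venc,
                                   pixel_spacing = pixel_spacing)
  }
  stopifnot(inherits(series, "velocity_series"))
  log_stage(verbose, "detecting ROI (cardiac band ",
            paste(cardiac_band, collapse = "-"), " Hz)")
  roi_obj <- detect_roi(series, cardiac_band, override = roi)
  log_stage(verbose, "de-aliasing (venc ", series$venc, " mm/s)")
  series <- dealias(series)
  log_stage(verbose, "background correction")
  series <- background_correct(series, roi_obj, cardiac_band)
  log_stage(verbose, "flow curve over ", sum(roi_obj$mask), " ROI pixels")
  curve <- compute_flow_curve(series, roi_obj)
  log_stage(verbose, "segmenting cardiac cycles")
  cycles <- segment_cycles(curve, cardiac_band = cardiac_band)
  log_stage(verbose, length(cycles), " cycles; building ensemble")
  ensemble <- build_ensemble(cycles, n_phase)
  metrics <- flow_metrics(ensemble, curve, roi_obj, resp_band)
  phases <- NULL
  if (!is.null(arterial_roi)) {
    log_stage(verbose, "systole/diastole split from the arterial curve")
    art_curve <- compute_flow_curve(series,
                                    roi_mask(arterial_roi,
                                             series$pixel_spacing))
    phases <- cardiac_phase_split(art_curve, ensemble, cycles)
  }
  out <- structure(list(metrics = metrics, ensemble = ensemble,
                        curve = curve, roi = roi_obj, cycles = cycles,
                        phases = phases),
                   class = "flow_result")
  if (!is.null(output_dir)) {
    cfg <- list(dt = series$dt, venc = series$venc,
                cardiac_band = cardiac_band, resp_band = resp_band,
                n_phase = n_phase)
    files <- write_flow_report(metrics, ensemble, curve, output_dir,
                               config = cfg)
    log_stage(verbose, "report written to ", files[["json"]])
  }
  out
}

#' Combine morphology and flow into pressure differences
#'
#' ΔP = R·Q for each cardiac- and breath-driven peak flow, plus the
#' along-length pressure-gradient curve at the peak cardiac-driven flow.
#'
#' @param morpho An `aqueduct_model`, a morphology JSON report path, or a
#'   single resistance value (mPa·s/mm³).
#' @param flow A `flow_result`, a [flow_metrics()] object, or a flow JSON
#'   report path.
#' @param gradient_flow Flow rate for the gradient curve; default the peak
#'   cardiac-driven flow Qc+.
#' @param output_dir Optional directory for the JSON/CSV report.
#' @param verbose Log stages.
#' @return A list of class `deltap_result`: `pressure`
#'   ([compute_pressure_metrics()]) and `gradient` (when element data are
#'   available).
#' @export
run_deltap <- function(morpho, flow, gradient_flow = NULL,
                       output_dir = NULL, verbose = TRUE) {
  profile <- NULL; endpoint <- NULL
  if (is.character(morpho)) {
    if (!file.exists(morpho)) stop("morphology report not found: ", morpho)
    j <- jsonlite::read_json(morpho, simplifyVector = TRUE)
    resistance <- j$summary$R
    endpoint <- j$summary$endpoint_index_95
    if (!is.null(j$elements))
      profile <- resistance_profile(j$elements)
  } else if (inherits(morpho, "aqueduct_model")) {
    resistance <- morpho$R
    profile <- morpho$profile
    endpoint <- morpho$endpoint_index_95
  } else if (is.numeric(morpho) && length(morpho) == 1L) {
    resistance <- morpho
  } else stop("`morpho` must be a model, report path or resistance value")

  if (is.character(flow)) {
    if (!file.exists(flow)) stop("flow report not found: ", flow)
    j <- jsonlite::read_json(flow, simplifyVector = TRUE)
    fm <- structure(j$metrics, class = "flow_metrics")
  } else if (inherits(flow, "flow_result")) {
    fm <- flow$metrics
  } else if (inherits(flow, "flow_metrics")) {
    fm <- flow
  } else stop("`flow` must be a flow result, metrics or report path")

  pm <- compute_pressure_metrics(resistance, fm)
  grad <- NULL
  if (!is.null(profile)) {
    qg <- if (is.null(gradient_flow)) fm$qc_plus else gradient_flow
    grad <- pressure_gradient_curve(profile, qg, endpoint)
  }
  log_stage(verbose, sprintf(
    "peak-to-peak cardiac %.1f Pa, breath %.1f Pa",
    pm$p2p_cardiac, pm$p2p_breath))
  out <- structure(list(pressure = pm, gradient = grad),
                   class = "deltap_result")
  if (!is.null(output_dir)) {
    files <- write_pressure_report(pm, grad, output_dir,
                                   config = list(resistance = resistance))
    log_stage(verbose, "report written to ", files[["json"]])
  }
  out
}
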