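# Trans-aqueductal pressure differences: resistance x flow, split into
# cardiac-driven and breath-driven components.

#' Cardiac- and breath-driven pressure differences
#'
#' Multiplies the aqueduct's hydraulic resistance with each of the
#' cardiac-driven and breath-driven peak flow rates: ΔP = R·Q (Pa).
#' Peak-to-peak values are the sums of the two directions; the
#' breath-to-cardiac ratio is reported in percent.
#'
#' @param resistance Total aqueduct resistance R, mPa·s/mm³.
#' @param fm A [flow_metrics()] object.
#' @return A list of class `pressure_metrics`: `dpc_plus`, `dpc_minus`,
#'   `dpc`, `dpb_plus`, `dpb_minus`, `dpb` (Pa, magnitudes), `p2p_cardiac`,
#'   `p2p_breath` (Pa) with mmHg mirrors, and `ratio_b_over_c` (%).
#' @examples
#' fm <- structure(list(qc_plus = 115, qc_minus = 127, qb_plus = 97,
#'                      qb_minus = 93), class = "flow_metrics")
#' compute_pressure_metrics(100, fm)$p2p_cardiac  # 24.2 Pa
#' @export
compute_pressure_metrics <- function(resistance, fm) {
  if (!is.numeric(resistance) || length(resistance) != 1L || resistance < 0)
    stop("`resistance` must be a single non-negative number (mPa·s/mm³)")
  stopifnot(inherits(fm, "flow_metrics"))
  dpc_plus <- pressure_difference(resistance, fm$qc_plus)
  dpc_minus <- pressure_difference(resistance, fm$qc_minus)
  dpb_plus <- pressure_difference(resistance, fm$qb_plus)
  dpb_minus <- pressure_difference(resistance, fm$qb_minus)
  dpc <- (dpc_plus + dpc_minus) / 2
  dpb <- (dpb_plus + dpb_minus) / 2
  p2p_c <- dpc_plus + dpc_minus
  p2p_b <- dpb_plus + dpb_minus
  structure(list(dpc_plus = dpc_plus, dpc_minus = dpc_minus, dpc = dpc,
                 dpb_plus = dpb_plus, dpb_minus = dpb_minus, dpb = dpb,
                 p2p_cardiac = p2p_c, p2p_breath = p2p_b,
                 p2p_cardiac_mmhg = pa_to_mmhg(p2p_c),
                 p2p_breath_mmhg = pa_to_mmhg(p2p_b),
                 ratio_b_over_c = if (dpc > 0) 100 * dpb / dpc else NA_real_,
                 resistance = resistance),
            class = "pressure_metrics")
}

#' @export
print.pressure_metrics <- function(x, ...) {
  cat("Trans-aqueductal pressure differences\n")
  cat(sprintf("  dPc+ / dPc- / dPc : %.2f / %.2f / %.2f Pa\n",
              x$dpc_plus, x$dpc_minus, x$dpc))
  cat(sprintf("  dPb+ / dPb- / dPb : %.2f / %.2f / %.2f Pa\n",
              x$dpb_plus, x$dpb_minus, x$dpb))
  cat(sprintf("  peak-to-peak cardiac: %.1f Pa (%.2f mmHg)\n",
              x$p2p_cardiac, x$p2p_cardiac_mmhg))
  cat(sprintf("  peak-to-peak breath : %.1f Pa (%.2f mmHg)\n",
              x$p2p_breath, x$p2p_breath_mmhg))
  if (is.finite(x$ratio_b_over_c))
    cat(sprintf("  dPb/dPc             : %.0f %%\n", x$ratio_b_over_c))
  invisible(x)
}

#' Pressure difference along the aqueduct length
#'
#' Cumulative ΔP from the starting point along the centerline at a given
#' flow rate: ΔP(s) = cumulative resistance up to s times Q, at every
#' element boundary. Evaluated at the peak cardiac-driven flow this is the
#' along-length pressure-gradient curve.
#'
#' @param profile A [resistance_profile()].
#' @param flow Flow rate Q, mm³/s (>= 0).
#' @param endpoint_index Optionally stop at this element (e.g. the 95%
#'   endpoint); default uses all elements.
#' @return A data frame of class `pressure_gradient_curve` with columns `s`
#'   (arc length at element boundaries, mm) and `dp` (cumulative ΔP, Pa).
#' @export
pressure_gradient_curve <- function(profile, flow, endpoint_index = NULL) {
  stopifnot(inherits(profile, "resistance_profile"))
  if (!is.numeric(flow) || length(flow) != 1L || flow < 0)
    stop("`flow` must be a single non-negative flow rate (mm³/s)")
  el <- profile$elements
  n <- if (is.null(endpoint_index)) nrow(el)
  else min(as.integer(endpoint_index), nrow(el))
  s <- cumsum(el$length[seq_len(n)])
  dp <- pressure_difference(profile$cumulative_r[seq_len(n)], flow)
  out <- data.frame(s = c(0, s), dp = c(0, dp))
  class(out) <- c("pressure_gradient_curve", "data.frame")
  out
}
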