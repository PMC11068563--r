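#' Exponential smoothing of a fluorescence trace
#'
#' First-order exponential smoothing with damping factor `d` (the weight on
#' the previous smoothed value, spreadsheet "damping factor" convention):
#' \deqn{s_1 = x_1, \qquad s_t = (1 - d)\,x_t + d\,s_{t-1}.}
#' With `d = 0` the trace is returned unchanged; a constant trace is a
#' fixed point; the output range is always contained in the input range.
#'
#' @param fluorescence raw trace values.
#' @param damping damping factor in `[0, 1)` (default 0.93, the standard
#'   setting for GCaMP6f uptake traces).
#' @return Smoothed trace, same length.
#' @export
smooth_exponential <- function(fluorescence, damping = 0.93) {
  if (!is.finite(damping) || damping < 0 || damping >= 1)
    stop("damping must lie in [0, 1)")
  if (any(!is.finite(fluorescence))) stop("fluorescence must be finite")
  if (length(fluorescence) == 0) return(fluorescence)
  as.numeric(stats::filter((1 - damping) * fluorescence, damping,
                           method = "recursive", init = fluorescence[1]))
}

#' Normalize a calcium trace as F over F_min
#'
#' Divides every point by the minimum fluorescence observed *before* the
#' stimulus (histamine perfusion), the standard F/F_min presentation for
#' matrix-targeted GCaMP6f uptake experiments.
#'
#' @param time_s time grid, strictly increasing, s.
#' @param fluorescence raw (or smoothed) trace.
#' @param stim_time_s perfusion-switch time, s; must lie inside the trace
#'   with at least two points before it.
#' @return List with `trace` (data frame `time_s`, `f_over_fmin`) and
#'   `f_min`.
#' @export
normalize_f_over_fmin <- function(time_s, fluorescence, stim_time_s) {
  check_trace(time_s, fluorescence, stim_time_s)
  pre <- time_s < stim_time_s
  if (sum(pre) < 2) stop("need at least 2 pre-stimulus points")
  f_min <- min(fluorescence[pre])
  if (f_min <= 0) stop("pre-stimulus minimum must be positive")
  list(trace = data.frame(time_s = time_s,
                          f_over_fmin = fluorescence / f_min),
       f_min = f_min)
}

check_trace <- function(time_s, fluorescence, stim_time_s) {
  if (length(time_s) != length(fluorescence))
    stop("time_s and fluorescence must have equal length")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (any(!is.finite(fluorescence))) stop("fluorescence must be finite")
  if (stim_time_s <= min(time_s) || stim_time_s > max(time_s))
    stop("stim_time_s must lie within the trace")
  invisible(TRUE)
}

#' Stimulus-response amplitude of a normalized calcium trace
#'
#' The response amplitude is the maximum post-stimulus F/F_min minus the
#' mean pre-stimulus baseline.  Because the trace is normalized first, the
#' amplitude is invariant to any positive gain on the raw fluorescence.
#'
#' @param time_s time grid, s.
#' @param f_over_fmin normalized trace (see [normalize_f_over_fmin()]).
#' @param stim_time_s perfusion-switch time, s.
#' @return Amplitude `max(post) - mean(pre)` in F/F_min units.
#' @examples
#' tr <- sim_ca_trace(amplitude = 0.5, noise = 0)
#' nz <- normalize_f_over_fmin(tr$time_s, tr$fluorescence, tr$stim_time_s)
#' histamine_response_amplitude(nz$trace$time_s, nz$trace$f_over_fmin, 60)
#' @export
histamine_response_amplitude <- function(time_s, f_over_fmin, stim_time_s) {
  check_trace(time_s, f_over_fmin, stim_time_s)
  pre <- time_s < stim_time_s
  post <- time_s >= stim_time_s
  if (!any(pre) || !any(post)) stop("empty pre- or post-stimulus segment")
  max(f_over_fmin[post]) - mean(f_over_fmin[pre])
}
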