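#' Construct a fluorescence trace
#'
#' Container for one astrocyte soma's raw fluorescence time series, as
#' exported from imaging software: arbitrary-unit intensities at a fixed
#' frame period (1 s frames over a 5 min recording in the reference
#' protocol), together with the scalar background fluorescence to subtract.
#'
#' @param values Numeric vector of raw fluorescence intensities (AU).
#' @param frame_period_s Frame period in seconds (default 1, i.e. 1 Hz).
#' @param cell_id Identifier for the cell (character or integer).
#' @param background Scalar background fluorescence (AU) subtracted before
#'   computing delta-F/F0.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, frame_period_s = 1, cell_id = "cell_1",
                        background = 0) {
  values <- as.numeric(values)
  if (length(values) < 30L)
    stop("a fluorescence trace needs at least 30 frames")
  if (!all(is.finite(values)))
    stop("fluorescence values must be finite")
  if (!is.numeric(frame_period_s) || frame_period_s <= 0)
    stop("frame_period_s must be positive")
  structure(
    list(cell_id = cell_id, frame_period_s = frame_period_s,
         values = values, background = background),
    class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> cell %s: %d frames @ %.3g s/frame, background %.3g AU\n",
              x$cell_id, length(x$values), x$frame_period_s, x$background))
  invisible(x)
}

#' Construct a sweep recording
#'
#' Uniformly sampled current- or voltage-sweep container used by the
#' synaptic-current and field-potential analyses. Values are pA for
#' voltage-clamp current sweeps and mV for field sweeps.
#'
#' @param values Numeric vector of samples.
#' @param sample_rate_hz Sampling rate in Hz (acquisition in the reference
#'   protocol was 4 kHz for whole-cell sweeps).
#' @param stim_times_ms Numeric vector of stimulus times, ms from sweep start.
#' @param holding_mv Holding potential in mV, or `NA` if not applicable.
#' @param modality One of `"current"` (pA) or `"field"` (mV).
#' @return An object of class `sweep_recording`.
#' @export
sweep_recording <- function(values, sample_rate_hz = 4000,
                            stim_times_ms = numeric(), holding_mv = NA_real_,
                            modality = c("current", "field")) {
  modality <- match.arg(modality)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sweep")
  dur_ms <- 1000 * length(values) / sample_rate_hz
  if (length(stim_times_ms) && any(stim_times_ms < 0 | stim_times_ms >= dur_ms))
    stop("stimulus times must fall inside the sweep")
  structure(
    list(sample_rate_hz = sample_rate_hz, values = values,
         stim_times_ms = as.numeric(stim_times_ms), holding_mv = holding_mv,
         modality = modality),
    class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %s sweep: %.3g s @ %g Hz, %d stimulus time(s)\n",
              x$modality, length(x$values) / x$sample_rate_hz,
              x$sample_rate_hz, length(x$stim_times_ms)))
  invisible(x)
}

#' Construct an LFP recording
#'
#' @param values Numeric vector, mV.
#' @param sample_rate_hz Sampling rate (default 1000 Hz).
#' @param injection_time_s Time of the convulsant injection marker in
#'   seconds, or `NA` when no marker exists (latency is then undefined).
#' @param filter_band Length-2 numeric, the band-pass edges in Hz associated
#'   with the recording (default `c(0.1, 100)`).
#' @param filtered Logical, whether `filter_band` has been applied.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(values, sample_rate_hz = 1000,
                          injection_time_s = NA_real_,
                          filter_band = c(0.1, 100), filtered = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty recording")
  if (length(filter_band) != 2L || filter_band[1] <= 0 ||
      filter_band[1] >= filter_band[2] || filter_band[2] >= sample_rate_hz / 2)
    stop("filter_band must satisfy 0 < low < high < Nyquist")
  structure(
    list(sample_rate_hz = sample_rate_hz, values = values,
         injection_time_s = injection_time_s, filter_band = filter_band,
         filtered = filtered),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %.4g s @ %g Hz%s%s\n",
              length(x$values) / x$sample_rate_hz, x$sample_rate_hz,
              if (x$filtered) sprintf(", band-passed %g-%g Hz", x$filter_band[1],
                                      x$filter_band[2]) else "",
              if (is.na(x$injection_time_s)) "" else
                sprintf(", injection at %g s", x$injection_time_s)))
  invisible(x)
}

# shared robust noise-SD estimate (median absolute deviation, normal-consistent)
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
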