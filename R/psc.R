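# Spontaneous and evoked postsynaptic-current metrics.

# indices of a sweep falling in [t0_ms, t1_ms)
win_idx <- function(sweep, t0_ms, t1_ms) {
  dt <- 1000 / sweep$sample_rate_hz
  i0 <- max(1L, floor(t0_ms / dt) + 1L)
  i1 <- min(length(sweep$values), ceiling(t1_ms / dt))
  if (i1 < i0) integer() else i0:i1
}

smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  na <- is.na(y)
  y[na] <- x[na]
  y
}

#' Detect spontaneous postsynaptic currents
#'
#' Events are local extrema of the polarity-rectified, baseline-subtracted
#' (median) signal exceeding an amplitude threshold, separated by at least
#' `min_interval_ms`. The default threshold is 3 times the robust noise SD
#' (median absolute deviation), computed on the rectified signal.
#'
#' @param sweep A [sweep_recording()] in pA.
#' @param polarity `"inward"` (negative events, e.g. EPSCs) or `"outward"`.
#' @param threshold_pa Detection threshold in pA; default `NULL` uses
#'   3 x robust SD.
#' @param min_interval_ms Minimum separation between events.
#' @param smooth_ms Running-mean smoothing applied before peak finding.
#' @return List of class `psc_events`: `events` (data.frame `time_ms`,
#'   `amplitude_pa`), `frequency_hz` (count / sweep duration),
#'   `mean_amplitude_pa`, `threshold_pa`.
#' @export
detect_spontaneous <- function(sweep, polarity = c("inward", "outward"),
                               threshold_pa = NULL, min_interval_ms = 10,
                               smooth_ms = 0.75) {
  polarity <- match.arg(polarity)
  x <- sweep$values
  if (!length(x)) stop("zero-length sweep")
  sgn <- if (polarity == "inward") -1 else 1
  r <- sgn * (x - stats::median(x))
  if (is.null(threshold_pa)) threshold_pa <- 3 * robust_sd(r)
  if (threshold_pa <= 0) stop("threshold_pa must be positive")
  dt_ms <- 1000 / sweep$sample_rate_hz
  k <- max(1L, round(smooth_ms / dt_ms))
  rs <- smooth_ma(r, k)
  n <- length(rs)
  cand <- which(rs >= threshold_pa)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[rs[cand] >= rs[cand - 1L] & rs[cand] >= rs[cand + 1L]]
  # shape confirmation: the rectified signal must dwell above half the
  # threshold for >= min_dwell_ms around the peak, which rejects isolated
  # noise excursions that a bare amplitude threshold would accept
  min_dwell_ms <- 2
  half <- rs >= threshold_pa / 2
  hr <- rle(half)
  run_len_ms <- rep(hr$lengths * dt_ms, hr$lengths)
  run_ok <- rep(hr$values, hr$lengths) & run_len_ms >= min_dwell_ms
  cand <- cand[run_ok[cand]]
  # derivative confirmation: a peak must re-rise by at least the threshold
  # from the minimum since the previous accepted peak, so noise wiggles on
  # a slow decay tail are not counted as new events
  conf <- integer()
  last <- 1L
  for (i in cand) {
    trough <- min(rs[last:i])
    if (rs[i] - trough >= threshold_pa) {
      conf <- c(conf, i)
      last <- i
    }
  }
  # greedy merge of peaks closer than min_interval, keeping the larger
  keep <- integer()
  for (i in conf) {
    if (length(keep) && (i - keep[length(keep)]) * dt_ms < min_interval_ms) {
      if (rs[i] > rs[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # amplitude from the raw rectified trace near the smoothed peak, so
  # smoothing does not bias baseline-to-peak amplitudes low
  amp <- vapply(keep, function(i)
    max(r[max(1L, i - 2L):min(n, i + 2L)]), numeric(1))
  ev <- data.frame(time_ms = (keep - 1L) * dt_ms, amplitude_pa = amp)
  dur_s <- n / sweep$sample_rate_hz
  structure(list(events = ev, frequency_hz = nrow(ev) / dur_s,
                 mean_amplitude_pa = if (nrow(ev)) mean(ev$amplitude_pa) else NA_real_,
                 threshold_pa = threshold_pa),
            class = "psc_events")
}

#' @export
print.psc_events <- function(x, ...) {
  cat(sprintf("<psc_events> %d event(s), frequency %.3g Hz, mean amplitude %.3g pA\n",
              nrow(x$events), x$frequency_hz, x$mean_amplitude_pa))
  invisible(x)
}

# single-exponential extrapolation of the response-1 decay tail; returns a
# function of time (ms) giving the predicted rectified amplitude
fit_decay <- function(t_ms, y) {
  pos <- y > max(y, 0) * 0.02 & y > 0
  if (sum(pos) < 5L) return(function(t) rep(0, length(t)))
  ft <- stats::lm(log(y[pos]) ~ t_ms[pos])
  a <- ft$coefficients[[1]]; b <- ft$coefficients[[2]]
  if (b >= 0) return(function(t) rep(0, length(t)))  # not decaying
  function(t) exp(a + b * t)
}

#' Paired-pulse ratio of evoked responses
#'
#' PPR is the ratio of the second response amplitude to the first
#' (baseline-to-peak within a post-stimulus window). With
#' `decay_correction` (default, appropriate at 100 ms inter-stimulus
#' intervals) the second amplitude is measured relative to the
#' extrapolated single-exponential decay of the first response fitted on
#' the inter-stimulus tail.
#'
#' @param sweep A [sweep_recording()] with (or overridden by) exactly two
#'   stimulus times.
#' @param stim_times_ms Optional override of the sweep's stimulus times.
#' @param decay_correction Logical.
#' @param window_ms Post-stimulus search window, ms (default 2-50).
#' @param baseline_ms Pre-stimulus baseline span, ms.
#' @return The ratio A2/A1 with attributes `a1_pa` and `a2_pa`.
#' @export
paired_pulse_ratio <- function(sweep, stim_times_ms = sweep$stim_times_ms,
                               decay_correction = TRUE,
                               window_ms = c(2, 50), baseline_ms = 10) {
  if (length(stim_times_ms) != 2L) stop("exactly two stimulus times required")
  s1 <- stim_times_ms[1]; s2 <- stim_times_ms[2]
  if (s2 <= s1) stop("stimulus times must be increasing")
  dt_ms <- 1000 / sweep$sample_rate_hz
  bl_idx <- win_idx(sweep, max(0, s1 - baseline_ms), s1)
  bl <- mean(sweep$values[bl_idx])
  noise <- robust_sd(sweep$values[bl_idx])
  w1 <- win_idx(sweep, s1 + window_ms[1], min(s1 + window_ms[2], s2))
  y1 <- sweep$values[w1] - bl
  sgn <- if (abs(min(y1)) >= abs(max(y1))) -1 else 1
  a1 <- max(sgn * y1)
  if ((noise > 0 && a1 <= 5 * noise) || a1 <= 0)
    stop("first response below the noise floor: PPR undefined")
  w2 <- win_idx(sweep, s2 + window_ms[1], s2 + window_ms[2])
  y2 <- sgn * (sweep$values[w2] - bl)
  if (decay_correction) {
    p1 <- w1[which.max(sgn * y1)]
    tail_idx <- win_idx(sweep, (p1 - 1) * dt_ms + 2, s2)
    pred <- fit_decay((tail_idx - 1L) * dt_ms,
                      sgn * (sweep$values[tail_idx] - bl))
    y2 <- y2 - pred((w2 - 1L) * dt_ms)
  }
  a2 <- max(y2)
  structure(a2 / a1, a1_pa = a1, a2_pa = a2)
}

#' Excitatory/inhibitory balance of a compound postsynaptic current
#'
#' For a compound PSC recorded at an intermediate holding potential
#' (-40 mV), the excitatory component is the inward (negative) phase --
#' peak = |minimum|, area = |integral of the negative lobe| -- and the
#' inhibitory component is the outward (positive) phase. Peak and area
#' E/I ratios are both reported (trapezoidal areas, pA*ms). Lobe
#' boundaries are the zero crossings of the baseline-subtracted trace
#' after a stimulus-artifact blanking window.
#'
#' @param sweep A [sweep_recording()] with one stimulus time.
#' @param blank_ms Artifact blanking after the stimulus (default 2 ms).
#' @param baseline_ms Pre-stimulus baseline span.
#' @param window_ms Post-stimulus analysis span; `NULL` (default) uses
#'   the whole sweep after the blanking window.
#' @return List of class `ei_result`: `exc_peak_pa`, `inh_peak_pa`,
#'   `exc_area`, `inh_area`, `ei_peak_ratio`, `ei_area_ratio`. When no
#'   outward phase exceeds the noise floor the inhibitory magnitudes are 0
#'   and the ratios are `NA` (never infinite).
#' @export
compound_ei <- function(sweep, blank_ms = 2, baseline_ms = 10,
                        window_ms = NULL) {
  if (length(sweep$stim_times_ms) != 1L) stop("exactly one stimulus time required")
  stim <- sweep$stim_times_ms[1]
  dt_ms <- 1000 / sweep$sample_rate_hz
  if (is.null(window_ms))
    window_ms <- length(sweep$values) * dt_ms - stim
  bl_idx <- win_idx(sweep, max(0, stim - baseline_ms), stim)
  bl <- mean(sweep$values[bl_idx])
  noise <- robust_sd(sweep$values[bl_idx])
  idx <- win_idx(sweep, stim + blank_ms, stim + window_ms)
  y <- sweep$values[idx] - bl
  neg <- pmax(-y, 0); pos <- pmax(y, 0)
  trapz <- function(v) dt_ms * (sum(v) - (v[1] + v[length(v)]) / 2)
  exc_peak <- max(neg); inh_peak <- max(pos)
  exc_area <- trapz(neg); inh_area <- trapz(pos)
  floor_pa <- 3 * noise
  if (inh_peak <= floor_pa) { inh_peak <- 0; inh_area <- 0 }
  if (exc_peak <= floor_pa) { exc_peak <- 0; exc_area <- 0 }
  structure(list(
    exc_peak_pa = exc_peak, inh_peak_pa = inh_peak,
    exc_area = exc_area, inh_area = inh_area,
    ei_peak_ratio = if (inh_peak > 0) exc_peak / inh_peak else NA_real_,
    ei_area_ratio = if (inh_area > 0) exc_area / inh_area else NA_real_),
    class = "ei_result")
}

#' @export
print.ei_result <- function(x, ...) {
  cat(sprintf(paste0("<ei_result> exc peak %.4g pA (area %.4g pA*ms), ",
                     "inh peak %.4g pA (area %.4g pA*ms)\n",
                     "  E/I peak ratio %.4g, area ratio %.4g\n"),
              x$exc_peak_pa, x$exc_area, x$inh_peak_pa, x$inh_area,
              x$ei_peak_ratio, x$ei_area_ratio))
  invisible(x)
}
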