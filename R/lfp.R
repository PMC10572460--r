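# LFP analysis: multitaper spectra, band power, interictal spikes,
# after-discharge detection.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal Slepian eigenproblem
#' (diagonal `((n-1-2t)/2)^2 cos(2 pi W)`, off-diagonal `t (n-t)/2`),
#' whose eigenvectors are the DPSS in index order. For long windows
#' (n > 1024) the tapers are computed at n = 1024, interpolated with
#' cubic splines and re-orthonormalised -- the standard large-n
#' construction. Tapers are unit-energy, sign-fixed (non-negative mean for
#' even orders, positive initial lobe for odd), and cached per
#' `(n, nw, k)`.
#'
#' @param n Window length, samples.
#' @param nw Time-bandwidth product (default 5).
#' @param k Number of tapers (default 9 = 2*nw - 1).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 5, k = 2 * nw - 1) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  base_n <- min(n, 1024L)
  w <- nw / base_n
  t0 <- 0:(base_n - 1)
  diag_el <- ((base_n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off <- (1:(base_n - 1)) * (base_n - 1:(base_n - 1)) / 2
  m <- diag(diag_el)
  m[cbind(1:(base_n - 1), 2:base_n)] <- off
  m[cbind(2:base_n, 1:(base_n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n > base_n) {
    # spline-interpolate to length n on the unit interval, re-orthonormalise
    u0 <- (t0 + 0.5) / base_n
    u1 <- (0:(n - 1) + 0.5) / n
    v <- apply(v, 2, function(col) stats::spline(u0, col, xout = u1)$y)
    v <- qr.Q(qr(v))
  }
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    flip <- if (j %% 2 == 1) sum(v[, j]) < 0 else
      sum(v[seq_len(ceiling(nrow(v) / 2)), j]) < 0
    if (flip) v[, j] <- -v[, j]
  }
  assign(key, v, envir = .dpss_cache)
  v
}

#' Multitaper power spectral density of an LFP recording
#'
#' The recording is divided into overlapping segments (defaults: 4000 ms
#' segments, 500 ms overlap); each demeaned segment is tapered with `k`
#' DPSS tapers at time-bandwidth product `nw` (defaults 9 tapers, nw = 5),
#' taper spectra are averaged within segments and segment spectra across
#' the recording. Power is one-sided density in mV^2/Hz; the frequency
#' spacing is the reciprocal of the segment duration.
#'
#' @param rec An [lfp_recording()].
#' @param segment_ms,overlap_ms Segmenting parameters, ms.
#' @param time_bandwidth Time-bandwidth product.
#' @param n_tapers Number of tapers; more than `2*time_bandwidth - 1`
#'   degrades taper concentration and triggers a warning (not an error).
#' @return List of class `mt_psd`: `freq` (Hz), `power` (averaged),
#'   `segments` (matrix, one column per segment), `params`.
#' @export
multitaper_psd <- function(rec, segment_ms = 4000, overlap_ms = 500,
                           time_bandwidth = 5, n_tapers = 9) {
  fs <- rec$sample_rate_hz
  nseg <- round(segment_ms / 1000 * fs)
  step <- round((segment_ms - overlap_ms) / 1000 * fs)
  if (length(rec$values) < nseg)
    stop("recording shorter than one segment")
  if (n_tapers > 2 * time_bandwidth - 1)
    warning("n_tapers > 2*time_bandwidth - 1: taper concentration degraded")
  tapers <- dpss_tapers(nseg, time_bandwidth, n_tapers)
  starts <- seq(1L, length(rec$values) - nseg + 1L, by = step)
  nf <- nseg %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nseg
  segs <- vapply(starts, function(s) {
    x <- rec$values[s:(s + nseg - 1L)]
    x <- x - mean(x)
    p <- rowMeans(vapply(seq_len(n_tapers), function(j) {
      sp <- abs(stats::fft(x * tapers[, j]))^2 / fs
      sp[seq_len(nf)]
    }, numeric(nf)))
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2L == 0L) dbl[nf] <- 1
    p * dbl
  }, numeric(nf))
  segs <- matrix(segs, nrow = nf)
  structure(list(freq = freq, power = rowMeans(segs), segments = segs,
                 params = list(segment_ms = segment_ms, overlap_ms = overlap_ms,
                               time_bandwidth = time_bandwidth,
                               n_tapers = n_tapers, sample_rate_hz = fs)),
            class = "mt_psd")
}

#' @export
print.mt_psd <- function(x, ...) {
  cat(sprintf("<mt_psd> %d frequencies (0-%.4g Hz, df = %.4g), %d segment(s), nw = %g, %d tapers\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1],
              ncol(x$segments), x$params$time_bandwidth, x$params$n_tapers))
  invisible(x)
}

#' @param x An `mt_psd` object.
#' @param ... Passed to [plot()].
#' @rdname multitaper_psd
#' @export
plot.mt_psd <- function(x, ...) {
  plot(x$freq[-1], x$power[-1], type = "l", log = "xy",
       xlab = "frequency (Hz)", ylab = "PSD (mV²/Hz)", ...)
  invisible(x)
}

#' Integrated band power of a PSD
#'
#' Sums the power density over the half-open band `[lo_hz, hi_hz)` times
#' the frequency spacing, so adjacent bands add exactly:
#' `band_power(p, 1, 3) + band_power(p, 3, 50) == band_power(p, 1, 50)`.
#'
#' @param psd An `mt_psd` object.
#' @param lo_hz,hi_hz Band edges, Hz (`lo < hi`, inside the grid). The
#'   default 1-3 Hz band is the low-frequency band in which ictal power
#'   concentrates.
#' @return Power (mV^2) in the band.
#' @export
band_power <- function(psd, lo_hz = 1, hi_hz = 3) {
  if (lo_hz >= hi_hz) stop("band edges inverted: need lo_hz < hi_hz")
  if (lo_hz < 0 || hi_hz > max(psd$freq) + diff(psd$freq[1:2]))
    stop("band outside the frequency grid")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo_hz & psd$freq < hi_hz
  sum(psd$power[sel]) * df
}

#' Zero-phase band-pass filter an LFP recording
#'
#' Butterworth band-pass (order 2) applied forward and backward
#' (`signal::filtfilt`) so event times acquire no filter latency. Default
#' band 0.1-100 Hz, the reference preprocessing band.
#'
#' @param rec An [lfp_recording()].
#' @param band Length-2 band edges, Hz.
#' @param order Butterworth order.
#' @return The filtered [lfp_recording()] with `filtered = TRUE`.
#' @export
lfp_bandpass <- function(rec, band = c(0.1, 100), order = 2) {
  ny <- rec$sample_rate_hz / 2
  bf <- signal::butter(order, band / ny, type = "pass")
  out <- rec
  out$values <- as.numeric(signal::filtfilt(bf, rec$values))
  out$filter_band <- band
  out$filtered <- TRUE
  out
}

#' Detect interictal spikes
#'
#' Transient high-amplitude deflections whose half-amplitude width falls
#' within `width_bounds_ms` (default 20-70 ms, the defining range for
#' interictal deflections and poly-spike complexes).
#'
#' @param rec An [lfp_recording()].
#' @param amp_threshold_sd Amplitude threshold in robust (MAD) SDs of the
#'   recording.
#' @param width_bounds_ms Length-2 accepted half-amplitude width range.
#' @param merge_gap_ms Above-threshold runs separated by less than this
#'   are treated as one deflection (poly-spike complexes stay one event).
#' @return Data frame: `time_s` (peak), `amplitude_mv`, `width_ms`.
#' @export
detect_interictal_spikes <- function(rec, amp_threshold_sd = 5,
                                     width_bounds_ms = c(20, 70),
                                     merge_gap_ms = 20) {
  if (amp_threshold_sd <= 0) stop("amp_threshold_sd must be positive")
  x <- rec$values
  fs <- rec$sample_rate_hz
  thr <- amp_threshold_sd * robust_sd(x)
  above <- abs(x) > thr
  if (!any(above))
    return(data.frame(time_s = numeric(), amplitude_mv = numeric(),
                      width_ms = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  # merge runs split by brief sub-threshold dips within one deflection
  gap <- round(merge_gap_ms / 1000 * fs)
  ms <- starts[1]; me <- ends[1]
  mstart <- integer(); mend <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me <= gap) me <- ends[i]
    else { mstart <- c(mstart, ms); mend <- c(mend, me)
           ms <- starts[i]; me <- ends[i] }
  }
  mstart <- c(mstart, ms); mend <- c(mend, me)
  out <- list()
  for (i in seq_along(mstart)) {
    seg <- mstart[i]:mend[i]
    pk <- seg[which.max(abs(x[seg]))]
    half <- abs(x[pk]) / 2
    l <- pk; while (l > 1L && abs(x[l - 1L]) >= half) l <- l - 1L
    rgt <- pk; while (rgt < length(x) && abs(x[rgt + 1L]) >= half) rgt <- rgt + 1L
    width_ms <- (rgt - l + 1L) / fs * 1000
    if (width_ms >= width_bounds_ms[1] && width_ms <= width_bounds_ms[2])
      out[[length(out) + 1L]] <- data.frame(
        time_s = (pk - 1L) / fs, amplitude_mv = abs(x[pk]),
        width_ms = width_ms)
  }
  if (!length(out))
    return(data.frame(time_s = numeric(), amplitude_mv = numeric(),
                      width_ms = numeric()))
  do.call(rbind, out)
}

#' Detect after-discharges and summarise ictal activity
#'
#' After-discharges (ADs) are intervals where the smoothed RMS envelope of
#' the recording exceeds a threshold (in robust SDs of the signal) for at
#' least `min_duration_s`. The detector automates what is traditionally a
#' manual call; every threshold is exposed. The summary reports incidence
#' per minute, latency of the first AD from the injection marker (missing
#' when the recording has none), per-AD durations, and -- when the
#' recording admits at least one spectral segment -- the 1-3 Hz band
#' power from the multitaper PSD.
#'
#' @param rec An [lfp_recording()].
#' @param envelope_threshold_sd Envelope threshold in robust SDs.
#' @param min_duration_s Minimum AD duration, seconds (default 2;
#'   ictal episodes last several seconds, which rejects brief background
#'   envelope excursions).
#' @param smooth_s RMS smoothing window, seconds (default 0.25).
#' @param merge_gap_s Supra-threshold stretches separated by less than
#'   this are merged into one AD before the duration filter.
#' @return List of class `ad_summary`: `ad_intervals` (data.frame
#'   `start_s`, `end_s`), `incidence_per_min`, `latency_s`, `durations_s`,
#'   `band_power_1_3`.
#' @export
detect_afterdischarges <- function(rec, envelope_threshold_sd = 2,
                                   min_duration_s = 2, smooth_s = 0.25,
                                   merge_gap_s = 1) {
  if (envelope_threshold_sd <= 0 || min_duration_s <= 0)
    stop("thresholds must be positive")
  x <- rec$values
  fs <- rec$sample_rate_hz
  k <- max(1L, round(smooth_s * fs))
  env <- sqrt(smooth_ma(x^2, k))
  thr <- envelope_threshold_sd * robust_sd(x)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  iv <- data.frame(start_s = numeric(), end_s = numeric())
  if (length(starts)) {
    # merge supra-threshold stretches separated by brief lulls: one
    # spike-wave episode with a momentary envelope dip is one AD
    gap <- round(merge_gap_s * fs)
    ms <- starts[1]; me <- ends[1]
    mstart <- integer(); mend <- integer()
    for (i in seq_along(starts)[-1]) {
      if (starts[i] - me <= gap) me <- ends[i]
      else { mstart <- c(mstart, ms); mend <- c(mend, me)
             ms <- starts[i]; me <- ends[i] }
    }
    mstart <- c(mstart, ms); mend <- c(mend, me)
    dur <- (mend - mstart + 1L) / fs
    keep <- dur >= min_duration_s
    iv <- data.frame(start_s = (mstart[keep] - 1L) / fs,
                     end_s = mend[keep] / fs)
  }
  minutes <- length(x) / fs / 60
  durations <- iv$end_s - iv$start_s
  latency <- if (nrow(iv) && !is.na(rec$injection_time_s))
    iv$start_s[1] - rec$injection_time_s else NA_real_
  bp <- tryCatch(band_power(multitaper_psd(rec), 1, 3),
                 error = function(e) NA_real_)
  structure(list(ad_intervals = iv, incidence_per_min = nrow(iv) / minutes,
                 latency_s = latency, durations_s = durations,
                 band_power_1_3 = bp),
            class = "ad_summary")
}

#' @export
print.ad_summary <- function(x, ...) {
  cat(sprintf("<ad_summary> %d AD(s), incidence %.3g/min, latency %s s, mean duration %s s\n",
              nrow(x$ad_intervals), x$incidence_per_min,
              format(x$latency_s, digits = 3),
              if (length(x$durations_s)) format(mean(x$durations_s), digits = 3) else "NA"))
  invisible(x)
}
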