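# Synthetic local field potential recordings.

#' Configuration for the LFP generator
#'
#' @param duration_s Recording length, seconds.
#' @param sample_rate_hz Sampling rate (default 1000 Hz, the reference
#'   analysis rate).
#' @param background_psd `"pink"` (1/f, resembling cortical LFP) or
#'   `"white"`.
#' @param background_sd_mv Background noise SD, mV.
#' @param ad_schedule Data frame of after-discharges to inject:
#'   `start_s, duration_s, dominant_freq_hz, amplitude_mv`. ADs may not
#'   overlap.
#' @param spike_schedule Data frame of interictal spikes:
#'   `time_s, width_ms, amplitude_mv`; widths must lie in 20-70 ms (the
#'   defining range for interictal deflections).
#' @param injection_time_s Convulsant-injection marker, seconds, or `NA`.
#' @param seed Integer RNG seed.
#' @return An object of class `lfp_sim_config`.
#' @export
lfp_sim_config <- function(duration_s = 120, sample_rate_hz = 1000,
                           background_psd = c("pink", "white"),
                           background_sd_mv = 0.05,
                           ad_schedule = NULL, spike_schedule = NULL,
                           injection_time_s = NA_real_, seed = 1) {
  background_psd <- match.arg(background_psd)
  empty_ad <- data.frame(start_s = numeric(), duration_s = numeric(),
                         dominant_freq_hz = numeric(), amplitude_mv = numeric())
  empty_sp <- data.frame(time_s = numeric(), width_ms = numeric(),
                         amplitude_mv = numeric())
  if (is.null(ad_schedule)) ad_schedule <- empty_ad
  if (is.null(spike_schedule)) spike_schedule <- empty_sp
  if (nrow(ad_schedule)) {
    ends <- ad_schedule$start_s + ad_schedule$duration_s
    if (any(ad_schedule$start_s < 0) || any(ends > duration_s))
      stop("scheduled ADs must fall inside [0, duration_s]")
    o <- order(ad_schedule$start_s)
    if (any(ad_schedule$start_s[o][-1] < ends[o][-length(ends)]))
      stop("scheduled ADs overlap")
  }
  if (nrow(spike_schedule)) {
    if (any(spike_schedule$time_s < 0 | spike_schedule$time_s > duration_s))
      stop("scheduled spikes must fall inside [0, duration_s]")
    if (any(spike_schedule$width_ms < 20 | spike_schedule$width_ms > 70))
      stop("interictal spike widths must lie in 20-70 ms")
  }
  structure(list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    background_psd = background_psd, background_sd_mv = background_sd_mv,
    ad_schedule = ad_schedule, spike_schedule = spike_schedule,
    injection_time_s = injection_time_s, seed = seed),
    class = "lfp_sim_config")
}

# 1/f-shaped Gaussian noise via FFT spectral shaping, normalised to unit SD
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-3, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f)           # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic LFP recording with ground truth
#'
#' Background noise (pink by default) plus scheduled after-discharges --
#' amplitude-modulated oscillations at their dominant frequency under a
#' Hann envelope -- and interictal spikes (Gaussian deflections whose
#' full-width at half maximum equals the scheduled width).
#'
#' @param cfg An [lfp_sim_config()].
#' @return List with `recording` ([lfp_recording()]) and `ground_truth`
#'   (list with `ads` and `spikes` data frames mirroring the schedules).
#' @export
gen_lfp <- function(cfg) {
  stopifnot(inherits(cfg, "lfp_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate_hz
    n <- round(cfg$duration_s * fs)
    x <- if (cfg$background_psd == "pink") pink_noise(n) else stats::rnorm(n)
    x <- x * cfg$background_sd_mv
    t_s <- (seq_len(n) - 1L) / fs
    if (nrow(cfg$ad_schedule)) for (i in seq_len(nrow(cfg$ad_schedule))) {
      a <- cfg$ad_schedule[i, ]
      idx <- which(t_s >= a$start_s & t_s < a$start_s + a$duration_s)
      ph <- stats::runif(1, 0, 2 * pi)
      # Tukey envelope (5% cosine taper each side): near-full amplitude
      # over most of the scheduled span, so detected durations track the
      # schedule closely
      u <- (seq_along(idx) - 1) / (length(idx) - 1)
      env <- rep(1, length(idx))
      tp <- 0.05
      lo <- u < tp; hi <- u > 1 - tp
      env[lo] <- 0.5 * (1 - cos(pi * u[lo] / tp))
      env[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / tp))
      x[idx] <- x[idx] + a$amplitude_mv * env *
        sin(2 * pi * a$dominant_freq_hz * t_s[idx] + ph)
    }
    if (nrow(cfg$spike_schedule)) for (i in seq_len(nrow(cfg$spike_schedule))) {
      s <- cfg$spike_schedule[i, ]
      sigma_s <- (s$width_ms / 1000) / (2 * sqrt(2 * log(2)))  # FWHM -> sd
      idx <- which(abs(t_s - s$time_s) < 5 * sigma_s)
      x[idx] <- x[idx] + s$amplitude_mv *
        exp(-(t_s[idx] - s$time_s)^2 / (2 * sigma_s^2))
    }
    list(recording = lfp_recording(x, fs, cfg$injection_time_s),
         ground_truth = list(ads = cfg$ad_schedule,
                             spikes = cfg$spike_schedule))
  })
}
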