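# Synthetic synaptic-current and field-potential sweeps.

# biexponential kernel normalised to unit peak; t in ms
biexp_kernel <- function(t, rise_tau_ms, decay_tau_ms) {
  stopifnot(rise_tau_ms < decay_tau_ms)
  tpk <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  pk <- exp(-tpk / decay_tau_ms) - exp(-tpk / rise_tau_ms)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau_ms) - exp(-t[pos] / rise_tau_ms)) / pk
  out
}

# area (ms) under a unit-peak biexponential
biexp_unit_area <- function(rise_tau_ms, decay_tau_ms) {
  tpk <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  pk <- exp(-tpk / decay_tau_ms) - exp(-tpk / rise_tau_ms)
  (decay_tau_ms - rise_tau_ms) / pk
}

# decay tau giving a requested unit-peak area at fixed rise tau
solve_decay_tau <- function(unit_area_ms, rise_tau_ms) {
  f <- function(td) biexp_unit_area(rise_tau_ms, td) - unit_area_ms
  if (f(rise_tau_ms * 1.001) > 0)
    stop("requested area/peak ratio too small for rise_tau = ", rise_tau_ms, " ms")
  stats::uniroot(f, c(rise_tau_ms * 1.001, 5000), tol = 1e-10)$root
}

#' Configuration for the spontaneous-PSC sweep generator
#'
#' @param sweep_duration_s Sweep length, seconds.
#' @param sample_rate_hz Sampling rate (default 4000 Hz, the reference
#'   acquisition rate).
#' @param event_rate_hz Poisson rate of spontaneous events.
#' @param amp_dist Length-2 `(mean, sd)` of event amplitudes, pA;
#'   log-normal, so draws are strictly positive.
#' @param rise_tau_ms,decay_tau_ms Biexponential kernel time constants.
#' @param polarity `"inward"` (negative-going, EPSC at negative holding) or
#'   `"outward"`.
#' @param noise_sd_pa Gaussian noise SD, pA.
#' @param seed Integer RNG seed.
#' @return An object of class `psc_sim_config`.
#' @export
psc_sim_config <- function(sweep_duration_s = 60, sample_rate_hz = 4000,
                           event_rate_hz = 0.5, amp_dist = c(20, 8),
                           rise_tau_ms = 1, decay_tau_ms = 6,
                           polarity = c("inward", "outward"),
                           noise_sd_pa = 2, seed = 1) {
  polarity <- match.arg(polarity)
  if (rise_tau_ms >= decay_tau_ms) stop("rise_tau_ms must be < decay_tau_ms")
  if (event_rate_hz < 0 || noise_sd_pa < 0 || any(amp_dist < 0))
    stop("rates, amplitudes and SDs must be non-negative")
  structure(list(
    sweep_duration_s = sweep_duration_s, sample_rate_hz = sample_rate_hz,
    event_rate_hz = event_rate_hz, amp_dist = amp_dist,
    rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
    polarity = polarity, noise_sd_pa = noise_sd_pa, seed = seed),
    class = "psc_sim_config")
}

#' Generate a spontaneous-PSC sweep with ground truth
#'
#' Poisson event times convolved with a unit-peak biexponential kernel;
#' log-normal amplitudes; Gaussian noise. Inward polarity gives
#' negative-going deflections.
#'
#' @param cfg A [psc_sim_config()].
#' @return List with `sweep` ([sweep_recording()]) and `ground_truth`
#'   (data.frame: time_ms = event onset, peak_time_ms, amplitude_pa).
#' @export
gen_psc_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "psc_sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$sweep_duration_s * cfg$sample_rate_hz)
    dt_ms <- 1000 / cfg$sample_rate_hz
    x <- stats::rnorm(n, 0, cfg$noise_sd_pa)
    n_ev <- stats::rpois(1, cfg$event_rate_hz * cfg$sweep_duration_s)
    onset_ms <- sort(stats::runif(n_ev, 0, cfg$sweep_duration_s * 1000 - 60))
    m <- cfg$amp_dist[1]; s <- cfg$amp_dist[2]
    amps <- if (n_ev > 0) {
      if (s == 0) rep(m, n_ev) else
        stats::rlnorm(n_ev, log(m^2 / sqrt(m^2 + s^2)), sqrt(log(1 + s^2 / m^2)))
    } else numeric()
    sgn <- if (cfg$polarity == "inward") -1 else 1
    klen <- ceiling((cfg$rise_tau_ms + 8 * cfg$decay_tau_ms) / dt_ms)
    kt <- (seq_len(klen) - 1L) * dt_ms
    kern <- biexp_kernel(kt, cfg$rise_tau_ms, cfg$decay_tau_ms)
    tpk <- cfg$rise_tau_ms * cfg$decay_tau_ms /
      (cfg$decay_tau_ms - cfg$rise_tau_ms) *
      log(cfg$decay_tau_ms / cfg$rise_tau_ms)
    for (i in seq_len(n_ev)) {
      i0 <- floor(onset_ms[i] / dt_ms) + 1L
      idx <- i0 + seq_len(klen) - 1L
      keep <- idx <= n
      x[idx[keep]] <- x[idx[keep]] + sgn * amps[i] * kern[keep]
    }
    gt <- data.frame(time_ms = onset_ms, peak_time_ms = onset_ms + tpk,
                     amplitude_pa = amps)
    list(sweep = sweep_recording(x, cfg$sample_rate_hz, holding_mv = -60,
                                 modality = "current"),
         ground_truth = gt)
  })
}

#' Generate an evoked paired-pulse sweep
#'
#' Two evoked responses at the given inter-stimulus interval; the second
#' response is superimposed on the residual decay of the first, so the true
#' paired-pulse ratio is recovered by a decay-corrected measurement of the
#' second amplitude (the convention [paired_pulse_ratio()] implements).
#'
#' @param a1_pa First-response peak amplitude, pA (> 0).
#' @param ppr_true True ratio of second to first amplitude (> 0).
#' @param isi_ms Inter-stimulus interval, ms (100 ms in the reference
#'   protocol).
#' @param kernel A [psc_sim_config()] supplying kinetics, polarity and
#'   noise; its rate field is ignored.
#' @param latency_ms Synaptic latency from stimulus to response onset.
#' @return A [sweep_recording()] with two `stim_times_ms`.
#' @export
gen_paired_pulse <- function(a1_pa, ppr_true, isi_ms = 100,
                             kernel = psc_sim_config(noise_sd_pa = 0),
                             latency_ms = 3) {
  if (a1_pa <= 0 || ppr_true <= 0) stop("a1_pa and ppr_true must be positive")
  if (isi_ms <= kernel$rise_tau_ms)
    stop("isi_ms must exceed the kernel rise time")
  with_seed(kernel$seed, {
    fs <- kernel$sample_rate_hz
    dt_ms <- 1000 / fs
    stim1 <- 50; stim2 <- 50 + isi_ms
    dur_ms <- stim2 + 8 * kernel$decay_tau_ms + 50
    n <- round(dur_ms / dt_ms)
    t_ms <- (seq_len(n) - 1L) * dt_ms
    sgn <- if (kernel$polarity == "inward") -1 else 1
    x <- stats::rnorm(n, 0, kernel$noise_sd_pa)
    x <- x + sgn * a1_pa *
      biexp_kernel(t_ms - stim1 - latency_ms, kernel$rise_tau_ms, kernel$decay_tau_ms)
    x <- x + sgn * a1_pa * ppr_true *
      biexp_kernel(t_ms - stim2 - latency_ms, kernel$rise_tau_ms, kernel$decay_tau_ms)
    sweep_recording(x, fs, stim_times_ms = c(stim1, stim2),
                    holding_mv = -60, modality = "current")
  })
}

#' Generate a compound postsynaptic current sweep
#'
#' Emulates a compound PSC recorded at an intermediate holding potential
#' (-40 mV): an early inward (excitatory, monosynaptic) component followed
#' by a delayed outward (inhibitory, disynaptic) component. The kernel
#' decay constants are solved so the component peaks and areas equal the
#' requested values.
#'
#' @param exc_peak_pa,inh_peak_pa Component peak magnitudes, pA (>= 0).
#' @param exc_area,inh_area Component areas, pA*ms (>= 0). The implied
#'   area/peak ratio must exceed the component rise time.
#' @param noise_sd Gaussian noise SD, pA.
#' @param seed Integer RNG seed.
#' @param inh_delay_ms Onset delay of the inhibitory component after the
#'   excitatory onset; by default long enough (at least 8 excitatory decay
#'   constants) that the components do not materially overlap.
#' @return A [sweep_recording()] with one stimulus time and
#'   `holding_mv = -40`.
#' @export
gen_compound_psc <- function(exc_peak_pa, exc_area, inh_peak_pa, inh_area,
                             noise_sd = 0, seed = 1, inh_delay_ms = NULL) {
  if (any(c(exc_peak_pa, exc_area, inh_peak_pa, inh_area) < 0))
    stop("peaks and areas must be non-negative")
  with_seed(seed, {
    fs <- 4000; dt_ms <- 1000 / fs
    stim <- 50; lat <- 3
    exc_td <- if (exc_peak_pa > 0)
      solve_decay_tau(exc_area / exc_peak_pa, rise_tau_ms = 1) else 0
    inh_td <- if (inh_peak_pa > 0)
      solve_decay_tau(inh_area / inh_peak_pa, rise_tau_ms = 2) else 0
    if (is.null(inh_delay_ms))  # let the excitatory component decay out
      inh_delay_ms <- max(45, 8 * exc_td)
    dur_ms <- max(400, stim + lat + inh_delay_ms + 8 * inh_td + 20)
    n <- round(dur_ms / dt_ms)
    t_ms <- (seq_len(n) - 1L) * dt_ms
    x <- stats::rnorm(n, 0, noise_sd)
    if (exc_peak_pa > 0)
      x <- x - exc_peak_pa * biexp_kernel(t_ms - stim - lat, 1, exc_td)
    if (inh_peak_pa > 0)
      x <- x + inh_peak_pa * biexp_kernel(t_ms - stim - lat - inh_delay_ms, 2, inh_td)
    sweep_recording(x, fs, stim_times_ms = stim, holding_mv = -40,
                    modality = "current")
  })
}

#' Generate a family of fEPSP sweeps across stimulus intensities
#'
#' Each sweep carries a brief stimulus artifact, a fast fiber volley whose
#' amplitude grows linearly with intensity, and a slower negative-going
#' fEPSP whose amplitude is `amp_scale` times a sigmoidal function of
#' intensity. Sweeps at or above `ps_threshold_ua` carry a positive-going
#' population-spike notch superimposed on the fEPSP trough, scaled
#' proportionally to the fEPSP so inter-family amplitude ratios are
#' preserved.
#'
#' @param intensities_ua Ascending stimulus intensities, microamps.
#' @param amp_scale Maximal fEPSP amplitude, mV (the sigmoid saturates at
#'   this value).
#' @param ps_threshold_ua Lowest intensity at which a population spike is
#'   injected; `Inf` for none.
#' @param noise_sd Gaussian noise SD, mV.
#' @param seed Integer RNG seed.
#' @param fv_scale Fiber-volley amplitude per microamp, mV.
#' @param i50_ua,sig_slope_ua Sigmoid midpoint and slope of the
#'   intensity-response function.
#' @param ps_rel Population-spike notch amplitude relative to the fEPSP
#'   amplitude.
#' @return A list of `list(intensity_ua=, sweep=)` entries.
#' @export
gen_fepsp_family <- function(intensities_ua, amp_scale, ps_threshold_ua = Inf,
                             noise_sd = 0, seed = 1, fv_scale = 0.004,
                             i50_ua = 50, sig_slope_ua = 15, ps_rel = 0.35) {
  if (is.unsorted(intensities_ua, strictly = TRUE))
    stop("intensities must be strictly ascending")
  with_seed(seed, {
    fs <- 10000; dt_ms <- 1000 / fs
    stim <- 10; dur_ms <- 60
    n <- round(dur_ms / dt_ms)
    t_ms <- (seq_len(n) - 1L) * dt_ms
    lapply(intensities_ua, function(I) {
      x <- stats::rnorm(n, 0, noise_sd)
      # biphasic stimulus artifact within the 2 ms blanking window
      x[t_ms >= stim & t_ms < stim + 0.4] <- 2
      x[t_ms >= stim + 0.4 & t_ms < stim + 0.8] <- -2
      # fiber volley: narrow negative gaussian at stim + 3 ms
      x <- x - fv_scale * I * exp(-(t_ms - stim - 3)^2 / (2 * 0.4^2))
      # fEPSP: negative alpha wave, onset stim + 5 ms, peak 5 ms later
      amp <- amp_scale / (1 + exp(-(I - i50_ua) / sig_slope_ua))
      ta <- t_ms - stim - 5
      alpha <- ifelse(ta > 0, (ta / 5) * exp(1 - ta / 5), 0)
      x <- x - amp * alpha
      if (I >= ps_threshold_ua) {
        trough <- stim + 10
        x <- x + ps_rel * amp * exp(-(t_ms - trough)^2 / (2 * 0.5^2))
      }
      list(intensity_ua = I,
           sweep = sweep_recording(x, fs, stim_times_ms = stim,
                                   modality = "field"))
    })
  })
}
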