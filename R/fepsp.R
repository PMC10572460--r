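# Field EPSP measurement, input-output curves, population-spike threshold.

#' Measure a single fEPSP sweep
#'
#' Extracts the fiber volley (first fast negative deflection after the
#' artifact blanking window), the fEPSP amplitude (baseline to negative
#' peak of the slower field potential), the rising-phase slope (line fit
#' over the 20-80 percent span of the descending-voltage phase, the
#' field's standard convention), and a population-spike flag: a
#' positive-going notch superimposed on the fEPSP trough whose prominence
#' exceeds `ps_criterion` times the fEPSP amplitude.
#'
#' @param sweep A field-modality [sweep_recording()] in mV.
#' @param stim_time_ms Stimulus time; defaults to the sweep's first.
#' @param blank_ms Stimulus-artifact blanking window (default 2 ms).
#' @param fv_window_ms Fiber-volley search window after the stimulus.
#' @param fepsp_window_ms fEPSP search window after the stimulus.
#' @param baseline_ms Pre-stimulus baseline span.
#' @param ps_criterion Notch prominence relative to fEPSP amplitude.
#' @param slope_span Amplitude fractions bounding the slope fit.
#' @return One-row data.frame: `fv_amp_mv`, `fepsp_amp_mv`,
#'   `fepsp_slope_mv_per_ms` (magnitude), `ps_present`, `ps_amp_mv`, `ok`
#'   (FALSE when no deflection exceeded the noise floor; measures then 0).
#' @export
measure_fepsp <- function(sweep, stim_time_ms = sweep$stim_times_ms[1],
                          blank_ms = 2, fv_window_ms = c(2, 5),
                          fepsp_window_ms = c(5, 40), baseline_ms = 5,
                          ps_criterion = 0.1, slope_span = c(0.2, 0.8)) {
  if (!length(stim_time_ms) || is.na(stim_time_ms))
    stop("a stimulus time is required")
  dt_ms <- 1000 / sweep$sample_rate_hz
  bl_idx <- win_idx(sweep, max(0, stim_time_ms - baseline_ms), stim_time_ms)
  bl <- mean(sweep$values[bl_idx])
  noise <- robust_sd(sweep$values[bl_idx])
  zeroed <- data.frame(fv_amp_mv = 0, fepsp_amp_mv = 0,
                       fepsp_slope_mv_per_ms = 0, ps_present = FALSE,
                       ps_amp_mv = 0, ok = FALSE)
  f_idx <- win_idx(sweep, stim_time_ms + fepsp_window_ms[1],
                   stim_time_ms + fepsp_window_ms[2])
  y <- sweep$values[f_idx] - bl
  if (max(abs(y)) <= 5 * noise || max(-y) <= 0) return(zeroed)
  # fiber volley: most negative point in the early window, after blanking
  v_idx <- win_idx(sweep, stim_time_ms + max(blank_ms, fv_window_ms[1]),
                   stim_time_ms + fv_window_ms[2])
  fv <- max(0, -(min(sweep$values[v_idx]) - bl))
  if (fv <= 5 * noise) fv <- 0
  amp <- max(-y)
  trough <- which.min(y)
  # slope: 20-80% amplitude crossings on the falling-voltage (rising) phase
  lo <- slope_span[1] * amp; hi <- slope_span[2] * amp
  rise <- y[seq_len(trough)]
  i_lo <- which(-rise >= lo)[1]
  i_hi <- which(-rise >= hi)[1]
  slope <- if (!is.na(i_lo) && !is.na(i_hi) && i_hi > i_lo) {
    seg <- i_lo:i_hi
    abs(stats::coef(stats::lm(rise[seg] ~ seg))[[2]] / dt_ms)
  } else 0
  # population spike: interior positive-going notch near the trough
  k <- max(1L, round(0.3 / dt_ms))
  ys <- smooth_ma(y, k)
  region <- which(-ys >= lo)        # trough region above 20% amplitude
  ps_present <- FALSE; ps_amp <- 0
  if (length(region) > 4L) {
    seg <- ys[region]
    mx <- local_maxima(seg)
    for (m in mx) {
      left_min <- min(seg[seq_len(m)])
      right_min <- min(seg[m:length(seg)])
      prom <- seg[m] - max(left_min, right_min)
      if (prom >= ps_criterion * amp && prom > ps_amp) {
        ps_present <- TRUE
        ps_amp <- prom
      }
    }
  }
  data.frame(fv_amp_mv = fv, fepsp_amp_mv = amp,
             fepsp_slope_mv_per_ms = slope, ps_present = ps_present,
             ps_amp_mv = ps_amp, ok = TRUE)
}

#' Measure every sweep of an fEPSP family
#'
#' @param family A list of `list(intensity_ua=, sweep=)` entries, as
#'   returned by [gen_fepsp_family()].
#' @param ... Passed to [measure_fepsp()].
#' @return Data frame of per-intensity measures, ready for [build_io()].
#' @export
measure_family <- function(family, ...) {
  rows <- lapply(family, function(f)
    cbind(intensity_ua = f$intensity_ua, measure_fepsp(f$sweep, ...)))
  do.call(rbind, rows)
}

#' Build an input-output curve
#'
#' @param measures Data frame with `intensity_ua` plus [measure_fepsp()]
#'   columns.
#' @return The measures ordered by intensity, class `io_curve`, with
#'   attribute `ps_threshold_ua` (lowest intensity whose measure has a
#'   population spike; `NA` if none).
#' @export
build_io <- function(measures) {
  stopifnot(is.data.frame(measures), "intensity_ua" %in% names(measures))
  measures <- measures[order(measures$intensity_ua), , drop = FALSE]
  if (anyDuplicated(measures$intensity_ua))
    stop("intensities must be unique")
  with_ps <- measures$intensity_ua[measures$ps_present]
  attr(measures, "ps_threshold_ua") <-
    if (length(with_ps)) min(with_ps) else NA_real_
  class(measures) <- c("io_curve", "data.frame")
  measures
}

#' Population-spike threshold of an input-output curve
#'
#' The lowest stimulation intensity at which a population spike is
#' present -- an index of postsynaptic excitability (lower threshold,
#' higher excitability).
#'
#' @param curve An [build_io()] curve.
#' @return Intensity in microamps, or `NA` when no sweep shows a spike.
#' @export
ps_threshold <- function(curve) {
  stopifnot(inherits(curve, "io_curve"))
  attr(curve, "ps_threshold_ua")
}

#' Compare two input-output curves
#'
#' Per-intensity fEPSP amplitude ratios (curve b over curve a) at shared
#' intensities, plus their mean -- e.g. a uniform 2-fold enhancement gives
#' ratio 2 at every intensity.
#'
#' @param curve_a,curve_b [build_io()] curves.
#' @return List: `table` (intensity_ua, amp_a, amp_b, ratio),
#'   `mean_ratio`.
#' @export
compare_io <- function(curve_a, curve_b) {
  shared <- intersect(curve_a$intensity_ua, curve_b$intensity_ua)
  if (!length(shared)) stop("curves share no stimulation intensities")
  a <- curve_a[match(shared, curve_a$intensity_ua), ]
  b <- curve_b[match(shared, curve_b$intensity_ua), ]
  tab <- data.frame(intensity_ua = shared, amp_a = a$fepsp_amp_mv,
                    amp_b = b$fepsp_amp_mv,
                    ratio = b$fepsp_amp_mv / a$fepsp_amp_mv)
  list(table = tab, mean_ratio = mean(tab$ratio))
}

#' Paired before/after effect on the paired-pulse ratio
#'
#' Quantifies a within-slice manipulation (e.g. bath fluorocitrate) as
#' per-pair PPR differences with a paired statistical comparison.
#'
#' @param ppr_before,ppr_after Equal-length numeric PPR samples, paired by
#'   slice.
#' @return List of class `paired_effect`: `diff` (after - before),
#'   `mean_change`, `comparison` (paired [compare_two()] result, or `NULL`
#'   for fewer than 3 pairs).
#' @export
fc_ppr_effect <- function(ppr_before, ppr_after) {
  if (length(ppr_before) != length(ppr_after))
    stop("before/after samples must be paired (equal length)")
  d <- ppr_after - ppr_before
  cmp <- if (length(d) >= 3) compare_two(ppr_after, ppr_before, paired = TRUE)
         else NULL
  structure(list(diff = d, mean_change = mean(d), comparison = cmp),
            class = "paired_effect")
}

#' @export
print.paired_effect <- function(x, ...) {
  cat(sprintf("<paired_effect> n = %d pairs, mean change %+.4g\n",
              length(x$diff), x$mean_change))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
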