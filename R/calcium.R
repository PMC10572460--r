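# Astrocyte calcium transient pipeline: baseline, dF/F0, event detection,
# multi-peak splitting, percentile cut-off, fast/slow classification.

#' Compute delta-F/F0 from a raw trace and a baseline estimate
#'
#' `dff[t] = ((F[t] - bg) - (F0 - bg)) / (F0 - bg)`, i.e. the fractional
#' change over the quiescent baseline after background subtraction.
#'
#' @param trace A [fluor_trace()].
#' @param baseline A [find_baseline()] result (or any list with `f0`).
#' @return Numeric vector of delta-F/F0, same length as the trace.
#' @export
compute_dff <- function(trace, baseline) {
  f0 <- baseline$f0
  denom <- f0 - trace$background
  if (denom <= 0)
    stop("degenerate baseline: F0 must exceed the background fluorescence")
  ((trace$values - trace$background) - denom) / denom
}

# rolling standard deviation over every length-w window (via cumulants)
rolling_sd <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1L)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- (s2 - s^2 / w) / (w - 1)
  sqrt(pmax(v, 0))
}

#' Find a quiescent baseline window
#'
#' Selects the `min_quiet_frames`-long window with the smallest
#' within-window standard deviation, then iterates once: events are
#' detected against that provisional baseline and, if any overlap the
#' window, the lowest-SD window not intersecting an event is chosen
#' instead. `f0` is the chosen window's mean; `sd0` is the robust
#' first-difference noise estimate (`mad(diff(x))/sqrt(2)`), which avoids
#' the downward selection bias of the minimum-SD window. A manual
#' `(start, end)` window (0-based, inclusive) may be supplied to override
#' the search.
#'
#' @param trace A [fluor_trace()].
#' @param min_quiet_frames Window length (default 30 frames, the minimum
#'   quiescent stretch the protocol requires).
#' @param window Optional manual override, length-2 integer (0-based
#'   inclusive frames).
#' @param k_sd,min_frames Detection parameters used in the single
#'   refinement pass.
#' @return List of class `baseline_estimate`: `f0` (AU), `sd0` (AU),
#'   `window` (0-based inclusive frame span).
#' @export
find_baseline <- function(trace, min_quiet_frames = 30, window = NULL,
                          k_sd = 2, min_frames = 5) {
  x <- trace$values
  w <- as.integer(min_quiet_frames)
  if (length(x) < w) stop("trace shorter than the required quiet window")
  if (!is.null(window)) {
    idx <- (window[1] + 1L):(window[2] + 1L)
    if (length(idx) < w) stop("manual window shorter than min_quiet_frames")
    return(structure(list(f0 = mean(x[idx]), sd0 = stats::sd(x[idx]),
                          window = c(window[1], window[2])),
                     class = "baseline_estimate"))
  }
  sds <- rolling_sd(x, w)
  cs <- cumsum(c(0, x))
  means <- (cs[seq_len(length(x) - w + 1L) + w] -
              cs[seq_len(length(x) - w + 1L)]) / w
  # calcium transients only raise fluorescence, so a quiet window must lie
  # near the trace floor (lower quartile): a flat event plateau is not a
  # baseline even if its variance is low
  min_sd <- min(sds)
  low <- means <= stats::quantile(x, 0.25) + 4 * min_sd
  if (!any(low)) low <- rep(TRUE, length(means))
  best <- which(low)[which.min(sds[low])]
  # the minimum-SD window understates the noise SD (selection bias over
  # ~n overlapping windows); the robust first-difference estimator is
  # unbiased for frame-to-frame noise and insensitive to sparse transients
  sd0_est <- robust_sd(diff(x)) / sqrt(2)
  make_est <- function(start) {
    idx <- start:(start + w - 1L)
    structure(list(f0 = mean(x[idx]), sd0 = sd0_est,
                   window = c(start - 1L, start + w - 2L)),
              class = "baseline_estimate")
  }
  est <- make_est(best)
  # refinement: re-detect events with the provisional baseline and avoid them
  if (est$sd0 > 0) {
    dff <- compute_dff(trace, est)
    sd0_dff <- est$sd0 / (est$f0 - trace$background)
    ev <- detect_events(dff, sd0_dff, k_sd = k_sd, min_frames = min_frames,
                        frame_period_s = trace$frame_period_s)
    if (nrow(ev)) {
      bad <- rep(FALSE, length(x))
      for (i in seq_len(nrow(ev)))
        bad[(ev$onset_frame[i] + 1L):(ev$offset_frame[i] + 1L)] <- TRUE
      starts <- seq_len(length(x) - w + 1L)
      clean <- vapply(starts, function(s) !any(bad[s:(s + w - 1L)]), logical(1))
      if (!any(clean))
        stop("no ", w, "-frame window free of detected activity; supply a ",
             "manual baseline window via `window = c(start, end)`")
      cand <- starts[clean & low]
      if (!length(cand)) cand <- starts[clean]
      est <- make_est(cand[which.min(sds[cand])])
    }
  }
  est
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> F0 = %.4g AU, sd0 = %.4g AU, frames %d-%d\n",
              x$f0, x$sd0, x$window[1], x$window[2]))
  invisible(x)
}

empty_events <- function() {
  data.frame(onset_frame = integer(), offset_frame = integer(),
             duration_s = numeric(), peak_dff = numeric(),
             label = character())
}

#' Detect calcium transients in a delta-F/F0 trace
#'
#' An event is a maximal run of frames whose delta-F/F0 exceeds the
#' baseline by at least `k_sd` standard deviations, lasting no fewer than
#' `min_frames` consecutive frames (defaults 2 SD and 5 frames).
#'
#' @param dff Numeric delta-F/F0 vector.
#' @param sd0_dff Baseline SD expressed in delta-F/F0 units (> 0).
#' @param k_sd Threshold in baseline SDs.
#' @param min_frames Minimum run length, frames.
#' @param frame_period_s Seconds per frame, used for `duration_s`.
#' @return Data frame of events (class `ca_events`): `onset_frame`,
#'   `offset_frame` (0-based, inclusive), `duration_s`, `peak_dff`,
#'   `label` (`"unclassified"`), ordered by onset and non-overlapping.
#' @export
detect_events <- function(dff, sd0_dff, k_sd = 2, min_frames = 5,
                          frame_period_s = 1) {
  if (sd0_dff <= 0) stop("flat baseline: sd0 must be positive")
  thr <- k_sd * sd0_dff
  above <- dff >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) return(structure(empty_events(), class = c("ca_events", "data.frame")))
  on <- starts[keep]; off <- ends[keep]
  ev <- data.frame(
    onset_frame = on - 1L, offset_frame = off - 1L,
    duration_s = (off - on + 1L) * frame_period_s,
    peak_dff = vapply(seq_along(on), function(i) max(dff[on[i]:off[i]]),
                      numeric(1)),
    label = "unclassified")
  structure(ev, class = c("ca_events", "data.frame"))
}

# interior local maxima of x (indices), simple plateau-tolerant scan
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  # collapse plateaus: treat zero slope as continuing the previous trend
  for (i in seq_along(d)) if (d[i] == 0 && i > 1L) d[i] <- d[i - 1L]
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

#' Split multi-peak events at deep troughs
#'
#' Within each detected event, if the delta-F/F0 falls to 50 percent or
#' less of the smaller of two adjacent local maxima, the event is cut at
#' the trough into independent transients (`mode = "relative"`, default).
#' `mode = "absolute"` additionally cuts wherever the trough falls below
#' 0.5 delta-F/F0 (i.e. below 50 percent of F0 itself). Fragments shorter
#' than `min_frames` are discarded; results are contiguous, ordered and
#' non-overlapping.
#'
#' @param events A `ca_events` data frame from [detect_events()].
#' @param dff The delta-F/F0 vector the events were detected in.
#' @param min_frames Minimum fragment length, frames.
#' @param frame_period_s Seconds per frame.
#' @param mode `"relative"` or `"absolute"` (see Details).
#' @param smooth_frames Running-mean window (frames) used when locating
#'   peaks and troughs, so a single noisy frame cannot split an event; at
#'   1 Hz frame rates genuine calcium troughs span several frames.
#' @return A `ca_events` data frame with multi-peak events split.
#' @export
split_multipeak <- function(events, dff, min_frames = 5, frame_period_s = 1,
                            mode = c("relative", "absolute"),
                            smooth_frames = 3) {
  mode <- match.arg(mode)
  if (!nrow(events)) return(events)
  out <- list()
  for (i in seq_len(nrow(events))) {
    on <- events$onset_frame[i] + 1L
    off <- events$offset_frame[i] + 1L
    seg <- dff[on:off]
    segs <- smooth_ma(seg, min(smooth_frames, length(seg)))
    peaks <- local_maxima(segs)
    cuts <- integer()
    if (length(peaks) >= 2L) {
      for (j in seq_len(length(peaks) - 1L)) {
        lo <- peaks[j]; hi <- peaks[j + 1L]
        tr <- lo + which.min(segs[lo:hi]) - 1L
        deep <- segs[tr] <= 0.5 * min(segs[lo], segs[hi])
        if (mode == "absolute") deep <- deep || segs[tr] < 0.5
        if (deep) cuts <- c(cuts, tr)
      }
    }
    bounds <- c(0L, cuts - 1L, length(seg))  # fragment j: (bounds[j]+1)..bounds[j+1]
    # right fragment starts at the trough frame: boundaries are trough-1
    for (j in seq_len(length(bounds) - 1L)) {
      a <- bounds[j] + 1L; b <- bounds[j + 1L]
      if (b - a + 1L < min_frames) next
      out[[length(out) + 1L]] <- data.frame(
        onset_frame = on + a - 2L, offset_frame = on + b - 2L,
        duration_s = (b - a + 1L) * frame_period_s,
        peak_dff = max(seg[a:b]), label = "unclassified")
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_events()
  structure(ev, class = c("ca_events", "data.frame"))
}

#' Duration cut-off from the 75th percentile of pooled durations
#'
#' Empirical percentile with linear interpolation between closest order
#' statistics (the standard type-7 quantile rule, recorded in the result's
#' attributes). The reference study derived 23.1 s this way.
#'
#' @param durations_s Non-empty numeric vector of event durations, seconds.
#' @param percentile Percentile in (0, 100]; default 75.
#' @return The cut-off in seconds, with attributes `percentile` and
#'   `quantile_type`.
#' @export
derive_cutoff <- function(durations_s, percentile = 75) {
  if (!length(durations_s)) stop("empty duration sample")
  q <- unname(stats::quantile(durations_s, percentile / 100, type = 7))
  structure(q, percentile = percentile, quantile_type = 7L)
}

#' Classify events as fast or slow transients
#'
#' Fast transients (FT) are strictly shorter than the cut-off; events with
#' duration at or above the cut-off are slow transients (ST). Default
#' cut-off 23.1 s, the reference study's 75th-percentile criterion.
#'
#' @param events A `ca_events` data frame with `duration_s`.
#' @param cutoff_s Duration cut-off, seconds.
#' @return The events with `label` set to `"FT"` or `"ST"`, order
#'   preserved.
#' @export
classify_events <- function(events, cutoff_s = 23.1) {
  if (nrow(events))
    events$label <- ifelse(events$duration_s < cutoff_s, "FT", "ST")
  attr(events, "cutoff_s") <- cutoff_s
  events
}

#' Per-cell summary of classified events
#'
#' Reports the event count, mean duration, percentage of slow transients,
#' and the FT/ST count ratio -- the astroglial excitability index (lower
#' values mean relatively more slow transients, i.e. greater
#' calcium-dependent excitability). The ratio is `NA` when no ST occurred.
#'
#' @param events A classified `ca_events` data frame.
#' @param cell_id Identifier copied into the summary row.
#' @return One-row data frame: `cell_id, n_events, mean_duration_s,
#'   st_percent, ft_count, st_count, ft_st_ratio`.
#' @export
summarize_cell <- function(events, cell_id = "cell_1") {
  n <- nrow(events)
  ft <- sum(events$label == "FT")
  st <- sum(events$label == "ST")
  data.frame(
    cell_id = cell_id, n_events = n,
    mean_duration_s = if (n) mean(events$duration_s) else NA_real_,
    st_percent = if (n) 100 * st / n else NA_real_,
    ft_count = ft, st_count = st,
    ft_st_ratio = if (st > 0) ft / st else NA_real_)
}

#' Pool per-cell event tables into a group summary
#'
#' @param events_by_cell Named list of classified `ca_events` data frames,
#'   one per cell.
#' @return List of class `ca_group`: `per_cell` (stacked
#'   [summarize_cell()] rows) and `pooled_durations_s` (all event
#'   durations, for cumulative-distribution plots and cut-off derivation).
#' @export
summarize_group <- function(events_by_cell) {
  ids <- names(events_by_cell)
  if (is.null(ids)) ids <- sprintf("cell_%02d", seq_along(events_by_cell))
  per_cell <- do.call(rbind, Map(summarize_cell, events_by_cell, ids))
  pooled <- unlist(lapply(events_by_cell, function(e) e$duration_s),
                   use.names = FALSE)
  structure(list(per_cell = per_cell, pooled_durations_s = pooled),
            class = "ca_group")
}

#' @export
print.ca_group <- function(x, ...) {
  cat(sprintf("<ca_group> %d cells, %d pooled events\n",
              nrow(x$per_cell), length(x$pooled_durations_s)))
  print(x$per_cell, row.names = FALSE)
  invisible(x)
}

#' Run the full calcium pipeline on one trace
#'
#' Baseline search, delta-F/F0, threshold detection, multi-peak splitting
#' and FT/ST classification in one call.
#'
#' @param trace A [fluor_trace()].
#' @param k_sd,min_frames Detection parameters (defaults 2 SD, 5 frames).
#' @param cutoff_s FT/ST duration cut-off, seconds (default 23.1).
#' @param split_mode Splitting rule passed to [split_multipeak()].
#' @param baseline_window Optional manual baseline window.
#' @return List of class `ca_analysis`: `trace`, `baseline`, `dff`,
#'   `events` (classified), `summary` (one [summarize_cell()] row).
#' @export
analyze_trace <- function(trace, k_sd = 2, min_frames = 5, cutoff_s = 23.1,
                          split_mode = "relative", baseline_window = NULL) {
  bl <- find_baseline(trace, window = baseline_window,
                      k_sd = k_sd, min_frames = min_frames)
  dff <- compute_dff(trace, bl)
  sd0_dff <- bl$sd0 / (bl$f0 - trace$background)
  ev <- detect_events(dff, sd0_dff, k_sd, min_frames, trace$frame_period_s)
  ev <- split_multipeak(ev, dff, min_frames, trace$frame_period_s,
                        mode = split_mode)
  ev <- classify_events(ev, cutoff_s)
  structure(list(trace = trace, baseline = bl, dff = dff, events = ev,
                 summary = summarize_cell(ev, trace$cell_id)),
            class = "ca_analysis")
}

#' @export
print.ca_analysis <- function(x, ...) {
  cat(sprintf("<ca_analysis> cell %s: %d event(s) (%d FT, %d ST)\n",
              x$trace$cell_id, x$summary$n_events, x$summary$ft_count,
              x$summary$st_count))
  if (nrow(x$events)) print(as.data.frame(x$events), row.names = FALSE)
  invisible(x)
}

#' @param x A `ca_analysis` object.
#' @param ... Passed to [plot()].
#' @rdname analyze_trace
#' @export
plot.ca_analysis <- function(x, ...) {
  t_s <- (seq_along(x$dff) - 1L) * x$trace$frame_period_s
  plot(t_s, x$dff, type = "l", xlab = "time (s)",
       ylab = expression(Delta * F / F[0]),
       main = x$trace$cell_id, ...)
  if (nrow(x$events)) {
    col <- ifelse(x$events$label == "ST", "red", "black")
    for (i in seq_len(nrow(x$events))) {
      i0 <- x$events$onset_frame[i] + 1L
      i1 <- x$events$offset_frame[i] + 1L
      graphics::lines(t_s[i0:i1], x$dff[i0:i1], col = col[i], lwd = 2)
    }
  }
  invisible(x)
}
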