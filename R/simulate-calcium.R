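# Synthetic astrocyte calcium traces with ground truth.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the calcium-trace generator
#'
#' Defaults emulate the reference imaging protocol: 1 Hz frames for 5 min
#' (300 frames), somatic fluorescence around 2000 AU. Event durations are
#' drawn from two log-normal populations: fast transients (FT) well below
#' and slow transients (ST) well above the 23.1 s duration cut-off, so the
#' true class of every injected event is known. Event peak amplitudes are
#' expressed in multiples of the noise SD (i.e. the per-event SNR).
#'
#' @param n_cells Number of cells (traces) to generate.
#' @param n_frames Frames per trace (>= 30).
#' @param frame_period_s Seconds per frame.
#' @param baseline_level Quiescent fluorescence including background, AU.
#' @param noise_sd Gaussian noise SD, AU.
#' @param event_rate_per_min Expected transient rate per minute per cell.
#' @param st_fraction Probability an event is a slow transient, in [0, 1].
#' @param ft_duration_dist,st_duration_dist Length-2 `(meanlog, sdlog)` of
#'   the log-normal duration distributions, seconds.
#' @param event_amp_dist Length-2 `(mean, sd)` of peak amplitude in
#'   multiples of `noise_sd`; draws are truncated below at 4.
#' @param drift_slope Linear baseline drift, AU per frame.
#' @param background Scalar background fluorescence, AU.
#' @param overlap_mode If `TRUE`, each transient is generated as a merged
#'   two-peak event (trough at 40 percent of the smaller peak) so the
#'   multi-peak splitting rule can be exercised; ground truth then lists the
#'   two sub-events separately.
#' @param seed Integer RNG seed.
#' @return An object of class `ca_sim_config`.
#' @export
ca_sim_config <- function(n_cells = 10, n_frames = 300, frame_period_s = 1,
                          baseline_level = 2000, noise_sd = 40,
                          event_rate_per_min = 1, st_fraction = 0.25,
                          ft_duration_dist = c(log(8), 0.35),
                          st_duration_dist = c(log(45), 0.25),
                          event_amp_dist = c(10, 2), drift_slope = 0,
                          background = 100, overlap_mode = FALSE, seed = 1) {
  if (st_fraction < 0 || st_fraction > 1) stop("st_fraction must be in [0, 1]")
  if (n_frames < 30) stop("n_frames must be at least 30 (baseline window)")
  if (noise_sd < 0 || event_rate_per_min < 0) stop("rates and SDs must be non-negative")
  structure(list(
    n_cells = n_cells, n_frames = as.integer(n_frames),
    frame_period_s = frame_period_s, baseline_level = baseline_level,
    noise_sd = noise_sd, event_rate_per_min = event_rate_per_min,
    st_fraction = st_fraction, ft_duration_dist = ft_duration_dist,
    st_duration_dist = st_duration_dist, event_amp_dist = event_amp_dist,
    drift_slope = drift_slope, background = background,
    overlap_mode = overlap_mode, seed = seed), class = "ca_sim_config")
}

# One transient: supra-threshold part lasts exactly `dur` frames at the
# detection threshold 2*noise_sd -- linear rise over ~10% of the duration,
# plateau, geometric fall that hits the edge level on the last frame, then a
# sub-threshold decay tail. Returned in units of noise_sd.
transient_shape <- function(dur, amp_sd, edge_sd = 4) {
  if (dur == 1L) return(list(supra = amp_sd, tail = c(1.5, 0.7)))
  r <- max(1L, round(0.1 * dur))
  f <- max(1L, round(0.3 * dur))
  if (r + f >= dur) { r <- 1L; f <- max(1L, dur - 2L) }
  plateau <- dur - r - f
  rise <- seq(edge_sd, amp_sd, length.out = r + 1L)[seq_len(r)]
  fall <- amp_sd * (edge_sd / amp_sd)^(seq_len(f) / f)
  supra <- c(rise, rep(amp_sd, plateau), fall)
  # sub-threshold tail drops fast so the supra-threshold run ends exactly
  # at the drawn duration (halving per frame stays well below the 2-SD
  # detection threshold from the first tail frame)
  tail <- edge_sd * 0.35^seq_len(6L)
  tail <- tail[tail > 0.2]
  list(supra = supra, tail = tail)
}

#' Generate synthetic calcium traces with ground truth
#'
#' Each trace is `baseline_level + drift + Gaussian noise` plus injected
#' transients whose supra-threshold duration equals the drawn duration at
#' the event-detection threshold (2 SD above baseline). Events are placed
#' with at least a 2-frame gap, and the first 30 frames of every trace are
#' kept event-free so a quiescent baseline window always exists.
#'
#' @param cfg A [ca_sim_config()].
#' @return A list with `traces` (list of [fluor_trace()]) and
#'   `ground_truth` (data.frame: cell_id, onset_frame, offset_frame,
#'   duration_s, amp_sd, class).
#' @export
gen_calcium_traces <- function(cfg) {
  stopifnot(inherits(cfg, "ca_sim_config"))
  with_seed(cfg$seed, {
    traces <- vector("list", cfg$n_cells)
    gt <- list()
    minutes <- cfg$n_frames * cfg$frame_period_s / 60
    for (ci in seq_len(cfg$n_cells)) {
      id <- sprintf("cell_%02d", ci)
      n_ev <- stats::rpois(1, cfg$event_rate_per_min * minutes)
      sig <- numeric(cfg$n_frames)          # in noise_sd units
      occupied <- rep(FALSE, cfg$n_frames)
      occupied[seq_len(min(30L, cfg$n_frames))] <- TRUE  # quiescent window
      placed <- 0L
      for (ev in seq_len(n_ev)) {
        is_st <- stats::runif(1) < cfg$st_fraction
        dd <- if (is_st) cfg$st_duration_dist else cfg$ft_duration_dist
        dur_s <- stats::rlnorm(1, dd[1], dd[2])
        dur <- max(5L, as.integer(round(dur_s / cfg$frame_period_s)))
        amp <- max(4, stats::rnorm(1, cfg$event_amp_dist[1], cfg$event_amp_dist[2]))
        sh <- transient_shape(dur, amp)
        total <- length(sh$supra) + length(sh$tail)
        if (total + 32L > cfg$n_frames)
          stop("n_frames too small to host an event of ", dur, " frames plus ",
               "a 30-frame quiescent window; reduce durations or ",
               "event_rate_per_min, or increase n_frames")
        ok <- FALSE
        for (try in 1:200) {
          onset <- sample.int(cfg$n_frames - total + 1L, 1L)
          span <- seq.int(max(1L, onset - 2L), min(cfg$n_frames, onset + total + 1L))
          if (!any(occupied[span])) { ok <- TRUE; break }
        }
        if (!ok) next  # trace too full; skip remaining events
        idx <- onset + seq_along(sh$supra) - 1L
        if (cfg$overlap_mode && dur >= 12L) {
          # merged two-peak event: two half-duration peaks joined by a trough
          # at 40% of the smaller peak, detected as one supra-threshold run
          half <- dur %/% 2L
          s1 <- transient_shape(half, amp)
          s2 <- transient_shape(dur - half, amp)
          trough <- rep(0.4 * amp, 3L)  # multi-frame so smoothing keeps it deep
          merged <- c(s1$supra, trough, s2$supra)
          idx <- onset + seq_along(merged) - 1L
          tidx <- onset + length(merged) + seq_along(s2$tail) - 1L
          keep <- tidx <= cfg$n_frames
          sig[idx] <- sig[idx] + merged
          sig[tidx[keep]] <- sig[tidx[keep]] + s2$tail[keep]
          occupied[seq.int(onset, min(cfg$n_frames, max(tidx)))] <- TRUE
          off1 <- onset + half - 1L
          gt[[length(gt) + 1L]] <- data.frame(
            cell_id = id, onset_frame = c(onset, off1 + 4L) - 1L,
            offset_frame = c(off1, onset + length(merged) - 1L) - 1L,
            duration_s = c(half, dur - half) * cfg$frame_period_s,
            amp_sd = amp, class = if (is_st) "ST" else "FT",
            merged = TRUE)
          placed <- placed + 1L
          next
        }
        sig[idx] <- sig[idx] + sh$supra
        tidx <- onset + length(sh$supra) + seq_along(sh$tail) - 1L
        keep <- tidx <= cfg$n_frames
        sig[tidx[keep]] <- sig[tidx[keep]] + sh$tail[keep]
        occupied[seq.int(onset, min(cfg$n_frames, onset + total + 1L))] <- TRUE
        gt[[length(gt) + 1L]] <- data.frame(
          cell_id = id, onset_frame = onset - 1L,
          offset_frame = onset + dur - 2L,
          duration_s = dur * cfg$frame_period_s, amp_sd = amp,
          class = if (is_st) "ST" else "FT", merged = FALSE)
        placed <- placed + 1L
      }
      drift <- cfg$drift_slope * (seq_len(cfg$n_frames) - 1L)
      values <- cfg$baseline_level + drift + sig * cfg$noise_sd +
        stats::rnorm(cfg$n_frames, 0, cfg$noise_sd)
      traces[[ci]] <- fluor_trace(values, cfg$frame_period_s, id,
                                  background = cfg$background)
    }
    gt <- if (length(gt)) do.call(rbind, gt) else
      data.frame(cell_id = character(), onset_frame = integer(),
                 offset_frame = integer(), duration_s = numeric(),
                 amp_sd = numeric(), class = character(), merged = logical())
    list(traces = traces, ground_truth = gt)
  })
}
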