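# Independent oracles used across test files.

# brute-force percentile: sort + manual linear interpolation between order
# statistics (independent of stats::quantile)
brute_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force rectangle-sum area of the rectified lobes of a sweep segment
rect_area <- function(y, dt_ms) {
  list(neg = sum(pmax(-y, 0)) * dt_ms, pos = sum(pmax(y, 0)) * dt_ms)
}

# match detected event onsets to ground truth within a frame tolerance;
# returns counts for recall/precision computations
match_events <- function(det_onsets, true_onsets, tol) {
  matched <- rep(FALSE, length(true_onsets))
  tp <- 0L; fp <- 0L
  for (o in det_onsets) {
    d <- abs(true_onsets - o)
    m <- which(d <= tol & !matched)[1]
    if (!is.na(m)) { matched[m] <- TRUE; tp <- tp + 1L } else fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = sum(!matched))
}

# hand-built dff trace holding given supra-threshold segments on a zero
# baseline (sd0 implied 1 when values are in SD units)
dff_with_segments <- function(n, segments) {
  x <- numeric(n)
  for (s in segments) x[s$at + seq_along(s$values) - 1L] <- s$values
  x
}
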