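# Calcium pipeline: dF/F0 arithmetic, baseline search, detection rules,
# splitting, cut-off derivation, classification, summaries.

test_that("compute_dff matches direct arithmetic and is gain-invariant", {
  tr <- fluor_trace(c(rep(1100, 40), 1600, rep(1100, 40)), background = 100)
  bl <- list(f0 = 1100)
  dff <- compute_dff(tr, bl)
  expect_equal(dff[41], 0.5)                 # (1500-1000)/1000
  expect_equal(dff[1], 0)
  # constant multiplicative gain on (F - bg) leaves dff unchanged
  tr2 <- fluor_trace((tr$values - 100) * 3 + 100, background = 100)
  dff2 <- compute_dff(tr2, list(f0 = (1100 - 100) * 3 + 100))
  expect_equal(dff2, dff)
  # degenerate baseline rejected
  expect_error(compute_dff(tr, list(f0 = 50)), "baseline")
})

test_that("find_baseline selects a quiet window excluding events", {
  set.seed(31)
  x <- rnorm(300, 2000, 5)
  x[101:151] <- x[101:151] + 200  # one event, frames 100-150 (0-based)
  tr <- fluor_trace(x, cell_id = "c", background = 0)
  bl <- find_baseline(tr)
  expect_gte(bl$window[2] - bl$window[1] + 1L, 30)
  expect_true(bl$window[2] < 100 || bl$window[1] > 150)
  expect_lt(abs(bl$f0 - 2000), 3 * 5 / sqrt(30))
  # constant trace: f0 exact, sd0 = 0, and detection then refuses it
  trc <- fluor_trace(rep(1500, 60))
  blc <- find_baseline(trc)
  expect_equal(blc$f0, 1500)
  expect_identical(blc$sd0, 0)
  expect_error(detect_events(rep(0, 60), sd0_dff = 0), "sd0")
  # manual override honoured
  blm <- find_baseline(tr, window = c(200, 240))
  expect_identical(blm$window, c(200, 240))
})

test_that("detection needs 2 SD for at least 5 consecutive frames", {
  base <- numeric(100)
  ev6 <- dff_with_segments(100, list(list(at = 40, values = rep(2.5, 6))))
  expect_identical(nrow(detect_events(ev6, 1)), 1L)
  ev4 <- dff_with_segments(100, list(list(at = 40, values = rep(3, 4))))
  expect_identical(nrow(detect_events(ev4, 1)), 0L)
  # exactly at threshold counts (>=), below does not
  at2 <- dff_with_segments(100, list(list(at = 40, values = rep(2, 5))))
  expect_identical(nrow(detect_events(at2, 1)), 1L)
  under <- dff_with_segments(100, list(list(at = 40, values = rep(1.99, 10))))
  expect_identical(nrow(detect_events(under, 1)), 0L)
})

test_that("detected events carry correct spans, peaks and ordering", {
  dff <- dff_with_segments(200, list(
    list(at = 30, values = c(3, 5, 9, 5, 3)),
    list(at = 120, values = rep(4, 7))))
  ev <- detect_events(dff, 1, frame_period_s = 2)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$onset_frame, c(29L, 119L))
  expect_identical(ev$offset_frame, c(33L, 125L))
  expect_equal(ev$duration_s, c(10, 14))      # frames x 2 s
  expect_equal(ev$peak_dff, c(9, 4))
  # frame/second duality
  expect_equal(ev$duration_s,
               (ev$offset_frame - ev$onset_frame + 1) * 2)
})

test_that("injected well-separated events are recovered frame-accurately", {
  sim <- gen_calcium_traces(ca_sim_config(n_cells = 6, noise_sd = 1e-3,
                                          event_rate_per_min = 1, seed = 13))
  for (i in seq_along(sim$traces)) {
    a <- analyze_trace(sim$traces[[i]])
    gt <- sim$ground_truth[sim$ground_truth$cell_id == sprintf("cell_%02d", i), ]
    gt <- gt[order(gt$onset_frame), ]
    expect_identical(nrow(a$events), nrow(gt))
    if (nrow(gt)) {
      expect_lte(max(abs(a$events$onset_frame - gt$onset_frame)), 1)
      # event edges sit at the detection threshold, so durations carry up
      # to one frame of crossing jitter per flank
      expect_lte(max(abs(a$events$duration_s - gt$duration_s)), 2)
    }
  }
})

test_that("multi-peak events split at deep troughs only", {
  # two 10-SD peaks joined by a 40% trough: split into two transients
  two <- dff_with_segments(60, list(list(at = 10, values =
    c(4, 8, 10, 10, 8, 6, 4, 4, 4, 6, 8, 10, 10, 8, 4))))
  ev <- detect_events(two, 1)
  expect_identical(nrow(ev), 1L)
  sp <- split_multipeak(ev, two)
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$onset_frame[1], ev$onset_frame[1])
  expect_identical(sp$offset_frame[2], ev$offset_frame[1])
  # fragments are contiguous and non-overlapping
  expect_identical(sp$onset_frame[2], sp$offset_frame[1] + 1L)
  # trough at 80% of both peaks: no split
  shallow <- dff_with_segments(60, list(list(at = 10, values =
    c(4, 8, 10, 10, 8, 8, 8, 8, 8, 8, 10, 10, 8, 4))))
  ev2 <- detect_events(shallow, 1)
  expect_identical(nrow(split_multipeak(ev2, shallow)), 1L)
  # monotone rise-fall events are returned unchanged
  mono <- dff_with_segments(60, list(list(at = 10, values =
    c(4, 5, 6, 8, 10, 8, 6, 5, 4))))
  ev3 <- detect_events(mono, 1)
  expect_identical(split_multipeak(ev3, mono), ev3)
})

test_that("absolute split mode also cuts below 50% of F0", {
  # trough at 0.3 dff (60% of the 0.5-dff peaks): relative rule keeps it,
  # absolute rule cuts because the trough falls below 0.5 dff
  seg <- c(0.3, 0.4, 0.5, 0.5, 0.4, 0.3, 0.3, 0.3, 0.4, 0.5, 0.5, 0.4, 0.3)
  dff <- dff_with_segments(40, list(list(at = 10, values = seg * 100)))
  dff <- dff / 100  # values in dff units; sd0 chosen so all frames qualify
  ev <- detect_events(dff, 0.01)
  expect_identical(nrow(split_multipeak(ev, dff, mode = "relative")), 1L)
  expect_identical(nrow(split_multipeak(ev, dff, mode = "absolute")), 2L)
})

test_that("derive_cutoff matches a brute-force percentile", {
  expect_equal(as.numeric(derive_cutoff(c(10, 20, 30, 40))), 32.5)
  expect_equal(as.numeric(derive_cutoff(rep(7, 5))), 7)
  set.seed(77)
  for (i in 1:25) {
    x <- rlnorm(sample(5:200, 1), 2, 0.8)
    p <- sample(c(25, 50, 75, 90), 1)
    expect_equal(as.numeric(derive_cutoff(x, p)), brute_percentile(x, p))
    expect_gte(derive_cutoff(x, p), min(x))
    expect_lte(derive_cutoff(x, p), max(x))
  }
  expect_error(derive_cutoff(numeric()), "empty")
})

test_that("classification respects the strict-less-than FT rule", {
  ev <- data.frame(onset_frame = 0:3, offset_frame = 1:4,
                   duration_s = c(5, 30, 23.1, 23.0999),
                   peak_dff = 1, label = "unclassified")
  cl <- classify_events(ev, cutoff_s = 23.1)
  expect_identical(cl$label, c("FT", "ST", "ST", "FT"))
  expect_identical(cl$duration_s, ev$duration_s)  # order preserved
})

test_that("cell and group summaries compute the excitability indices", {
  ev <- data.frame(onset_frame = c(0, 10, 20, 40), offset_frame = c(5, 15, 25, 70),
                   duration_s = c(6, 6, 6, 31), peak_dff = 1,
                   label = c("FT", "FT", "FT", "ST"))
  s <- summarize_cell(ev, "c1")
  expect_identical(s$n_events, 4L)
  expect_equal(s$st_percent, 25)
  expect_equal(s$ft_st_ratio, 3)
  expect_identical(s$ft_count + s$st_count, s$n_events)
  # all-FT cell: ratio missing, never a division error
  allft <- ev[ev$label == "FT", ]
  s2 <- summarize_cell(allft, "c2")
  expect_equal(s2$st_percent, 0)
  expect_true(is.na(s2$ft_st_ratio))
  grp <- summarize_group(list(c1 = ev, c2 = allft))
  expect_identical(nrow(grp$per_cell), 2L)
  expect_identical(length(grp$pooled_durations_s), 7L)
})

test_that("higher ST fraction lowers the recovered FT/ST ratio", {
  mean_ratio <- function(stf, seed) {
    sim <- gen_calcium_traces(ca_sim_config(n_cells = 12, st_fraction = stf,
                                            event_rate_per_min = 1.5,
                                            seed = seed))
    an <- lapply(sim$traces, analyze_trace)
    r <- vapply(an, function(a) a$summary$ft_st_ratio, numeric(1))
    mean(r, na.rm = TRUE)
  }
  r_low <- mean_ratio(0.2, 101)
  r_high <- mean_ratio(0.6, 102)
  expect_lt(r_high, r_low)
})

test_that("classification recovers ground-truth labels at generator defaults", {
  sim <- gen_calcium_traces(ca_sim_config(n_cells = 25, st_fraction = 0.4,
                                          event_rate_per_min = 1.2, seed = 55))
  ok <- 0L; n <- 0L
  for (i in seq_along(sim$traces)) {
    a <- analyze_trace(sim$traces[[i]])
    gt <- sim$ground_truth[sim$ground_truth$cell_id == sprintf("cell_%02d", i), ]
    for (j in seq_len(nrow(a$events))) {
      m <- which(abs(gt$onset_frame - a$events$onset_frame[j]) <= 2)[1]
      if (!is.na(m)) {
        n <- n + 1L
        if (gt$class[m] == a$events$label[j]) ok <- ok + 1L
      }
    }
  }
  expect_gt(n, 100)
  expect_gte(ok / n, 0.95)
})
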