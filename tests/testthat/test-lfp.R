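# Multitaper PSD, band power, interictal spikes, after-discharges.

test_that("DPSS tapers are orthonormal and concentrated", {
  v <- dpss_tapers(512, 5, 9)
  gram <- crossprod(v)
  expect_equal(gram, diag(9), tolerance = 1e-8)
  # interpolated long-window tapers stay orthonormal
  v2 <- dpss_tapers(4000, 5, 9)
  expect_equal(crossprod(v2), diag(9), tolerance = 1e-6)
  # first taper is bell-shaped and positive
  expect_true(all(v[, 1] > 0))
  expect_gt(v[256, 1], v[10, 1])
})

test_that("PSD grid spacing is the reciprocal of the segment duration", {
  rec <- lfp_recording(rnorm(8000), 1000)
  psd <- multitaper_psd(rec, segment_ms = 4000, overlap_ms = 500)
  expect_equal(psd$freq[2] - psd$freq[1], 1 / 4)
  expect_equal(max(psd$freq), 500)
  expect_identical(ncol(psd$segments), 2L)  # starts at 0 and 3.5 s
  expect_warning(multitaper_psd(rec, n_tapers = 12), "concentration")
  expect_error(multitaper_psd(lfp_recording(rnorm(100), 1000)), "segment")
})

test_that("a pure 2 Hz sinusoid peaks inside the 1-3 Hz band", {
  t <- (0:19999) / 1000
  rec <- lfp_recording(sin(2 * pi * 2 * t), 1000)
  psd <- multitaper_psd(rec)
  pk <- psd$freq[which.max(psd$power)]
  expect_gt(pk, 1); expect_lt(pk, 3)
  # the line is smeared over the taper bandwidth W = nw/T = 1.25 Hz, so
  # near-total power lies within peak +/- W and the 1-3 Hz band dominates
  total <- band_power(psd, 0, 500)
  expect_gte(band_power(psd, 0.5, 3.5) / total, 0.95)
  expect_gte(band_power(psd, 1, 3) / total, 0.8)
})

test_that("white-noise PSD is flat and Parseval holds", {
  set.seed(12)
  ratios <- replicate(20, {
    rec <- lfp_recording(rnorm(12000), 1000)
    psd <- multitaper_psd(rec)
    band_power(psd, 50, 150) / band_power(psd, 250, 350)
  })
  expect_true(all(ratios > 0.8 & ratios < 1.25))
  rec <- lfp_recording(rnorm(20000), 1000)
  psd <- multitaper_psd(rec)
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(sum(psd$power) * df, var(rec$values), tolerance = 0.05)
})

test_that("band power is additive over adjacent bands and rejects bad bands", {
  rec <- lfp_recording(rnorm(8000), 1000)
  psd <- multitaper_psd(rec)
  expect_equal(band_power(psd, 1, 3) + band_power(psd, 3, 50),
               band_power(psd, 1, 50))
  expect_error(band_power(psd, 3, 1), "inverted")
  expect_identical(band_power(multitaper_psd(
    lfp_recording(numeric(8000) + 0 * rnorm(8000), 1000)), 1, 3), 0)
})

test_that("interictal spikes are recovered by width and amplitude", {
  cfg <- lfp_sim_config(duration_s = 60, background_sd_mv = 0.05,
    spike_schedule = data.frame(time_s = c(10, 25, 40),
                                width_ms = c(40, 30, 60),
                                amplitude_mv = 0.8),
    seed = 6)
  rec <- gen_lfp(cfg)$recording
  sp <- detect_interictal_spikes(rec)
  expect_identical(nrow(sp), 3L)
  expect_lt(max(abs(sort(sp$time_s) - c(10, 25, 40))), 0.01)
  expect_equal(sp$width_ms[order(sp$time_s)], c(40, 30, 60), tolerance = 0.15)
  # too-narrow deflections rejected even at high amplitude
  x <- rnorm(30000, 0, 0.05)
  x[15000 + (-3:3)] <- 1.5   # ~7 ms wide
  expect_identical(nrow(detect_interictal_spikes(lfp_recording(x, 1000))), 0L)
  # flat recording: empty list
  expect_identical(nrow(detect_interictal_spikes(
    lfp_recording(rnorm(5000, 0, 0.01), 1000))), 0L)
})

test_that("after-discharges are recovered with incidence and latency", {
  cfg <- lfp_sim_config(duration_s = 120, injection_time_s = 10,
    ad_schedule = data.frame(start_s = c(30, 80), duration_s = c(8, 12),
                             dominant_freq_hz = c(2, 3),
                             amplitude_mv = 0.5),
    seed = 14)
  sim <- gen_lfp(cfg)
  ads <- detect_afterdischarges(sim$recording)
  expect_identical(nrow(ads$ad_intervals), 2L)
  expect_equal(ads$incidence_per_min, 1)          # 2 ADs in 2 min
  expect_lt(abs(ads$latency_s - 20), 0.5)
  expect_equal(ads$durations_s, c(8, 12), tolerance = 0.08)
  expect_lt(max(abs(ads$ad_intervals$start_s - c(30, 80))), 0.5)
  # background-only recording: no ADs, incidence 0
  quiet <- gen_lfp(lfp_sim_config(duration_s = 60, seed = 15))$recording
  ads0 <- detect_afterdischarges(quiet)
  expect_identical(nrow(ads0$ad_intervals), 0L)
  expect_identical(ads0$incidence_per_min, 0)
  # no injection marker: latency missing
  cfg2 <- lfp_sim_config(duration_s = 60,
    ad_schedule = data.frame(start_s = 20, duration_s = 8,
                             dominant_freq_hz = 2, amplitude_mv = 0.5),
    seed = 16)
  expect_true(is.na(detect_afterdischarges(gen_lfp(cfg2)$recording)$latency_s))
})

test_that("zero-phase band-pass keeps event times unshifted", {
  cfg <- lfp_sim_config(duration_s = 60, background_sd_mv = 0.02,
    spike_schedule = data.frame(time_s = 30, width_ms = 40,
                                amplitude_mv = 0.8),
    seed = 17)
  rec <- gen_lfp(cfg)$recording
  filt <- lfp_bandpass(rec)
  expect_true(filt$filtered)
  sp <- detect_interictal_spikes(filt)
  expect_gte(nrow(sp), 1L)
  expect_lt(abs(sp$time_s[which.max(sp$amplitude_mv)] - 30), 0.01)
})
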