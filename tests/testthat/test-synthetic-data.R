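# Generators: determinism, ground-truth closure, class separation,
# noiseless self-consistency.

test_that("generators are deterministic for a fixed config and seed", {
  cfg <- ca_sim_config(n_cells = 2, seed = 42)
  expect_identical(gen_calcium_traces(cfg), gen_calcium_traces(cfg))
  pcfg <- psc_sim_config(sweep_duration_s = 10, seed = 42)
  expect_identical(gen_psc_sweep(pcfg), gen_psc_sweep(pcfg))
  lcfg <- lfp_sim_config(duration_s = 20, seed = 42)
  expect_identical(gen_lfp(lcfg), gen_lfp(lcfg))
  expect_identical(gen_fepsp_family(c(20, 60), 1, seed = 42),
                   gen_fepsp_family(c(20, 60), 1, seed = 42))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(7); a <- rnorm(1)
  set.seed(7); invisible(gen_psc_sweep(psc_sim_config(sweep_duration_s = 5)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("zero event rates give pure background with empty ground truth", {
  sim <- gen_calcium_traces(ca_sim_config(n_cells = 2, event_rate_per_min = 0,
                                          seed = 1))
  expect_identical(nrow(sim$ground_truth), 0L)
  for (tr in sim$traces)
    expect_lt(abs(mean(tr$values) - 2000), 10)
  ps <- gen_psc_sweep(psc_sim_config(event_rate_hz = 0, sweep_duration_s = 5,
                                     seed = 1))
  expect_identical(nrow(ps$ground_truth), 0L)
  expect_lt(max(abs(ps$sweep$values)), 6 * 2)  # noise only
})

test_that("slow-transient-only configs give durations above the cut-off", {
  cfg <- ca_sim_config(n_cells = 5, st_fraction = 1, event_rate_per_min = 2,
                       seed = 5)
  gt <- gen_calcium_traces(cfg)$ground_truth
  expect_gt(nrow(gt), 10)
  expect_true(all(gt$duration_s > 23.1))
})

test_that("duration populations separate at 23.1 s with default distributions", {
  cfg <- ca_sim_config(n_cells = 60, st_fraction = 0.5, event_rate_per_min = 1.5,
                       seed = 9)
  gt <- gen_calcium_traces(cfg)$ground_truth
  st <- gt$duration_s[gt$class == "ST"]
  ft <- gt$duration_s[gt$class == "FT"]
  expect_gt(length(st), 50); expect_gt(length(ft), 50)
  expect_gte(mean(st > 23.1), 0.99)
  expect_gte(mean(ft < 23.1), 0.99)
})

test_that("calcium ground truth is closed over injected events", {
  sim <- gen_calcium_traces(ca_sim_config(n_cells = 10, seed = 3))
  gt <- sim$ground_truth
  # one record per event, no duplicated spans within a cell
  key <- paste(gt$cell_id, gt$onset_frame)
  expect_identical(anyDuplicated(key), 0L)
  # every listed event has supra-threshold signal at its onset
  for (i in seq_len(nrow(gt))) {
    ci <- as.integer(sub("cell_", "", gt$cell_id[i]))
    tr <- sim$traces[[ci]]
    # onset frame sits at >= 4 noise-SDs above baseline, minus noise margin
    expect_gt(tr$values[gt$onset_frame[i] + 1L], 2000 + 40)
  }
})

test_that("PSC event counts fall in the Poisson 99% interval", {
  cfg <- psc_sim_config(sweep_duration_s = 60, event_rate_hz = 2, seed = 21)
  n <- nrow(gen_psc_sweep(cfg)$ground_truth)
  expect_gte(n, qpois(0.005, 120))
  expect_lte(n, qpois(0.995, 120))
})

test_that("inward polarity gives negative-going deflections", {
  cfg <- psc_sim_config(sweep_duration_s = 20, event_rate_hz = 1,
                        noise_sd_pa = 0, polarity = "inward", seed = 2)
  sw <- gen_psc_sweep(cfg)$sweep
  expect_lt(min(sw$values), -5)
  expect_lt(max(sw$values), 1e-9)
})

test_that("paired-pulse generator is self-consistent under the analyzer", {
  for (ppr in c(0.6, 0.8, 1, 1.3)) {
    sw <- gen_paired_pulse(100, ppr, isi_ms = 100,
                           kernel = psc_sim_config(noise_sd_pa = 0))
    expect_equal(as.numeric(paired_pulse_ratio(sw)), ppr, tolerance = 1e-3)
  }
  expect_error(gen_paired_pulse(100, 0.8, isi_ms = 0.5),
               "rise time")
})

test_that("compound PSC generator hits requested peaks and areas", {
  sw <- gen_compound_psc(200, 200 * 8, 100, 100 * 30, noise_sd = 0)
  ei <- compound_ei(sw)
  expect_equal(ei$exc_peak_pa, 200, tolerance = 1e-3)
  expect_equal(ei$inh_peak_pa, 100, tolerance = 1e-3)
  expect_equal(ei$exc_area, 1600, tolerance = 5e-3)
  expect_equal(ei$inh_area, 3000, tolerance = 5e-3)
  expect_equal(ei$ei_peak_ratio, 2, tolerance = 1e-3)
  # linearity: doubling the excitatory component doubles the E/I ratio
  sw2 <- gen_compound_psc(400, 400 * 8, 100, 100 * 30, noise_sd = 0)
  expect_equal(compound_ei(sw2)$ei_peak_ratio, 4, tolerance = 1e-3)
  # inhibitory-free sweep is purely inward
  sw3 <- gen_compound_psc(200, 200 * 8, 0, 0, noise_sd = 0)
  expect_lte(max(sw3$values), 0)
})

test_that("fEPSP families scale linearly and place the population spike", {
  ints <- c(20, 40, 60, 80, 100)
  fam1 <- gen_fepsp_family(ints, amp_scale = 0.8, ps_threshold_ua = 60)
  fam2 <- gen_fepsp_family(ints, amp_scale = 1.6, ps_threshold_ua = 60)
  m1 <- measure_family(fam1); m2 <- measure_family(fam2)
  expect_equal(m2$fepsp_amp_mv / m1$fepsp_amp_mv, rep(2, 5), tolerance = 1e-6)
  expect_identical(m1$ps_present, ints >= 60)
  # intensity far below threshold: no fEPSP beyond the artifact
  fam0 <- gen_fepsp_family(1e-6, amp_scale = 0.8, i50_ua = 50)
  m0 <- measure_fepsp(fam0[[1]]$sweep)
  expect_false(m0$ps_present)
})

test_that("LFP generator validates schedules and reproduces spectra", {
  expect_error(lfp_sim_config(duration_s = 10,
    ad_schedule = data.frame(start_s = 5, duration_s = 8,
                             dominant_freq_hz = 2, amplitude_mv = 1)),
    "inside")
  expect_error(lfp_sim_config(duration_s = 60,
    ad_schedule = data.frame(start_s = c(5, 8), duration_s = c(5, 5),
                             dominant_freq_hz = 2, amplitude_mv = 1)),
    "overlap")
  expect_error(lfp_sim_config(duration_s = 60,
    spike_schedule = data.frame(time_s = 5, width_ms = 10, amplitude_mv = 1)),
    "20-70")
  # a 2 Hz AD concentrates its power inside the 1-3 Hz band
  cfg <- lfp_sim_config(duration_s = 30, background_sd_mv = 0.01,
    ad_schedule = data.frame(start_s = 10, duration_s = 10,
                             dominant_freq_hz = 2, amplitude_mv = 0.5),
    seed = 4)
  rec <- gen_lfp(cfg)$recording
  ad_seg <- lfp_recording(rec$values[10001:20000], 1000)
  psd <- multitaper_psd(ad_seg)
  expect_gt(psd$freq[which.max(psd$power)], 1)
  expect_lt(psd$freq[which.max(psd$power)], 3)
})
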