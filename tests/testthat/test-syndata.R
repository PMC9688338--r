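test_that("spike-wave template has the expected length, peak, and spectrum", {
  expect_equal(make_spike_wave_template(256, 4, 1, amplitude = 0),
               rep(0, 64), ignore_attr = TRUE)
  tpl <- make_spike_wave_template(256, 4, n_cycles = 1, amplitude = 2)
  expect_length(tpl, 64)
  expect_equal(max(tpl), 2)
  expect_lt(which.max(tpl) / length(tpl), 0.25)
  # dominant non-DC spectral line at the repetition rate (1 Hz bins)
  tpl3 <- make_spike_wave_template(256, 3, n_cycles = 3)
  expect_length(tpl3, 256)
  spec <- Mod(stats::fft(tpl3 - mean(tpl3)))[2:128]
  freqs <- (1:127) * 256 / length(tpl3)
  expect_lte(abs(freqs[which.max(spec)] - 3), 1)
  expect_error(make_spike_wave_template(256, 4, 1, amplitude = -1))
  expect_error(make_spike_wave_template(256, -3, 1))
  expect_error(make_spike_wave_template(10, 4, 1))  # fs < 4 f_sw
})

test_that("coupled sources show planted lagged coherence and nothing else", {
  # no edges: all pairwise ImCoh near zero at 60 s
  s0 <- synthesize_coupled_sources(4, list(), freq = 4, duration = 60,
                                   seed = 10)
  ic0 <- imaginary_coherence_matrix(s0$activity, 256, freqs = 4)
  expect_lt(mean(abs(ic0[1, , ][upper.tri(ic0[1, , ])])), 0.1)
  # quarter-cycle lag, noiseless: |ImCoh| near 1 on the planted pair
  s1 <- synthesize_coupled_sources(3, list(c(1, 2)), phase_lag = pi / 2,
                                   freq = 4, duration = 10, noise_sd = 0,
                                   seed = 11)
  ic1 <- suppressWarnings(imaginary_coherence_matrix(s1$activity, 256,
                                                     freqs = 4))
  expect_gt(abs(ic1[1, 1, 2]), 0.95)
  # determinism
  s2 <- synthesize_coupled_sources(3, list(c(1, 2)), seed = 12)
  s3 <- synthesize_coupled_sources(3, list(c(1, 2)), seed = 12)
  expect_identical(s2$activity, s3$activity)
  # zero-lag coupling warns about invisibility to ImCoh
  expect_warning(synthesize_coupled_sources(3, list(c(1, 2)), phase_lag = 0,
                                            seed = 1),
                 "imaginary")
  expect_error(synthesize_coupled_sources(3, list(c(1, 1))))
  expect_error(synthesize_coupled_sources(3, list(c(1, 2)), freq = 200))
})

test_that("synthetic lead fields are full-rank with unit-order columns", {
  lf <- generate_lead_field(19, 60, seed = 4)
  expect_equal(dim(lf), c(19, 60))
  expect_equal(qr(lf)$rank, 19)
  norms <- sqrt(colSums(lf^2))
  expect_true(all(norms >= 0.5 & norms <= 2))
  expect_identical(lf, generate_lead_field(19, 60, seed = 4))
  expect_error(generate_lead_field(1, 10))
})

test_that("cohort generator plants the configured events with 4 s separation", {
  cfg <- synth_config(seed = 5)
  coh <- synthesize_cohort(cfg)
  ev <- coh$ground_truth$spike_event_samples
  expect_length(coh$recordings, 23)
  expect_equal(length(unlist(ev)), 115)  # 23 subjects x 5 events
  for (e in ev) expect_true(all(diff(e) >= 4 * cfg$fs))
  expect_equal(dim(coh$recordings[[1]]$data)[1], 19)
  # determinism of the generator
  coh2 <- synthesize_cohort(cfg)
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)
  # the spiking generator stays outside the coupled node set
  expect_false(coh$ground_truth$active_source_index %in%
                 unlist(cfg$planted_edges))
})

test_that("an event-free cohort recording yields no detections", {
  cfg0 <- synth_config(n_subjects = 1, n_gsw_epochs_per_subject = 0, seed = 3)
  coh0 <- synthesize_cohort(cfg0)
  rec <- common_average_reference(apply_filter_chain(coh0$recordings[[1]]))
  expect_length(detect_spike_events(global_field_power(rec)), 0)
})

test_that("noiseless GSW spectra peak in the spike-wave band", {
  tpl <- make_spike_wave_template(256, 3.5, n_cycles = 4)
  spec <- Mod(stats::fft(tpl - mean(tpl)))
  nf <- length(tpl)
  freqs <- (seq_len(nf) - 1) * 256 / nf
  keep <- freqs > 0.5 & freqs < 128
  peak_f <- freqs[keep][which.max(spec[keep])]
  expect_lte(abs(peak_f - 3.5), 0.5)
})
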