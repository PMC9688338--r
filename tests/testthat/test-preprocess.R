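fs <- 256
tt <- (0:(fs * 8 - 1)) / fs

test_that("filter chain passes 10 Hz, suppresses 50 Hz, and is linear", {
  zero <- sensor_recording(matrix(0, 2, 512), fs)
  expect_equal(apply_filter_chain(zero)$data, matrix(0, 2, 512),
               ignore_attr = TRUE)
  mid <- (fs * 2):(fs * 6)  # steady-state portion
  r10 <- sensor_recording(rbind(sin(2 * pi * 10 * tt),
                                cos(2 * pi * 10 * tt)), fs)
  f10 <- apply_filter_chain(r10)
  expect_lt(abs(stats::sd(f10$data[1, mid]) / stats::sd(r10$data[1, mid]) - 1),
            0.05)
  r50 <- sensor_recording(rbind(sin(2 * pi * 50 * tt),
                                cos(2 * pi * 50 * tt)), fs)
  f50 <- apply_filter_chain(r50)
  att_db <- 20 * log10(stats::sd(f50$data[1, mid]) /
                         stats::sd(r50$data[1, mid]))
  expect_lt(att_db, -30)
  # linearity: response to a sum equals the sum of responses
  a <- sin(2 * pi * 7 * tt); b <- sin(2 * pi * 21 * tt)
  fa <- apply_filter_chain(sensor_recording(rbind(a, a), fs))$data[1, ]
  fb <- apply_filter_chain(sensor_recording(rbind(b, b), fs))$data[1, ]
  fab <- apply_filter_chain(sensor_recording(rbind(a + b, a + b), fs))$data[1, ]
  expect_lt(max(abs(fab - fa - fb)), 1e-8)
  bad <- sensor_recording(matrix(1, 2, 512), fs)
  bad$data[1, 1] <- NaN
  expect_error(apply_filter_chain(bad), "finite")
  # fs too low for the 97-103 Hz stop band: stage skipped with a warning
  low <- sensor_recording(matrix(rnorm(2 * 400), 2), 200)
  expect_warning(apply_filter_chain(low), "97-103")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  r <- sensor_recording(rbind(c(1, 1), c(3, 3)), 10)
  out <- common_average_reference(r)
  expect_equal(out$data, rbind(c(-1, -1), c(1, 1)), ignore_attr = TRUE)
  set.seed(1)
  r2 <- sensor_recording(matrix(rnorm(19 * 100), 19), fs)
  c1 <- common_average_reference(r2)
  expect_lt(max(abs(colMeans(c1$data))), 1e-10)
  c2 <- common_average_reference(c1)
  expect_equal(c1$data, c2$data, tolerance = 1e-12)
  expect_error(common_average_reference(sensor_recording(matrix(1, 1, 5), 10)))
})

test_that("global field power matches its definition and is reference-free", {
  expect_equal(global_field_power(
    sensor_recording(matrix(3, 4, 5), 10))$values, rep(0, 5))
  expect_equal(global_field_power(
    sensor_recording(matrix(c(1, -1), 2, 1), 10))$values, 1)
  expect_equal(global_field_power(
    sensor_recording(matrix(c(2, 0, -2, 0), 4, 1), 10))$values, sqrt(2))
  set.seed(7)
  m <- matrix(rnorm(19 * 40), 19)
  g1 <- global_field_power(sensor_recording(m, fs))$values
  expect_equal(g1, oracle_gfp(m), tolerance = 1e-12)
  # adding a common per-sample offset changes nothing
  off <- matrix(rnorm(40), 19, 40, byrow = TRUE)
  g2 <- global_field_power(sensor_recording(m + off, fs))$values
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("spike events sit at the midpoint of the ascending limb", {
  flat <- structure(list(values = rep(1, 500), fs = fs), class = "gfp_series")
  expect_length(detect_spike_events(flat, min_prominence = 0.1), 0)
  # linear ramp 0 -> 1 over samples 100..120, then fall
  v <- rep(0.001, 300)
  v[100:120] <- seq(0, 1, length.out = 21)
  v[121:140] <- seq(1, 0.001, length.out = 21)[-1]
  g <- structure(list(values = v, fs = fs), class = "gfp_series")
  ev <- detect_spike_events(g, min_prominence = 0.5, refractory = 0)
  expect_equal(ev, 110L)
  # two close peaks collapse to the larger within the refractory window
  v2 <- rep(0, 1000)
  v2[200:220] <- c(seq(0, 1, length.out = 11), seq(1, 0, length.out = 11)[-1])
  v2[300:320] <- 0.6 * c(seq(0, 1, length.out = 11),
                         seq(1, 0, length.out = 11)[-1])
  g2 <- structure(list(values = v2, fs = fs), class = "gfp_series")
  ev2 <- detect_spike_events(g2, min_prominence = 0.3, refractory = 1)
  expect_length(ev2, 1)
  expect_equal(ev2, 205L)
  ev3 <- detect_spike_events(g2, min_prominence = 0.3, refractory = 0.1)
  expect_length(ev3, 2)
})

test_that("cohort spike detection reaches 0.95 sensitivity and precision", {
  cfg <- synth_config(seed = 21)
  coh <- synthesize_cohort(cfg)
  hits <- extras <- c()
  for (s in seq_along(coh$recordings)) {
    rec <- common_average_reference(apply_filter_chain(coh$recordings[[s]]))
    ev <- detect_spike_events(global_field_power(rec))
    true <- coh$ground_truth$spike_event_samples[[s]]
    hits <- c(hits, vapply(true, function(e) any(abs(ev - e) <= 2), logical(1)))
    extras <- c(extras, vapply(ev, function(e) all(abs(true - e) > 2),
                               logical(1)))
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(1 - mean(extras), 0.95)
})

test_that("GSW epochs are event-locked, merged by train, and bounded", {
  set.seed(2)
  rec <- sensor_recording(matrix(rnorm(3 * 2048), 3), fs)
  es <- extract_epochs(rec, events = 513L, pre = 2, post = 2)
  expect_equal(dim(es$data), c(1, 3, 1024))
  expect_equal(es$data[1, , ], rec$data[, 1:1024], ignore_attr = TRUE)
  # two events 1 s apart: one epoch anchored at the first spike
  es2 <- extract_epochs(rec, events = c(600L, 600L + fs))
  expect_equal(dim(es2$data)[1], 1)
  expect_equal(es2$events, 600L)
  expect_length(extract_epochs(rec, integer(0))$events, 0)
  expect_warning(extract_epochs(rec, events = 10L), "skipped")
})

test_that("resting-state epochs avoid events and reproduce under a seed", {
  set.seed(3)
  rec <- sensor_recording(matrix(rnorm(3 * fs * 60), 3), fs)
  events <- c(10 * fs, 30 * fs)
  expect_length(select_rs_epochs(rec, events, n = 0)$events, 0)
  rs <- select_rs_epochs(rec, events, n = 5, seed = 9)
  expect_equal(dim(rs$data), c(5, 3, 4 * fs))
  for (s0 in rs$events) {
    win <- c(s0, s0 + 4 * fs - 1)
    for (e in events)
      expect_true(e < win[1] - 2 * fs || e > win[2] + 2 * fs)
  }
  expect_true(all(diff(sort(rs$events)) >= 4 * fs))
  rs2 <- select_rs_epochs(rec, events, n = 5, seed = 9)
  expect_identical(rs$events, rs2$events)
  expect_error(select_rs_epochs(rec, events, n = 100, seed = 1),
               "insufficient")
})

test_that("amplitude-threshold rejection drops contaminated epochs", {
  arr <- array(rnorm(4 * 2 * 100), c(4, 2, 100))
  arr[2, 1, 50] <- 500
  es <- epoch_set(arr, fs, state = "RS")
  kept <- reject_artifact_epochs(es, threshold = 150)
  expect_equal(dim(kept$data)[1], 3)
})
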