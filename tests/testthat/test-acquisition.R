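test_that("quiet gravity-only recordings never trigger", {
  rec <- impulse_recording(peak_g = 1)           # no impulse above gravity
  expect_null(detect_trigger(rec$left, rec$right))
})

test_that("the trigger fires at the first crossing of the norm threshold", {
  rec <- impulse_recording(peak_g = 15, t_impact = 1.5)
  ev <- detect_trigger(rec$left, rec$right)
  expect_s3_class(ev, "trigger_event")
  expect_lte(ev$trigger_time, 1.5)               # first crossing is on the rise
  expect_gt(ev$peak_norm, 14 * 9.81)
  expect_equal(ev$source_wearable, "left")
  # brute-force scan over the merged streams agrees
  scan_first <- function(rec, thr) {
    nrm <- acc_norm_of(rec)
    i <- which(nrm > thr)[1]
    if (is.na(i)) Inf else (i - 1) / 1000
  }
  expect_equal(ev$trigger_time,
               min(scan_first(rec$left, 14 * 9.81),
                   scan_first(rec$right, 14 * 9.81)))
  # no earlier sample crosses (first-crossing property)
  nrm <- acc_norm_of(rec$left)
  before <- nrm[seq_len(round(ev$trigger_time * 1000))]
  expect_true(all(before <= 14 * 9.81))
})

test_that("trigger scan matches a brute-force oracle on simulated attempts", {
  for (seed in 1:3) {
    rec <- generate_attempt(attempt_scenario("drop"), seed = seed)
    ev <- detect_trigger(rec$left, rec$right)
    oracle_t <- min(vapply(list(rec$left, rec$right), function(r) {
      i <- which(acc_norm_of(r) > 14 * 9.81)[1]
      if (is.na(i)) Inf else (i - 1) / 1000
    }, numeric(1)))
    expect_equal(ev$trigger_time, oracle_t)
  }
})

test_that("mismatched time bases are rejected", {
  rec <- impulse_recording(15)
  rec$right$duration <- 5
  expect_error(detect_trigger(rec$left, rec$right), "time base")
})

test_that("segments span exactly 3 s at every native rate", {
  seg <- example_segment("catch")
  for (w in c("left", "right")) {
    expect_equal(length(seg[[w]]$acc_x), 3000)
    expect_equal(length(seg[[w]]$gyro_z), 3000)
    expect_equal(length(seg[[w]]$mag_y), 300)
    expect_equal(length(seg[[w]]$audio), 24000)
    expect_equal(length(seg[[w]]$pressure), 300)
  }
  # both wearables cut over the identical window
  expect_equal(seg$t_start, seg$trigger$trigger_time - 1)
  # the cut reproduces the raw samples around the trigger
  rec <- generate_attempt(attempt_scenario("catch"), seed = 1)
  i0 <- round(seg$t_start * 1000)
  expect_equal(seg$left$acc_x, rec$left$channels$acc_x[(i0 + 1):(i0 + 3000)])
})

test_that("segments needing pre-buffer data outside the recording are rejected", {
  rec <- impulse_recording(15, t_impact = 0.5)
  ev <- detect_trigger(rec$left, rec$right)
  expect_error(segment_attempt(rec$left, rec$right, ev), "pre-trigger")
})

test_that("sweeping impulse peaks recovers the 14 g firing threshold", {
  peaks <- seq(12, 16, by = 0.25)
  fires <- vapply(peaks, function(p) {
    rec <- impulse_recording(p)
    !is.null(detect_trigger(rec$left, rec$right))
  }, logical(1))
  first <- peaks[which(fires)[1]]
  expect_lte(abs(first - 14), 0.25)              # within one sweep step
  expect_true(all(fires[peaks >= first]))        # monotone beyond threshold
})
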