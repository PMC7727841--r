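test_that("scenario fields are validated against the condition grid", {
  sc <- attempt_scenario("drop", catch_style = "one_handed",
                         athlete_level = "novice")
  expect_s3_class(sc, "attempt_scenario")
  expect_error(attempt_scenario("fumble"), "outcome")
  expect_error(attempt_scenario("catch", movement = "cartwheel"), "movement")
  lv <- scenario_levels()
  expect_setequal(lv$athlete_level, c("novice", "advanced", "expert"))
  expect_setequal(lv$outcome, c("catch", "drop"))
})

test_that("generated attempts are deterministic, triggerable and in range", {
  spec <- sensor_channels()
  for (case in list(c("catch", "two_handed"), c("drop", "one_handed"))) {
    sc <- attempt_scenario(case[1], catch_style = case[2])
    rec <- generate_attempt(sc, seed = 11)
    rec2 <- generate_attempt(sc, seed = 11)
    expect_identical(rec, rec2)                  # bit-identical under a seed
    rec3 <- generate_attempt(sc, seed = 12)
    expect_false(identical(rec$left$channels$acc_x, rec3$left$channels$acc_x))
    # triggerability by construction: some sample exceeds 14 g on a wrist
    peak <- max(acc_norm_of(rec$left), acc_norm_of(rec$right))
    expect_gt(peak, 14 * 9.81)
    # every sample clipped to its channel range, on the 16-bit grid
    for (w in c("left", "right")) {
      for (j in seq_len(nrow(spec))) {
        x <- rec[[w]]$channels[[spec$name[j]]]
        expect_equal(length(x), 4 * spec$fs[j])
        expect_true(all(x >= spec$range_lo[j] & x <= spec$range_hi[j]))
        step <- (spec$range_hi[j] - spec$range_lo[j]) / (2^16 - 1)
        k <- (x - spec$range_lo[j]) / step
        expect_equal(max(abs(k - round(k))), 0, tolerance = 1e-6)
      }
    }
  }
})

test_that("oversized impacts saturate at the accelerometer limit", {
  sc <- attempt_scenario("catch")
  rec <- generate_attempt(sc, seed = 5,
                          params = sim_params(impact_peak_g = c(100, 100)))
  az <- abs(c(rec$left$channels$acc_x, rec$left$channels$acc_y,
              rec$left$channels$acc_z))
  expect_true(all(az <= 156.96))
  expect_equal(max(az), 156.96)                  # visibly clipped
})

test_that("short recordings and bad scenarios are rejected", {
  expect_error(generate_attempt(attempt_scenario("catch"), duration = 2,
                                seed = 1), "duration")
  expect_error(generate_attempt(list(outcome = "catch", movement = "nope"),
                                seed = 1), "movement")
  expect_error(generate_attempt(attempt_scenario("catch")), "seed")
})

test_that("dataset manifests match the configured composition exactly", {
  man <- generate_dataset(seed = 1)              # study-emulation default
  expect_equal(nrow(man), 759)
  expect_equal(sum(man$outcome == "catch"), 541)
  expect_equal(sum(man$outcome == "drop"), 218)
  lv <- scenario_levels()
  for (f in c("pass_source", "movement", "catch_style", "athlete_level"))
    expect_true(all(man[[f]] %in% lv[[f]]))
  man2 <- generate_dataset(seed = 1)
  expect_identical(man, man2)
  small <- generate_dataset(dataset_config(2, 1), seed = 3)
  expect_equal(sort(small$outcome), c("catch", "catch", "drop"))
  expect_error(dataset_config(0, 5), "positive")
  expect_error(dataset_config(5, -1), "positive")
})

test_that("materialized attempts reproduce from the manifest seeds", {
  man <- generate_dataset(dataset_config(2, 2), seed = 42)
  a1 <- materialize_attempt(man, 3)
  a2 <- materialize_attempt(man, 3)
  expect_identical(a1, a2)
  expect_equal(a1$left$label, man$outcome[3])
})

test_that("baseline classifier separates default classes but not null ones", {
  # degenerate all-zero segment defaults to drop
  seg <- example_segment("catch")
  zero <- seg
  for (w in c("left", "right"))
    zero[[w]] <- lapply(zero[[w]], function(x) x * 0)
  expect_equal(oracle_classify(zero), "drop")

  # default simulator: well above the majority-class rate on 60 attempts
  man <- generate_dataset(dataset_config(30, 30), seed = 5)
  pred <- vapply(seq_len(nrow(man)), function(i) {
    r <- materialize_attempt(man, i)
    ev <- detect_trigger(r$left, r$right)
    oracle_classify(segment_attempt(r$left, r$right, ev))
  }, character(1))
  expect_gt(mean(pred == man$outcome), 0.5)

  # class effect switched off: accuracy falls to chance on a balanced set
  null_par <- sim_params(class_effect = 0)
  man0 <- generate_dataset(dataset_config(30, 30, params = null_par), seed = 303)
  pred0 <- vapply(seq_len(nrow(man0)), function(i) {
    r <- materialize_attempt(man0, i)
    ev <- detect_trigger(r$left, r$right)
    oracle_classify(segment_attempt(r$left, r$right, ev))
  }, character(1))
  expect_lt(abs(mean(pred0 == man0$outcome) - 0.5), 0.15)
})

test_that("post-impact acceleration energy separates the classes", {
  # the pre-registered class statistic is recoverable on a modest sample
  man <- generate_dataset(dataset_config(20, 20), seed = 77)
  stat <- vapply(seq_len(nrow(man)), function(i) {
    r <- materialize_attempt(man, i)
    ev <- detect_trigger(r$left, r$right)
    seg <- segment_attempt(r$left, r$right, ev)
    a <- acc_norm_of(list(channels = seg$left))
    t <- (seq_along(a) - 1) / 1000
    sqrt(mean((a - median(a))[t >= 1.5 & t < 3]^2))
  }, numeric(1))
  expect_gt(mean(stat[man$outcome == "drop"]),
            mean(stat[man$outcome == "catch"]))
  expect_lt(t.test(stat ~ man$outcome)$p.value, 0.01)
})
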