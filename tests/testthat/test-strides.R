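events_tbl <- function(ic, fc) {
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(t = ic, kind = "IC",
                   side = rep(c("A", "B"), length.out = length(ic))),
    tibble::tibble(t = fc, kind = "FC", side = NA_character_)
  ), t)
}

test_that("stride bookkeeping reproduces the hand-traced event sequence", {
  st <- assemble_strides(events_tbl(c(0, 0.5, 1.0), c(0.15, 0.65, 1.15)))
  expect_equal(nrow(st), 1)
  expect_equal(st$stride_time, 1.0)
  expect_equal(c(st$step_time0, st$step_time1), c(0.5, 0.5))
  expect_equal(st$stance_time, 0.65)
  expect_equal(st$swing_time, 0.35)
  expect_equal(st$double_support_time, 0.30)
  expect_true(st$valid)
})

test_that("quality control flags missing contacts and implausible timing", {
  st <- assemble_strides(events_tbl(c(0, 0.5, 1.0), c(0.15)))
  expect_false(st$valid)
  expect_equal(st$invalid_reason, "missing FC")

  st2 <- assemble_strides(events_tbl(c(0, 0.5, 3.5), c(0.15, 0.65, 3.0)))
  expect_false(st2$valid)
  expect_equal(st2$invalid_reason, "stride time out of range")

  # stance fraction outside the plausible band
  st3 <- assemble_strides(events_tbl(c(0, 0.5, 1.0), c(0.15, 0.95)))
  expect_equal(st3$invalid_reason, "stance fraction out of range")

  expect_error(assemble_strides(events_tbl(c(0, 0.5), 0.15)), "complete stride")
})

test_that("turn strides are excluded from the valid set", {
  # steady 0.55 s steps with one 1.05 s turnaround pause: the strides
  # spanning it are long (but physiologically plausible) and must be
  # attributed to the turn, not to gait
  ic <- c(seq(0, 5.5, by = 0.55), 6.6, seq(7.15, 12.1, by = 0.55))
  fc <- head(ic, -1) + 0.15
  st <- assemble_strides(events_tbl(ic, fc))
  expect_true("turn" %in% st$invalid_reason)
  expect_true(all(st$stride_time[!is.na(st$invalid_reason) &
                                   st$invalid_reason == "turn"] >
                    1.4 * median(st$stride_time)))
})

test_that("vertical excursion integrates the closed-form trajectory", {
  fs <- 128
  f <- 1 / 0.55
  h0 <- 0.04
  t <- seq(0, 10, by = 1 / fs)
  # downward-positive acceleration of height -h0/2*cos(2 pi f t)
  sig <- make_signal(-(h0 / 2) * (2 * pi * f)^2 * cos(2 * pi * f * t))
  h <- stride_vertical_displacement(sig, 0, 2 / f)
  expect_equal(h, h0, tolerance = 0.05)

  expect_equal(stride_vertical_displacement(make_signal(rep(0, 1280)), 0, 2),
               0)

  ramp <- make_signal(seq(-1, 1, length.out = 1281))
  expect_lt(stride_vertical_displacement(ramp, 0, 2), 0.1 * h0)

  expect_error(stride_vertical_displacement(sig, 0, 99), "past the signal")
})

test_that("the inverted-pendulum formula is exact and monotone", {
  expect_identical(inverted_pendulum_stride_length(0, 1.0), 0)
  expect_equal(inverted_pendulum_stride_length(0.02, 1.0),
               2 * sqrt(2 * 1.0 * 0.02 - 0.02^2), tolerance = 1e-15)
  expect_equal(inverted_pendulum_stride_length(0.02, 1.0), 0.3979950,
               tolerance = 1e-7)
  expect_equal(inverted_pendulum_stride_length(1, 1), 2)
  expect_error(inverted_pendulum_stride_length(1.1, 1), "exceed")
  expect_error(inverted_pendulum_stride_length(-0.1, 1), "non-negative")

  h <- seq(0, 1, length.out = 200)
  expect_true(all(diff(inverted_pendulum_stride_length(h, 1.0)) > 0))
})

test_that("derived spatial measures follow their defining ratios", {
  st <- assemble_strides(events_tbl(c(0, 0.5, 1.0, 1.5, 2.0),
                                    c(0.15, 0.65, 1.15, 1.65)))
  sig <- make_signal(rep(0, 128 * 3 + 1))
  out <- compute_stride_features(st, sig, l = 1.0)
  expect_equal(out$gait_speed, out$stride_length / out$stride_time)
  expect_equal(out$step_length, out$stride_length / 2)
  expect_equal(out$cadence, rep(120, nrow(out)))
})

test_that("temporal identities hold exactly for every assembled stride", {
  total <- 0
  for (seed in 1:4) {
    sim <- walk_fixture(stride_time = c(0.9, 1.1, 1.3, 1.5)[seed],
                        duration = 60, snr_db = 20, seed = 20 + seed,
                        step_asymmetry = c(0, 0.02, 0, 0.03)[seed])
    st <- assemble_strides(detect_gait_events(sim$signal))
    ok <- st[st$valid, ]
    total <- total + nrow(ok)
    expect_identical(ok$stride_time, ok$step_time0 + ok$step_time1)
    expect_identical(ok$stride_time, ok$stance_time + ok$swing_time)
    expect_true(all(ok$double_support_time >= 0 &
                      ok$double_support_time < ok$stride_time))
    expect_true(all(ok$ic0 < ok$ic1 & ok$ic1 < ok$ic2))
  }
  expect_gt(total, 100)
})

test_that("programmed stride timing and length are recovered from raw signal", {
  sim <- walk_fixture(stride_time = 1.2, h0 = 0.035, duration = 90,
                      snr_db = 20, seed = 31)
  st <- extract_gait(sim$recording, l = 1.0)
  ok <- st[st$valid, ]
  expect_gt(nrow(ok), 50)
  expect_lt(abs(median(ok$stride_time) - 1.2), 1 / 128)
  target <- inverted_pendulum_stride_length(0.035, 1.0)
  expect_lt(abs(median(ok$stride_length) - target) / target, 0.05)
})
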