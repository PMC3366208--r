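test_that("cumulative distance unwraps the cyclic track", {
  expect_equal(cumulative_distance(12, 0, 5, 52), 7)
  expect_equal(cumulative_distance(5, 1, 5, 52), 52)
  expect_equal(cumulative_distance(3, 0, 5, 52), -2)
  # additive across lap boundaries: differences do not depend on the
  # start-unit choice
  for (s in c(1, 20, 45)) {
    d1 <- cumulative_distance(10, 1, s, 52)
    d2 <- cumulative_distance(30, 2, s, 52)
    expect_equal(d2 - d1, 72)
  }
  expect_error(cumulative_distance(1, 0, 1, 0), "positive")
})

test_that("unit separations convert to nm at 5.70 nm per unit", {
  expect_equal(step_size_nm(7), 39.9)
  expect_equal(step_size_nm(0), 0)
  expect_equal(step_size_nm(6), 34.2)
  expect_error(step_size_nm(1, spacing = 0), "positive")
})

test_that("programmed staircases are recovered exactly by extract_steps", {
  # ten forward steps of 6 units
  tr <- make_fixture_staircase(rep(6, 10), k_dwell = 0.02, seed = 101,
                               initial_sep = 6)
  ev <- extract_steps(tr)
  expect_equal(nrow(ev), 11)           # initial config + 10 steps
  expect_equal(ev$separation, rep(6, 11))
  expect_true(all(ev$direction == "forward"))
  # one programmed backstep is counted as exactly one
  tr2 <- make_fixture_staircase(c(6, 6, -2, 6), k_dwell = 0.02, seed = 102,
                                initial_sep = 6)
  ev2 <- extract_steps(tr2)
  expect_identical(ev2$direction, attr(tr2, "expected_steps")$direction)
  expect_equal(count_backsteps(ev2)$n_back, 1)
  expect_equal(count_backsteps(ev2)$fraction, 1 / 5)
  # mixed fixture equals a brute-force frame scan
  tr3 <- make_fixture_staircase(c(4, -3, 5, 6, -2, 7), k_dwell = 0.01,
                                seed = 103, initial_sep = 5)
  ev3 <- extract_steps(tr3)
  bf <- scan_steps_bruteforce(tr3)
  expect_equal(nrow(ev3), nrow(bf))
  expect_equal(ev3$frame, bf$frame)
  expect_equal(ev3$separation, abs(bf$d1 - bf$d2))
})

test_that("a constant both-bound block collapses to one event at its last frame", {
  frames <- data.frame(frame = 1:40, state1 = 2L, state2 = 2L,
                       swung1 = FALSE, swung2 = FALSE,
                       unit1 = 1L, unit2 = 4L, d1 = 0, d2 = 3)
  tr <- new_trajectory(frames)
  ev <- extract_steps(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 40)
  expect_equal(ev$separation, 3)
})

test_that("dwell extraction matches the generator and attributes heads", {
  tr <- make_fixture_staircase(rep(5, 30), k_dwell = 0.01, seed = 104,
                               initial_sep = 5)
  dw <- extract_dwells(tr)
  expect_equal(dw$duration, attr(tr, "dwell_durations"))
  # heads alternate steps, so attributed heads alternate too
  heads <- dw$head[!is.na(dw$head)]
  expect_true(all(abs(diff(heads)) == 1))
})

test_that("dwell rate fits recover the generator across the printed regime", {
  for (k in c(0.004, 0.012, 0.015)) {
    t <- sample_dwells(2000, k, seed = round(1e5 * k))
    fit <- fit_dwell_rate(t)
    expect_lt(abs(fit$k12 - k) / k, 0.10)
    expect_equal(fit$mean_lifetime, 1 / fit$k12)
    # maximum-likelihood cross-check agrees with the histogram fit
    expect_lt(abs(fit$k_ml - fit$k12) / k, 0.15)
  }
  expect_error(fit_dwell_rate(c(10, 20, 30)), "too few")
  expect_error(fit_dwell_rate(rep(50, 100)), "degenerate")
})

test_that("step-size Gaussian fit recovers synthetic distributions", {
  # degenerate all-equal data: (value, 0), the short-leg case
  expect_equal(fit_step_gaussian(rep(3, 50)), c(mean = 3, sd = 0))
  expect_equal(unname(fit_step_gaussian(c(4, 6))[1]), 5, tolerance = 1e-3)
  set.seed(43)
  x <- round(rnorm(500, 6.07, 0.95))
  fit <- fit_step_gaussian(x)
  expect_lt(abs(fit["mean"] - 6.07), 3 * 0.95 / sqrt(500) + 0.15)
  expect_error(fit_step_gaussian(3), "at least 2")
})

test_that("duty ratios count tight frames and obey the dimer inequality", {
  n <- 100
  frames <- data.frame(frame = 1:n,
                       state1 = rep(c(2L, 0L), c(51, 49)),
                       state2 = rep(c(0L, 2L), c(51, 49)),
                       swung1 = FALSE, swung2 = FALSE,
                       unit1 = NA_integer_, unit2 = NA_integer_,
                       d1 = 0, d2 = 0)
  frames$unit1[frames$state1 > 0] <- 1L
  frames$unit2[frames$state2 > 0] <- 5L
  tr <- new_trajectory(frames)
  expect_equal(duty_ratio(tr, 1), 0.51)
  expect_equal(duty_ratio(tr, 2), 0.49)
  # alternating heads tight on every frame: dimer ratio 1
  expect_equal(duty_ratio(tr, "either"), 1)
  expect_gte(duty_ratio(tr, "either"),
             max(duty_ratio(tr, 1), duty_ratio(tr, 2)))
})

test_that("the no-interaction dimer duty prediction is 1 - (1-r)^2", {
  expect_equal(round(predict_dimer_duty(0.51), 2), 0.76)
  expect_equal(round(predict_dimer_duty(0.55), 2), 0.80)
  expect_equal(round(predict_dimer_duty(0.54), 2), 0.79)
  expect_equal(predict_dimer_duty(0), 0)
  expect_equal(predict_dimer_duty(1), 1)
  expect_error(predict_dimer_duty(1.2), "\\[0, 1\\]")
})

test_that("velocity fits recover exact and noisy staircase slopes", {
  # exact line D = 0.05 t
  frames <- data.frame(frame = 1:200, state1 = 2L, state2 = 2L,
                       swung1 = FALSE, swung2 = FALSE,
                       unit1 = 1L, unit2 = 1L,
                       d1 = 0.05 * (1:200), d2 = 0.05 * (1:200))
  tr <- new_trajectory(frames)
  expect_equal(velocity_fit(tr)$slope, 0.05, tolerance = 1e-9)
  # noisy synthetic staircase with known mean rate, within 5%
  tr2 <- make_fixture_staircase(rep(6, 60), k_dwell = 0.05, seed = 105,
                                initial_sep = 6, search_frames = 10L)
  rate <- with(attributes(tr2),
               sum(expected_steps$separation[1]) * 0)  # placeholder
  v <- velocity_fit(tr2, window_frames = nrow(tr2), window_laps = 99)$slope
  # generator advances 6 units per (dwell + gap) cycle on average
  cyc <- mean(attr(tr2, "dwell_durations")) + 10
  expect_lt(abs(v - 6 / cyc) / (6 / cyc), 0.2)
})

test_that("coexistence tables equal a brute-force recount", {
  tr <- make_fixture_staircase(c(5, 6, -3, 4), k_dwell = 0.02, seed = 106)
  co <- coexistence_table(tr)
  expect_equal(unclass(co$counts), recount_coexistence(tr),
               ignore_attr = TRUE)
  expect_equal(co$counts["F", "F"], 0)
  expect_equal(co$counts["S", "S"], 0)
  # symmetric combination adds mirror cells, keeps the diagonal
  expect_equal(co$combined["L", "T"], co$counts["L", "T"] + co$counts["T", "L"])
  # single-frame trajectory: exactly one nonzero cell
  one <- new_trajectory(data.frame(frame = 1L, state1 = 2L, state2 = 1L,
                                   swung1 = FALSE, swung2 = FALSE,
                                   unit1 = 1L, unit2 = 4L, d1 = 0, d2 = 3))
  expect_equal(sum(coexistence_table(one)$counts), 1)
  expect_equal(coexistence_table(one)$counts["T", "L"], 1)
})

test_that("the apex angle reproduces the constant-angle geometry", {
  a <- apex_angle(0.6 * 34.2, 34.2)   # L/s = 0.6
  expect_equal(unname(a["theta"]), 112.9, tolerance = 0.05)
  expect_equal(unname(a["leg_axis_angle"]), 33.55, tolerance = 0.03)
  expect_equal(unname(apex_angle(10, 20)["theta"]), 180)
  expect_equal(unname(apex_angle(10, 1e-9)["theta"]), 0, tolerance = 1e-5)
  expect_error(apex_angle(10, 21), "span")
})

test_that("step-size/leg-length lines match closed-form least squares", {
  # exact fit recovered
  n_iq <- c(2, 4, 6)
  y <- 4.38 * n_iq + 8.52
  f <- fit_step_vs_leg(y, n_iq = n_iq)
  expect_equal(unname(f$vs_iq), c(4.38, 8.52), tolerance = 1e-9)
  # published per-model step sizes give the published line (printed rounding)
  steps <- c(17.1, 26.45, 34.60)
  f2 <- fit_step_vs_leg(steps, n_iq = n_iq, leg_nm = c(9.3, 14.60, 19.90))
  expect_equal(unname(f2$vs_iq["slope"]), 4.38, tolerance = 0.01)
  expect_equal(unname(f2$vs_iq["intercept"]), 8.52, tolerance = 0.05)
  # the leg-on-step line is the one that is near-proportional
  expect_equal(unname(f2$leg_vs_step["slope"]), 0.6, tolerance = 0.02)
  # through-origin variant on proportional data returns the ratio
  f3 <- fit_step_vs_leg(c(2, 4, 6), leg_nm = c(1, 2, 3))
  expect_equal(unname(f3$leg_vs_step_origin), 0.5, tolerance = 1e-9)
  expect_error(fit_step_vs_leg(c(1, 2), n_iq = c(2, 2)), "degenerate")
})
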