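test_that("first update from body temperature is the pure proportional response", {
  ctrl <- pi_controller(90)
  ctrl <- update_controller(ctrl, tip_T = 37, dt = 0.25)
  expect_equal(ctrl$V, 1.15 * 53)
  ## the error is accumulated after the output is formed
  expect_equal(ctrl$integral, 53 * 0.25)
})

test_that("at zero error the output is the integral term alone", {
  ctrl <- pi_controller(90)
  ctrl$integral <- 120
  ctrl <- update_controller(ctrl, tip_T = 90, dt = 0.25)
  expect_equal(ctrl$V, 0.06 * 120)
  ## zero error leaves the accumulator unchanged
  expect_equal(ctrl$integral, 120)
})

test_that("output clamps at zero and the integrator freezes while clamped", {
  ctrl <- pi_controller(90)
  ctrl$integral <- 5
  ctrl <- update_controller(ctrl, tip_T = 120, dt = 0.25)
  expect_identical(ctrl$V, 0)
  expect_true(ctrl$clamped)
  expect_equal(ctrl$integral, 5)   # frozen: no windup
  ## recovery: once the error allows a positive output, accumulation resumes
  ctrl <- update_controller(ctrl, tip_T = 80, dt = 0.25)
  expect_gt(ctrl$V, 0)
  expect_equal(ctrl$integral, 5 + 10 * 0.25)
  expect_error(update_controller(ctrl, 80, dt = 0), "positive")
})

test_that("cooldown mode forces zero voltage permanently", {
  ctrl <- pi_controller(90)
  ctrl <- update_controller(ctrl, 37, 0.25)
  ctrl <- cooldown_mode(ctrl)
  expect_identical(ctrl$V, 0)
  ctrl <- update_controller(ctrl, 37, 0.25)   # even with a large error
  expect_identical(ctrl$V, 0)
})

test_that("closed loop reaches and holds the 90 C band in all scenarios", {
  for (sc in c("a", "b", "c")) {
    r <- study_run(sc, 90)
    st <- r$step_trace
    late <- st$time_s > 200 & st$time_s <= 240   # settled heating phase
    expect_true(all(abs(st$tip_temp_C[late] - 90) < 1),
                label = paste("band holding, scenario", sc))
  }
  ## transient overshoot under 3 C for the perfused-background geometries
  for (sc in c("a", "b")) {
    st <- study_run(sc, 90)$step_trace
    heating <- st$time_s <= 240
    expect_lt(max(st$tip_temp_C[heating]) - 90, 3)
  }
})

test_that("voltage is never negative in a full closed-loop run", {
  for (sc in c("a", "c")) {
    r <- study_run(sc, 90)
    expect_true(all(r$step_trace$voltage_V >= 0))
    ## cooldown phase: identically zero
    cool <- r$step_trace$time_s > 240
    expect_true(all(r$step_trace$voltage_V[cool] == 0))
  }
})
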