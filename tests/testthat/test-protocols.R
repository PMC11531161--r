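# Protocol mechanics are exercised at coarse solver settings; the
# full-resolution endpoint values are checked in the acceptance suite.

test_that("a pump-speed ramp returns one summary row per speed", {
  rows <- ramp_rpm(make_systolic_dysfunction(), c(3000, 4000),
                   steps_per_beat = fast$steps_per_beat, tol = fast$tol)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$rpm, c(3000, 4000))
  expect_lt(rows$cardiac_index[1], rows$cardiac_index[2])
  expect_equal(rows$stressed_blood_volume, c(2036, 2036))  # V_s held fixed
  expect_error(ramp_rpm(linear_model(), 3000), "no pump")
})

test_that("down-titration stops at the last fully feasible volume", {
  m <- set_pump_speed(make_systolic_dysfunction(), 4000)
  tit <- titrate_sbv(m, step = 300, direction = "down",
                     steps_per_beat = fast$steps_per_beat, tol = fast$tol)
  expect_s3_class(tit, "fontan_titration")
  expect_equal(tit$delta_sbv %% 300, 0)
  expect_lt(tit$delta_sbv, 0)
  # every accepted step is feasible; the last explored one is not
  steps <- tit$steps
  expect_false(steps$feasible[nrow(steps)])
  expect_true(all(steps$feasible[-nrow(steps)]))
  # the converged endpoint never has a sub-zero per-beat minimum
  s <- tit$summary
  expect_gte(min(s$min_p_sa, s$min_p_sv, s$min_v_sa, s$min_v_sv,
                 s$min_v_cas, s$min_v_cvs, s$min_v_cap, s$min_v_cvp), 0)
  expect_match(tit$stop_reason,
               "min-below-zero-guard|mean-pressure-near-zero")
})

test_that("up-titration returns immediately on a feasible model", {
  m <- set_pump_speed(make_systolic_dysfunction(), 3000)
  tit <- titrate_sbv(m, step = 100, direction = "up",
                     steps_per_beat = fast$steps_per_beat, tol = fast$tol)
  expect_equal(tit$delta_sbv, 0)
  expect_equal(nrow(tit$steps), 1)
})

test_that("up-titration restores feasibility of a drained circulation", {
  m <- set_pump_speed(make_high_pvr(), 3500)
  tit <- titrate_sbv(m, step = 100, direction = "up",
                     steps_per_beat = fast$steps_per_beat, tol = fast$tol)
  expect_gt(tit$delta_sbv, 0)
  s <- tit$summary
  expect_gte(min(s$min_p_sa, s$min_p_sv, s$min_v_sa, s$min_v_sv), 0)
  # one step less volume was infeasible
  prev <- tit$steps[nrow(tit$steps) - 1, ]
  expect_false(prev$feasible)
})

test_that("titration traces are deterministic", {
  m <- set_pump_speed(make_avvr(), 4000)
  run <- function() titrate_sbv(m, step = 300, direction = "down",
                                steps_per_beat = fast$steps_per_beat,
                                tol = fast$tol)
  t1 <- run(); t2 <- run()
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$final_sbv, t2$final_sbv)
})

test_that("titration honours its volume bounds", {
  m <- set_pump_speed(make_high_pvr(), 4000)
  expect_error(titrate_sbv(m, step = 100, direction = "up", max_sbv = 2000,
                           steps_per_beat = fast$steps_per_beat,
                           tol = fast$tol),
               "bound")
})

test_that("the resistance sweep needs more volume at higher resistance", {
  rows <- sweep_pvri(R_ap_values = c(0.06, 0.155), resolution = 50,
                     steps_per_beat = fast$steps_per_beat, tol = fast$tol)
  expect_equal(nrow(rows), 2)
  expect_lt(rows$stressed_blood_volume[1], rows$stressed_blood_volume[2])
  expect_lt(rows$cvp[1], rows$cvp[2])
  expect_true(all(rows$min_p_sa >= 0))
  expect_true(all(rows$mean_sa_pressure >= 0))
})

test_that("the CVP threshold interpolates the sweep monotonically", {
  rows <- tibble::tibble(
    pvri = c(3.01, 3.96, 5.07, 6.02, 6.97, 8.08, 9.03),
    cvp = c(8.70, 11.4, 14.5, 17.1, 19.8, 22.9, 25.6))
  th <- cvp_vs_pvri_threshold(rows, 15)
  expect_gt(th, 5.07)
  expect_lt(th, 6.02)
  # an exact row hit returns that row's PVRI
  expect_equal(cvp_vs_pvri_threshold(rows, 8.70), 3.01)
  expect_equal(cvp_vs_pvri_threshold(rows, 14.5), 5.07)
  expect_error(cvp_vs_pvri_threshold(rows, 5), "outside")
  expect_error(cvp_vs_pvri_threshold(rows[1:2, ] |>
                 dplyr::mutate(cvp = rev(cvp)), 10), "monotone")
})
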