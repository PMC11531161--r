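sv <- chamber_params(E_es = 3, A = 0.35, B = 0.033, V0 = 0, T_es = 0.2)
sa <- chamber_params(E_es = 0.5, A = 0.06, B = 0.264, V0 = 5, T_es = 0.12,
                     activation_offset = -0.016)
tim <- timing_params(75)

test_that("normalized elastance follows the raised-cosine activation", {
  expect_equal(normalized_elastance(0, 0.2, 0.8), 0)
  expect_equal(normalized_elastance(0.2, 0.2, 0.8), 1)   # peak at end systole
  expect_equal(normalized_elastance(0.1, 0.2, 0.8), 0.5)
  expect_equal(normalized_elastance(0.5, 0.2, 0.8), 0)   # diastolic plateau
  # bounded in [0, 1], zero on [2 T_es, T_c), periodic
  t <- seq(0, 2.4, by = 0.001)
  e <- normalized_elastance(t, 0.2, 0.8)
  expect_true(all(e >= 0 & e <= 1))
  plateau <- t %% 0.8 >= 0.4
  expect_true(all(e[plateau] == 0))
  expect_equal(e, normalized_elastance(t + 0.8, 0.2, 0.8))
})

test_that("elastance timing parameters are validated", {
  expect_error(normalized_elastance(0.1, T_es = 0, T_c = 0.8), "positive")
  expect_error(normalized_elastance(0.1, T_es = 0.5, T_c = 0.8), "exceed")
  expect_error(chamber_params(E_es = 0, A = 1, B = 1, V0 = 0, T_es = 0.2),
               "E_es")
  expect_error(timing_params(75, T_c = 1), "60 / heart_rate")
})

test_that("EDPVR is exponential and extends below the unstressed volume", {
  expect_equal(end_diastolic_pressure(sv$V0, sv), 0)
  expect_equal(end_diastolic_pressure(sa$V0, sa), 0)
  expect_equal(end_diastolic_pressure(100, sv), 9.13942362223026,
               tolerance = 1e-10)
  expect_equal(end_diastolic_pressure(20, sa), 3.08743955694703,
               tolerance = 1e-10)
  # no clamping below V0: small negative filling pressures are real
  expect_lt(end_diastolic_pressure(2, sa), 0)
  expect_gt(end_diastolic_pressure(2, sa), -sa$A)
})

test_that("ESPVR is linear in volume", {
  expect_equal(end_systolic_pressure(sv$V0, sv), 0)
  expect_equal(end_systolic_pressure(100, sv), 300)
  sv_weak <- chamber_params(E_es = 1.215, A = 0.35, B = 0.033, V0 = 0,
                            T_es = 0.2)
  expect_equal(end_systolic_pressure(100, sv_weak), 121.5)
})

test_that("chamber pressure blends the two relations by activation", {
  # activation 0 and 1 collapse to the pure EDPVR / ESPVR branches
  expect_equal(chamber_pressure(100, 0.5, sv, tim),
               end_diastolic_pressure(100, sv))
  expect_equal(chamber_pressure(100, 0.2, sv, tim),
               end_systolic_pressure(100, sv))
  # half activation at t = 0.1
  expect_equal(chamber_pressure(100, 0.1, sv, tim), 154.569711811151,
               tolerance = 1e-10)
})

test_that("chamber pressure is non-decreasing in volume above V0", {
  for (t in c(0, 0.07, 0.13, 0.31, 0.62)) {
    v <- seq(sv$V0, sv$V0 + 150, by = 1)
    expect_true(all(diff(chamber_pressure(v, t, sv, tim)) >= 0))
    v <- seq(sa$V0, sa$V0 + 40, by = 0.5)
    expect_true(all(diff(chamber_pressure(v, t, sa, tim)) >= 0))
  }
})

test_that("chamber pressure is periodic and the atrium leads by 16 ms", {
  t <- seq(0, 0.8, by = 0.002)
  expect_equal(chamber_pressure(30, t, sa, tim),
               chamber_pressure(30, t + 0.8, sa, tim))
  # atrial activation peak at t = T_es,SA - 0.016 on the global clock
  e_sa <- normalized_elastance(t + 0.016, sa$T_es, tim$T_c)
  expect_equal(t[which.max(e_sa)], sa$T_es - 0.016)
  expect_equal(max(e_sa), 1)
})
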