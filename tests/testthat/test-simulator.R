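test_that("diode valves conduct forward only", {
  expect_equal(valve_flow(5, 10, 0.001), 0)
  expect_equal(valve_flow(10, 5, 0.001), 5000)
  expect_equal(valve_flow(7, 7, 0.001), 0)
  expect_equal(regurgitant_flow(10, 100, 0.225), 0)
  expect_equal(regurgitant_flow(100, 10, 0.225), 400)
  expect_equal(regurgitant_flow(100, 10, NULL), 0)  # competent valve
})

test_that("aortic node pressure solves the root balance", {
  m <- baseline_fontan()
  # pump absent, valve reverse-biased: no flow, node floats to P_Cas
  expect_equal(aortic_node_pressure(10, 80, m), 80)
  # pump absent, valve conducting: resistive divider
  expect_equal(aortic_node_pressure(100, 90, m), 99.6774193548387,
               tolerance = 1e-12)
  # pump running: flow balance holds at the returned pressure
  mp <- set_pump_speed(baseline_fontan(), 3500)
  q0 <- pump_flow(0, mp$pump) * 1000 / 60
  for (psv in c(5, 60, 120)) {
    pn <- aortic_node_pressure(psv, 85, mp)
    lhs <- valve_flow(psv, pn, mp$valves$R_AV) + q0
    rhs <- (pn - 85) / mp$systemic$R_c
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("compartment rates sum to zero at arbitrary states", {
  set.seed(42)
  models <- list(make_systolic_dysfunction(), make_avvr(),
                 set_pump_speed(make_high_pvr(), 3500))
  for (m in models) {
    for (i in 1:10) {
      st <- random_state(m)
      t <- stats::runif(1, 0, m$timing$T_c)
      d <- circulation_derivatives(st, t, m)
      expect_lt(abs(sum(d)), 1e-12 * max(1, max(abs(d))))
    }
  }
})

test_that("the R reference derivatives match the compiled core", {
  set.seed(43)
  models <- list(make_systolic_dysfunction(), make_diastolic_dysfunction(),
                 make_avvr(), set_pump_speed(make_high_pvr(), 4000))
  for (m in models) {
    par <- fontansim:::pack_model(m)
    for (i in 1:10) {
      st <- random_state(m)
      t <- stats::runif(1, 0, m$timing$T_c)
      expect_equal(unname(circulation_derivatives(st, t, m)),
                   as.numeric(fontansim:::.fontan_derivs_cpp(par, st, t)),
                   tolerance = 1e-10)
    }
  }
})

test_that("frozen-activation rates match an independent linear-network solve", {
  m <- linear_model()
  e <- 0.3
  # independent oracle: Laplacian of the resistor network acting on the
  # pressure vector (order SA, SV, Cas, Cvs, Cap, Cvp)
  k <- c(e * m$sa$E_es, e * m$sv$E_es, 1 / m$systemic$C_a,
         1 / m$systemic$C_v, 1 / m$pulmonary$C_a, 1 / m$pulmonary$C_v)
  v0 <- c(m$sa$V0, m$sv$V0, 0, 0, 0, 0)
  edges <- rbind(
    c(1, 2, m$valves$R_AVV),
    c(2, 3, m$valves$R_AV + m$systemic$R_c),
    c(3, 4, m$systemic$R_a),
    c(4, 5, m$systemic$R_v + m$pulmonary$R_c),
    c(5, 6, m$pulmonary$R_a),
    c(6, 1, m$pulmonary$R_v))
  L <- matrix(0, 6, 6)
  for (j in seq_len(nrow(edges))) {
    a <- edges[j, 1]; b <- edges[j, 2]; g <- 1 / edges[j, 3]
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
  }
  set.seed(44)
  for (i in 1:5) {
    st <- random_state(m)
    p <- k * (st - v0)
    oracle <- as.numeric(-L %*% p)
    got <- circulation_derivatives(st, 0.123, m, freeze_activation = e,
                                   diode_mode = "resistor")
    expect_equal(unname(got), oracle, tolerance = 1e-9)
  }
})

test_that("the frozen linear model relaxes to the analytic DC equilibrium", {
  m <- linear_model(sbv = 800)
  e <- 0.3
  ss <- run_to_steady_state(m, freeze_activation = e,
                            diode_mode = "resistor", tol = 1e-9)
  k <- c(e * m$sa$E_es, e * m$sv$E_es, 1 / m$systemic$C_a,
         1 / m$systemic$C_v, 1 / m$pulmonary$C_a, 1 / m$pulmonary$C_v)
  v0 <- c(m$sa$V0, m$sv$V0, 0, 0, 0, 0)
  p_star <- (800 - sum(v0)) / sum(1 / k)
  expect_equal(unname(ss$final_state), v0 + p_star / k, tolerance = 1e-5)
})

test_that("total stressed volume is conserved over long runs", {
  sim <- simulate_fontan(make_avvr(), n_beats = 100, record = "last")
  expect_lt(abs(sim$volume_drift), 1e-8)
  expect_equal(sum(sim$final_state), 2015, tolerance = 1e-8)
})

test_that("the periodic steady state is independent of the initial split", {
  m <- make_systolic_dysfunction()
  set.seed(45)
  s1 <- beat_summary(run_to_steady_state(m, init = random_state(m)))
  s2 <- beat_summary(run_to_steady_state(m, init = random_state(m)))
  s3 <- beat_summary(run_to_steady_state(m))  # default split
  for (col in c("cardiac_index", "mean_arterial_pressure", "cvp",
                "mean_sa_pressure")) {
    expect_equal(s1[[col]], s2[[col]], tolerance = 1e-3)
    expect_equal(s1[[col]], s3[[col]], tolerance = 1e-3)
  }
})

test_that("beat-averaged flow is equal through every series element", {
  for (m in list(make_diastolic_dysfunction(),
                 set_pump_speed(make_systolic_dysfunction(), 3500))) {
    ss <- run_to_steady_state(m)
    st <- ss$beat_stats
    q_root <- st[["Q_AV"]] + st[["Q_pump"]]
    flows <- c(root = q_root, ras = st[["Q_ras"]], vs_cp = st[["Q_vs_cp"]],
               rap = st[["Q_rap"]], rvp = st[["Q_rvp"]],
               avv_net = st[["Q_AVV"]] - st[["Q_reg"]])
    expect_lt(max(flows) - min(flows), 0.1)
  }
})

test_that("an enabled pump at zero speed behaves like no pump", {
  m0 <- make_systolic_dysfunction()
  m0$pump <- NULL
  m1 <- make_systolic_dysfunction()   # pump present, rpm 0, disabled
  s0 <- simulate_fontan(m0, n_beats = 5)
  s1 <- simulate_fontan(m1, n_beats = 5)
  expect_identical(s0$trajectory$P_ao, s1$trajectory$P_ao)
  expect_identical(s0$final_state, s1$final_state)
})

test_that("the compiled integrator agrees with an adaptive reference solver", {
  m <- make_systolic_dysfunction()
  y0 <- run_to_steady_state(m)$final_state
  rhs <- function(t, y, p)
    list(circulation_derivatives(stats::setNames(y, names(y0)), t, m))
  out <- deSolve::lsoda(y0, c(0, 0.8, 1.6), rhs, rtol = 1e-8, atol = 1e-8,
                        hmax = 0.001)
  sim <- simulate_fontan(m, n_beats = 2, init = y0)
  expect_equal(unname(sim$final_state),
               unname(out[nrow(out), -1]), tolerance = 1e-4)
})

test_that("non-convergence raises a convergence error", {
  m <- make_systolic_dysfunction()
  expect_error(run_to_steady_state(m, max_beats = 3, tol = 1e-12),
               "steady state")
})
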