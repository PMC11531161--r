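test_that("the baseline parameterization carries the standard values", {
  m <- baseline_fontan()
  expect_equal(m$timing$T_c, 0.8)
  expect_equal(m$sv$E_es, 3); expect_equal(m$sv$T_es, 0.2)
  expect_equal(m$sa$E_es, 0.5); expect_equal(m$sa$V0, 5)
  expect_equal(m$sa$activation_offset, -0.016)
  expect_equal(m$systemic$R_a, 0.7); expect_equal(m$systemic$C_v, 70)
  expect_equal(m$pulmonary$C_a, 13)
  expect_equal(m$pump$K_A, 3.45e-6)
  expect_false(m$pump$enabled)
  expect_null(m$valves$R_AVVR)
  expect_equal(pvri_from_resistances(m$pulmonary$R_a, m$pulmonary$R_c,
                                     m$pulmonary$R_v, m$bsa),
               2.05833333333333, tolerance = 1e-10)
})

test_that("scenario factories apply exactly their named overrides", {
  sys <- make_systolic_dysfunction()
  expect_equal(sys$sv$E_es, 1.215)
  expect_equal(sys$stressed_blood_volume, 2036)
  expect_equal(sys$pulmonary$R_a, 0.06)
  expect_equal(sys$sv$B, 0.033)  # everything else at baseline

  dia <- make_diastolic_dysfunction()
  expect_equal(dia$sv$B, 0.0511)
  expect_equal(dia$stressed_blood_volume, 1999)
  expect_equal(dia$sv$E_es, 3)

  reg <- make_avvr()
  expect_equal(reg$valves$R_AVVR, 0.225)
  expect_equal(reg$stressed_blood_volume, 2015)

  pvr <- make_high_pvr()
  expect_equal(pvr$pulmonary$R_a, 0.23)
  expect_equal(pvr$stressed_blood_volume, 1903)
  expect_equal(pvr$sv$E_es, 3)  # baseline contractility
  expect_null(pvr$valves$R_AVVR)

  # the three PVRI-3 scenarios share the printed index
  for (m in list(sys, dia, reg))
    expect_equal(pvri_from_resistances(m$pulmonary$R_a, m$pulmonary$R_c,
                                       m$pulmonary$R_v, m$bsa),
                 3.01, tolerance = 0.01 / 3.01)
})

test_that("the sweep base combines both dysfunctions under assist", {
  m <- make_pvri_sweep_base()
  expect_equal(m$sv$E_es, 1.215)
  expect_equal(m$sv$B, 0.0511)
  expect_true(m$pump$enabled)
  expect_equal(m$pump$rpm, 3500)
  expect_equal(m$pulmonary$R_a, 0.06)
})

test_that("scenario configs round-trip through YAML losslessly", {
  cfg <- scenario_config("demo",
                         overrides = list(sv.E_es = 1.215,
                                          pulmonary.R_a = 0.06),
                         stressed_blood_volume = 2036, rpm = 3000,
                         rpm_schedule = c(3000, 3500, 4000),
                         protocol = "ramp")
  path <- withr::local_tempfile(fileext = ".yaml")
  save_scenario_config(cfg, path)
  back <- load_scenario_config(path)
  expect_equal(back, cfg)
  # and the model it builds matches applying the overrides by hand
  m <- as_fontan_model(back)
  expect_equal(m$sv$E_es, 1.215)
  expect_equal(m$pump$rpm, 3000)
})

test_that("bad configuration input is rejected with names", {
  expect_error(scenario_config("x", overrides = list(sv.Emax = 2)),
               "sv.Emax")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: x", "stressed_volume: 100"), path)
  expect_error(load_scenario_config(path), "stressed_volume")
  expect_error(load_scenario_config("no/such/file.yaml"), "no such file")
})

test_that("empty overrides reproduce the baseline model", {
  cfg <- scenario_config("plain", stressed_blood_volume = 1500)
  expect_equal(as_fontan_model(cfg), baseline_fontan())
})

test_that("bundled scenario files load and build models", {
  dir <- system.file("scenarios", package = "fontansim")
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, 5)
  for (f in files) {
    cfg <- load_scenario_config(f)
    m <- as_fontan_model(cfg)
    expect_s3_class(m, "fontan_model")
    expect_gt(m$stressed_blood_volume, 0)
  }
  # the bundled systolic scenario equals the factory product
  sys <- as_fontan_model(load_scenario_config(
    file.path(dir, "systolic_dysfunction.yaml")))
  expect_equal(sys, make_systolic_dysfunction())
})

test_that("the parameter table lists every model constant with units", {
  pt <- parameter_table(make_avvr())
  expect_true(all(c("parameter", "value", "unit") %in% names(pt)))
  expect_true("valves.R_AVVR" %in% pt$parameter)
  expect_equal(pt$value[pt$parameter == "systemic.R_a"], 0.7)
  expect_equal(pt$unit[pt$parameter == "sv.E_es"], "mmHg/mL")
})
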