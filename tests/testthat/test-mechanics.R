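test_that("breath mechanics ratio arithmetic on a hand-built breath", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  n <- length(t)
  pressure <- c(8, rep(28, 99), rep(8, n - 100))
  volume <- c(seq(0, 10, length.out = 100), rep(0, n - 100))
  flow <- c(rep(2, 100), rep(-2, 20), rep(0, n - 120))
  rec <- manual_recording(t, pressure, flow, volume, weight = 1)
  segs <- manual_segments(1, 101, n, rec)
  mech <- breath_mechanics(rec, segs, weight = 1)
  expect_equal(mech$dP, 20)
  expect_equal(mech$PEEP_measured, 8)
  expect_equal(mech$V_T, 0)  # volume returned to baseline at sample 101
  segs <- manual_segments(1, 100, n, rec)
  mech <- breath_mechanics(rec, segs, weight = 1)
  expect_equal(mech$V_T, 10)
  expect_equal(mech$C_dyn, 0.5)
  expect_equal(mech$Flow_peak, 2)
  expect_false(mech$degenerate)
})

test_that("a zero-volume breath is flagged degenerate with zero compliance", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  rec <- manual_recording(t, pressure = c(8, rep(20, 199)),
                          flow = c(rep(0.5, 100), rep(-0.5, 100)),
                          volume = rep(0, 200), weight = 1)
  segs <- manual_segments(1, 100, 200, rec)
  mech <- breath_mechanics(rec, segs, weight = 1)
  expect_true(mech$degenerate)
  expect_equal(mech$C_dyn, 0)
})

test_that("ratio compliance from plateau-reaching simulated breaths recovers C_rs within 5%", {
  rec <- default_recording()
  mech <- breath_mechanics(rec, default_segments())
  expect_lt(abs(mean(mech$C_dyn) * rec$weight - 1.25) / 1.25, 0.05)
  # and agrees with the regression compliance within 10%
  cfit <- coef(fit_eom(rec, default_segments()))[["C"]]
  expect_lt(abs(mean(mech$C_dyn) * rec$weight - cfit) / cfit, 0.10)
})

test_that("equation-of-motion fit recovers exact model data to solver tolerance", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  set.seed(3)
  q_lpm <- pmax(sin(2 * pi * t), 0) * 6      # arbitrary inspiratory flow
  vol <- cumsum(q_lpm * 1000 / 60) / sr
  paw <- 5 + vol / 0.9 + 0.04 * q_lpm * 1000 / 60
  rec <- manual_recording(t, paw, q_lpm, vol)
  segs <- manual_segments(1, 120, length(t), rec)
  fit <- fit_eom(rec, segs)
  expect_equal(coef(fit)[["C"]], 0.9, tolerance = 1e-8)
  expect_equal(coef(fit)[["R"]], 0.04, tolerance = 1e-8)
  expect_equal(coef(fit)[["P0"]], 5, tolerance = 1e-8)
  expect_lt(fit$rms, 1e-10)
  expect_equal(unname(predict(fit)[1]), paw[1], tolerance = 1e-8)
})

test_that("fit recovers simulator ground truth despite circuit dynamics", {
  for (F in c(4, 8)) {
    rec <- simulate_ventilation(vent_settings(bias_flow = F, circuit_compliance = 1),
                                lung_params(), duration = 10)
    fit <- fit_eom(rec)
    expect_lt(abs(coef(fit)[["C"]] - 1.25) / 1.25, 0.05)
    expect_lt(abs(coef(fit)[["R"]] - 0.025) / 0.025, 0.15)
  }
})

test_that("linearly dependent volume and flow raise a rank-deficiency error", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  vol <- 10 * sin(2 * pi * t)
  rec <- manual_recording(t, pressure = 8 + vol, flow = vol * 60 / 1000,
                          volume = vol)
  segs <- manual_segments(1, 100, length(t), rec)
  expect_error(fit_eom(rec, segs), "rank-deficient")
})

test_that("hand-integrated energy example: 20 cmH2O over 10 mL is 0.01961 J", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  n <- length(t)
  # pressure steps to PEEP+20 before volume moves, so (P - PEEP) dV = 20 dV
  pressure <- c(8, rep(28, n - 1))
  volume <- c(0, seq(0, 10, length.out = 99), rep(10, n - 100))
  flow <- c(rep(2, 100), rep(-2, 20), rep(0, n - 120))
  rec <- manual_recording(t, pressure, flow, volume, weight = 1)
  segs <- manual_segments(1, 100, n, rec)
  E <- energy_per_breath(rec, segs)
  expect_equal(E, 200 * 98.0665e-6, tolerance = 1e-9)
  expect_equal(E, 0.01961, tolerance = 1e-3)
  expect_equal(mp_tidal(E, rate = 60, weight = 1), 1.1768, tolerance = 1e-3)
})

test_that("a null breath carries zero energy", {
  sr <- 200
  t <- seq(0, 0.995, by = 1 / sr)
  rec <- manual_recording(t, pressure = c(8, rep(20, 199)),
                          flow = rep(0, 200), volume = rep(0, 200))
  segs <- manual_segments(1, 100, 200, rec)
  expect_equal(energy_per_breath(rec, segs), 0)
})

test_that("quasi-static limit: breath energy approaches the elastic energy V_T^2/(2C)", {
  st <- vent_settings(bias_flow = 1, set_PIP = 22, set_PEEP = 8, Ti = 2.4,
                      rate = 20)
  lu <- lung_params(C_rs = 1.25, R_aw = 0.001)
  rec <- simulate_ventilation(st, lu, duration = 6)
  segs <- segment_breaths(rec)
  E <- energy_per_breath(rec, segs)
  mech <- breath_mechanics(rec, segs)
  elastic <- mech$V_T^2 / (2 * 1.25) * 98.0665e-6
  expect_lt(max(abs(E - elastic) / elastic), 0.03)
})

test_that("breath energy always dominates the elastic minimum on resistive breaths", {
  rec <- default_recording()
  segs <- default_segments()
  E <- energy_per_breath(rec, segs)
  cfit <- coef(fit_eom(rec, segs))[["C"]]
  mech <- breath_mechanics(rec, segs)
  expect_true(all(E >= mech$V_T^2 / (2 * cfit) * 98.0665e-6 - 1e-12))
})

test_that("metrics ignore a volume-channel offset", {
  rec <- default_recording()
  segs <- default_segments()
  off <- rec
  off$volume <- rec$volume + 250
  expect_equal(breath_mechanics(off, segs), breath_mechanics(rec, segs))
  expect_equal(energy_per_breath(off, segs), energy_per_breath(rec, segs))
})

test_that("respiratory-system mechanical energy arithmetic and linearity", {
  expect_equal(me_rs(V_T = 10, dP = 20, PEEP = 8, weight = 1),
               180 * 98.0665e-6, tolerance = 1e-12)
  expect_equal(me_rs(10, 20, PEEP = 0, weight = 1), 100 * 98.0665e-6)
  expect_equal(me_rs(20, 20, 8, 1), 2 * me_rs(10, 20, 8, 1))
  expect_equal(me_rs(10, 20, 8, 1, form = "driving_only"), 100 * 98.0665e-6)
  expect_error(me_rs(-1, 20, 8, 1), "positive")
})

test_that("ventilatory efficiency index arithmetic and reciprocal scaling", {
  v <- vei(dP = 20, rate = 60, PaCO2 = 50)
  expect_equal(v$VEI, 3800 / 60000, tolerance = 1e-12)
  expect_equal(vei(40, 60, 50)$VEI, v$VEI / 2)
  expect_equal(vei(20, 120, 50)$VEI, v$VEI / 2)
  expect_equal(vei(20, 60, 100)$VEI, v$VEI / 2)
  expect_error(vei(0, 60, 50), "positive")
})

test_that("PV curve summaries: linear lung, simulator maneuver and extrapolation flag", {
  p <- seq(0, 35, by = 5)
  res <- analyze_pv_curve(p, 2 * p, weight = 1)
  expect_equal(res$TLC_mlkg, 70)
  expect_false(res$extrapolated)
  expect_equal(res$chords$compliance, rep(2, 3))

  pv <- static_pv_maneuver(lung_params())
  res <- analyze_pv_curve(pv$pressure, pv$volume, weight = 2.5)
  expect_lt(abs(res$TLC_mlkg - 1.25 * 35 / 2.5) / (1.25 * 35 / 2.5), 0.02)

  res <- analyze_pv_curve(seq(0, 30, 5), 2 * seq(0, 30, 5), weight = 1)
  expect_true(res$extrapolated)
  expect_equal(res$TLC_mlkg, 70)

  expect_error(analyze_pv_curve(c(0, 10, 20), c(0, 30, 10), weight = 1),
               "non-monotone")
})

test_that("impedance-to-volume calibration is the stated linear scale", {
  cal <- calibrate_delta_vl(c(0, 500, 1000), dZ_ref = 1000, V_ref = 40)
  expect_equal(as.numeric(cal), c(0, 20, 40))
  expect_equal(attr(cal, "scale_ml_per_au"), 0.04)
  expect_error(calibrate_delta_vl(1, dZ_ref = 0, V_ref = 40), "positive")
})
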