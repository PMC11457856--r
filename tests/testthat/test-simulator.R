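test_that("zero bias flow delivers no gas: volume and flow stay zero", {
  rec <- simulate_ventilation(vent_settings(bias_flow = 0), lung_params(),
                              duration = 3)
  expect_equal(max(abs(rec$volume)), 0)
  expect_equal(max(abs(rec$flow)), 0)
  expect_equal(rec$pressure, rep(8, length(rec$time)))
})

test_that("rigid-lung limit: no tidal volume, pressure reaches set PIP on the circuit time scale", {
  st <- vent_settings(bias_flow = 8)
  rec <- simulate_ventilation(st, lung_params(C_rs = 1e-6), duration = 2)
  expect_lt(max(rec$truth$V_T), 1e-3)
  # charging the circuit alone takes ~ C_circ * dP / F seconds
  t_expect <- st$circuit_compliance * (st$set_PIP - st$set_PEEP) /
    (st$bias_flow * 1000 / 60)
  expect_lt(rec$truth$t_to_pip[1], 3 * t_expect)
  expect_equal(max(rec$pressure), st$set_PIP, tolerance = 1e-6)
})

test_that("closed-form solution agrees with the 10-microsecond Euler oracle", {
  st <- vent_settings(bias_flow = 8, set_PIP = 30, set_PEEP = 8, Ti = 0.5,
                      rate = 60, circuit_compliance = 1)
  lu <- lung_params(C_rs = 1.0, R_aw = 0.05)
  rec <- simulate_ventilation(st, lu, duration = 1)
  oracle <- simulate_ventilation_euler(st, lu, n_breaths = 1)
  expect_lt(abs(rec$truth$V_T[1] - oracle$V_T[1]) / oracle$V_T[1], 0.005)
  expect_lt(abs(rec$truth$t_to_pip[1] - oracle$t_to_pip[1]), 0.002)
})

test_that("volume channel is the cumulative integral of flow over a breath", {
  rec <- default_recording()
  segs <- default_segments()
  # inspiratory limb (flow is discontinuous at the phase switch, so the
  # check runs within a phase where the sampled trapezoid is well defined)
  i0 <- segs$i_onset[2]; i1 <- segs$i_insp_end[2] - 1L
  q_mls <- rec$flow[i0:i1] * 1000 / 60
  v_trapz <- cumsum(c(0, 0.5 * (q_mls[-1] + q_mls[-length(q_mls)]))) / rec$sample_rate
  v_ref <- rec$volume[i0:i1] - rec$volume[i0]
  expect_lt(max(abs(v_trapz - v_ref)), 0.01 * max(v_ref))
})

test_that("inspired equals expired volume over a steady-state breath within 1%", {
  rec <- default_recording()
  segs <- default_segments()
  for (j in 3:5) {
    insp <- rec$volume[segs$i_insp_end[j]] - rec$volume[segs$i_onset[j]]
    exp_ <- rec$volume[segs$i_insp_end[j]] - rec$volume[segs$i_exp_end[j]]
    expect_lt(abs(insp - exp_) / insp, 0.01)
  }
})

test_that("expiratory flow decays with time constant R_aw * C_rs", {
  lu <- lung_params()
  rec <- default_recording()
  segs <- default_segments()
  i1 <- segs$i_insp_end[2]; i2 <- segs$i_exp_end[2]
  # clearly expiratory samples of breath 2 (detection smoothing can place
  # i_insp_end a sample or two inside late inspiration)
  idx <- intersect(i1:i2, which(rec$flow < -0.5))[1:12]
  lf <- log(-rec$flow[idx])
  tau_fit <- -1 / coef(lm(lf ~ rec$time[idx]))[2]
  expect_lt(abs(tau_fit - lu$R_aw * lu$C_rs) / (lu$R_aw * lu$C_rs), 0.05)
})

test_that("time-to-PIP strictly decreases and peak flow stays under bias flow as flow rises", {
  prev <- Inf
  for (F in c(4, 6, 8)) {
    rec <- simulate_ventilation(vent_settings(bias_flow = F), lung_params(),
                                duration = 3)
    tp <- rec$truth$t_to_pip[2]
    expect_lt(tp, prev)
    prev <- tp
    expect_lte(max(rec$truth$flow_peak), F * (1 + 1e-9))
  }
})

test_that("peak inspiratory flow never exceeds bias flow for any circuit compliance", {
  for (cc in c(0.1, 0.3, 1)) {
    st <- vent_settings(bias_flow = 8, circuit_compliance = cc)
    rec <- simulate_ventilation(st, lung_params(), duration = 3)
    expect_lte(max(rec$flow), 8 * (1 + 1e-9))
    # stiffer circuits bring peak flow closer to the bias flow
    expect_equal(max(rec$truth$flow_peak), 8 * 1.25 / (1.25 + cc),
                 tolerance = 0.01)
  }
})

test_that("sensor noise is seeded and reproducible", {
  st <- vent_settings(bias_flow = 8)
  nz <- c(pressure = 0.1, flow = 0.05, volume = 0.15)
  r1 <- simulate_ventilation(st, lung_params(), 2, noise = nz, seed = 9)
  r2 <- simulate_ventilation(st, lung_params(), 2, noise = nz, seed = 9)
  r3 <- simulate_ventilation(st, lung_params(), 2, noise = nz, seed = 10)
  expect_identical(r1$pressure, r2$pressure)
  expect_false(identical(r1$pressure, r3$pressure))
  expect_error(simulate_ventilation(st, lung_params(), 2, noise = nz),
               "seed")
})

test_that("surfactant applies a compliance step at the breath boundary", {
  lu <- lung_params(surfactant_time = 3, surfactant_factor = 2)
  rec <- simulate_ventilation(vent_settings(bias_flow = 8), lu, duration = 6)
  expect_equal(rec$truth$C_rs[rec$truth$t_onset < 3], rep(1.25, 3))
  expect_equal(rec$truth$C_rs[rec$truth$t_onset >= 3], rep(2.5, 3))
  vt <- rec$truth$V_T
  expect_gt(mean(vt[rec$truth$t_onset >= 4]), 1.8 * mean(vt[rec$truth$t_onset < 3]))
})

test_that("invalid settings and undersampling are rejected", {
  expect_error(vent_settings(bias_flow = 8, set_PIP = 6, set_PEEP = 8), "exceed")
  expect_error(vent_settings(bias_flow = 8, Ti = 1.2, rate = 60), "Ti")
  expect_error(vent_settings(bias_flow = 8, set_PIP = 45), "PIP_max")
  expect_error(lung_params(C_rs = -1), "C_rs")
  st <- vent_settings(bias_flow = 8)
  expect_error(simulate_ventilation(st, lung_params(), duration = 0.5),
               "at least one breath")
  expect_error(simulate_ventilation(st, lung_params(), 2, sample_rate = 30),
               "sample_rate")
  expect_error(simulate_ventilation(vent_settings(bias_flow = 8, Ti = 0.15),
                                    lung_params(), 2, sample_rate = 100),
               "resolve Ti")
})
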