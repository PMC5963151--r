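test_that("the ventricle surrogate interpolates between its ESPVR and EDPVR", {
  p <- ventricle_params(v0 = 20, e_es = 2.7, edp_a = 0.55, edp_b = 0.135,
                        v0d = 95)
  # passive limit and pure-ESPVR limit
  expect_equal(ventricle_pressure(110, 0, p),
               0.55 * (exp(0.135 * 15) - 1))
  expect_equal(ventricle_pressure(20, 1, p), 0)
  expect_equal(ventricle_pressure(70, 1, p), 2.7 * 50)
  # negative diastolic pressure below the diastolic reference volume
  expect_lt(ventricle_pressure(80, 0, p), 0)
  expect_error(ventricle_pressure(100, 1.5, p), "\\[0,1\\]")
})

test_that("valves are ideal diodes and the pump is a constant flow source", {
  expect_equal(valve_flow(10, 0, 0.05), 200)
  expect_equal(valve_flow(5, 5, 0.05), 0)
  expect_equal(valve_flow(0, 10, 0.05), 0)
  expect_error(valve_flow(1, 0, 0), "> 0")
  # smoothed diode approaches the exact one away from the kink
  expect_equal(valve_flow(10, 0, 0.05, smooth_w = 0.01), 200,
               tolerance = 1e-6)
  expect_equal(lvad_flow(0, 4), 4000 / 60)
  expect_equal(lvad_flow(123.4, 4), lvad_flow(0, 4))
  expect_equal(lvad_flow(0, 0), 0)
})

test_that("explicit stepping conserves volume and reports valve states", {
  sys <- list(params = circulation_params(),
              vent = ventricle_defaults(),
              afun = activation_waveform(transient_params()))
  y <- lvadsim:::initial_volumes(sys$params)
  tot0 <- sum(y)
  for (k in 1:2000) {
    st <- step_system(y, t = (k - 1) * 0.5, dt = 0.5, sys = sys)
    y <- st$volumes
  }
  expect_equal(sum(y), tot0, tolerance = 1e-10)
  expect_named(st$valves_open, c("mi", "ao", "tr", "pu"))
  expect_error(step_system(y, 0, dt = 2, sys = sys), "dt <= 1")
})

test_that("with no activation and no pump the loop relaxes toward static equilibrium", {
  sys <- list(params = circulation_params(), vent = ventricle_defaults(),
              afun = function(t) 0)
  y <- lvadsim:::initial_volumes(sys$params)
  rhs <- function(t, y, parms) {
    d <- lvadsim:::circ_derived(t, y, sys, smooth_w = 0.01)
    list(d$dy / 1000, d$aux)
  }
  out <- deSolve::ode(y, seq(0, 150000, by = 1000), rhs, parms = NULL,
                      method = "lsoda")
  fin <- out[nrow(out), ]
  d <- lvadsim:::circ_derived(0, fin[2:9], sys, smooth_w = 0)
  expect_true(all(abs(unlist(d$dy)) < 0.2))  # mL/s, essentially quiescent
  # and every valve carries (numerically) no flow at equilibrium
  flows <- d$aux[c("q_mi", "q_ao", "q_tr", "q_pu")]
  expect_true(all(abs(flows) < 0.2))
})

test_that("scenarios satisfy closed-loop conservation and steady cycling", {
  scn <- get_scenarios()
  for (s in scn) {
    vols <- s$traces[, c("v_la", "v_lv", "v_ra", "v_rv", "v_sa", "v_sv",
                         "v_pa", "v_pv")]
    tot <- rowSums(vols)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-4)  # 0.01%
    expect_true(all(vols >= 0))
    expect_lt(max(s$steady_metric), 0.01)
  }
  # valve complementarity on the fixed-step exact-diode integrator
  sr <- suppressWarnings(run_scenario("normal", n_cycles = 6,
                                      method = "rk4"))
  b <- segment_last_beat(sr$traces, 800)
  expect_true(all(b$q_mi >= 0 & b$q_ao >= 0 & b$q_tr >= 0 & b$q_pu >= 0))
  expect_true(all(b$q_mi * pmax(0, b$p_lv - b$p_la) < 1e-6 |
                  b$p_la >= b$p_lv))
})

test_that("scenario wiring matches the three study conditions", {
  scn <- get_scenarios()
  expect_equal(max(scn$normal$traces$q_lvad), 0)
  expect_equal(max(scn$hf$traces$q_lvad), 0)
  expect_equal(unique(scn$hf_lvad$traces$q_lvad), 4000 / 60)
  # HF transient actually drives a weaker activation
  expect_lt(max(scn$hf$traces$act), max(scn$normal$traces$act))
  expect_equal(scn$hf$transient$ca_amp, 0.9 * 0.7)
  expect_equal(scn$hf$transient$tau_decay, 150 * 0.7)
})

test_that("normal-target calibration recovers parameters in a round trip", {
  # model's own output as targets: the optimizer must return the truth
  p0 <- circulation_params(); v0 <- ventricle_defaults()
  truth <- c(e_es_lv = v0$lv$e_es, r_sa = p0$r_sa)
  sc <- suppressWarnings(run_scenario("normal", n_cycles = 6))
  out <- suppressWarnings(
    lvadsim:::scenario_outputs(summarize_scenario(sc)))
  targets <- out[c("lvesp", "co")]
  # start the fit away from the truth
  pstart <- p0; pstart$r_sa <- p0$r_sa * 1.3
  vstart <- v0; vstart$lv$e_es <- v0$lv$e_es * 0.8
  fit <- suppressWarnings(
    calibrate_normal(targets = targets, free = c("e_es_lv", "r_sa"),
                     params = pstart, vent = vstart, n_cycles = 6))
  expect_lt(abs(fit$vent$lv$e_es - truth["e_es_lv"]) / truth["e_es_lv"],
            0.05)
  expect_lt(abs(fit$params$r_sa - truth["r_sa"]) / truth["r_sa"], 0.05)
  expect_true(fit$converged)
})

test_that("shipped defaults match the canonical parameter file", {
  f <- system.file("extdata", "circulation_params.json", package = "lvadsim")
  ref <- jsonlite::read_json(f, simplifyVector = TRUE)
  p <- circulation_params(); v <- ventricle_defaults()
  for (nm in names(ref$circulation))
    expect_equal(p[[nm]], ref$circulation[[nm]], info = nm)
  for (nm in setdiff(names(ref$ventricle_lv), "act_k"))
    expect_equal(v$lv[[nm]], ref$ventricle_lv[[nm]], info = nm)
  expect_equal(v$rv$act_k, ref$ventricle_rv$act_k)
})
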