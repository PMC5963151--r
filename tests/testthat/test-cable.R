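test_that("the explicit stability bound is enforced before stepping", {
  g <- cable_grid(sigma = 15.4, dx = 0.01)   # bound ~0.0045 ms
  expect_error(run_cable(g, t_end = 5, dt = 0.01), "stability bound")
  expect_error(step_cable(g, dt = 0.01), "stability bound")
})

test_that("zero conductivity decouples the nodes into independent cells", {
  g <- cable_grid(n_nodes = 5, sigma = 0)
  stim <- c(-52, 0, 0, 0, 0)
  g2 <- g
  for (k in 1:50) g2 <- step_cable(g2, dt = 0.01, stim = stim)
  # every node evolves exactly like an independent single cell
  s0 <- init_state("epi"); s1 <- init_state("epi")
  for (k in 1:50) {
    s0 <- step_state(s0, dt = 0.01, i_stim = 0)
    s1 <- step_state(s1, dt = 0.01, i_stim = -52)
  }
  expect_equal(g2$states[1, 3], unname(s0[["v_m"]]), tolerance = 1e-12)
  expect_equal(g2$states[1, 1], unname(s1[["v_m"]]), tolerance = 1e-10)
})

test_that("uniform state with no stimulus stays spatially uniform", {
  g <- cable_grid(n_nodes = 20)
  for (k in 1:30) g <- step_cable(g, dt = 0.004, stim = 0)
  expect_lt(diff(range(g$states[1, ])), 1e-12)
})

test_that("a midpoint stimulus activates symmetrically; an end stimulus orders activation", {
  g <- cable_grid(n_nodes = 61)
  r <- run_cable(g, t_end = 40, stim_nodes = 29:33)
  at <- activation_times(r)$eat_ms
  expect_equal(at[31 - 10], at[31 + 10], tolerance = 0.05)
  expect_equal(at[2], at[60], tolerance = 0.05)
  # end stimulus: activation time increases monotonically with distance
  r2 <- run_cable(cable_grid(), t_end = 60)
  at2 <- activation_times(r2)
  expect_false(is.unsorted(at2$eat_ms[6:95]))
  # interpolated crossing lies between bracketing samples
  expect_true(all(at2$eat_ms >= min(r2$time_ms) &
                  at2$eat_ms <= max(r2$time_ms)))
})

test_that("conduction velocity is the distance-time slope with boundary window", {
  at <- data.frame(node_index = 1:100, position_cm = (0:99) * 0.01,
                   eat_ms = (0:99) * 0.01 * 5)  # exactly 5 ms/cm
  expect_equal(conduction_velocity(at), 200)
  at$eat_ms <- NA_real_
  expect_error(conduction_velocity(at), "fewer than 2")
})

test_that("propagation is uniform, sqrt-scaled in conductivity, and dt-convergent", {
  cvof <- function(sigma, dt = 0.01) {
    r <- run_cable(cable_grid(sigma = sigma), t_end = 60, dt = dt)
    conduction_velocity(activation_times(r))
  }
  cv1 <- cvof(2.2)
  expect_gt(cv1, 30); expect_lt(cv1, 120)   # working myocardium range
  # CV constant along the cable: compare two half-windows of the core
  r <- run_cable(cable_grid(sigma = 2.2), t_end = 60)
  at <- activation_times(r)
  cva <- conduction_velocity(at, window = c(0.25, 0.50))
  cvb <- conduction_velocity(at, window = c(0.50, 0.75))
  expect_lt(abs(cva - cvb) / cvb, 0.05)
  # doubling sigma multiplies CV by ~sqrt(2)
  cv2 <- cvof(4.4)
  expect_lt(abs(cv2 / cv1 - sqrt(2)) / sqrt(2), 0.10)
  # dt refinement changes CV by < 2%
  cvh <- cvof(2.2, dt = 0.005)
  expect_lt(abs(cv1 - cvh) / cvh, 0.02)
  # reversed stimulus end gives the same speed
  rr <- run_cable(cable_grid(sigma = 2.2), t_end = 60, stim_nodes = 96:100)
  cvr <- conduction_velocity(activation_times(rr))
  expect_lt(abs(cvr - cv1) / cv1, 0.01)
})

test_that("the fast-fiber preset conducts at about the clinical Purkinje speed", {
  g <- cable_grid_preset("purkinje")
  r <- run_cable(g, t_end = 40)
  cv <- conduction_velocity(activation_times(r))
  expect_lt(abs(cv - 200) / 200, 0.05)
})
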