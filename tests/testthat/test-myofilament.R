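test_that("the relaxed state is fully nonpermissive with zero tension", {
  s <- init_xb_state(2.2)
  expect_equal(sum(s[c("n_xb", "p_xb", "xb_prer", "xb_postr")]), 1)
  expect_equal(unname(s[["n_xb"]]), 1)
  expect_equal(active_tension(s), 0)
  expect_identical(unclass(init_xb_state(2.0)), unclass(init_xb_state(2.0)))
  expect_error(init_xb_state(1.0), "out of range")
})

test_that("state-fraction conservation holds to 1e-8 through twitches and random steps", {
  ct <- make_transient(transient_params())
  for (mode in c("isometric", "isotonic")) {
    tw <- run_twitch(ct, mode, n_beats = 3)
    expect_lt(max(abs(tw$frac_sum - 1)), 1e-8)
  }
  # random calcium steps
  set.seed(1)
  s <- init_xb_state(2.2)
  for (k in 1:2000) s <- step_xb(s, stats::runif(1, 0, 5), dt = 0.05,
                                 mode = "isotonic", load_kpa = 10)
  expect_lt(abs(sum(s[c("n_xb", "p_xb", "xb_prer", "xb_postr")]) - 1), 1e-8)
})

test_that("zero calcium keeps the filaments relaxed", {
  s <- init_xb_state(2.2, ca_dia = 0)
  for (k in 1:10000) s <- step_xb(s, 0, dt = 0.1)
  expect_lt(s[["xb_prer"]] + s[["xb_postr"]], 1e-6)
  expect_lt(active_tension(s), 1e-4)
})

test_that("time-marched fixed-calcium tension converges to the algebraic force-calcium curve", {
  fc <- steady_state_force_ca(2.2, c(0.3, 0.6, 1, 3))
  expect_false(is.unsorted(fc$tension_kpa))          # sigmoid, nondecreasing
  expect_lt(steady_state_force_ca(2.2, 0.01)$tension_kpa, 1e-3)
  for (i in seq_len(nrow(fc))) {
    s <- init_xb_state(2.2, fc$ca_uM[i])
    for (k in 1:6000) s <- step_xb(s, fc$ca_uM[i], dt = 0.1)
    expect_equal(active_tension(s), fc$tension_kpa[i],
                 tolerance = 0.01)
  }
})

test_that("saturating calcium drives a monotone rise of the post-rotation state", {
  s <- init_xb_state(2.2)
  post <- numeric(60)
  for (k in 1:60) {
    for (j in 1:100) s <- step_xb(s, 50, dt = 0.1)
    post[k] <- s[["xb_postr"]]
  }
  expect_false(is.unsorted(post))
  expect_gt(post[60], 0.5)
})

test_that("twitch protocols reproduce the single-cell contraction phenotypes", {
  ctn <- make_transient(transient_params())
  cth <- make_transient(apply_hf_remodeling(transient_params()))
  iso_n <- run_twitch(ctn, "isometric")
  iso_h <- run_twitch(cth, "isometric")
  # isometric clamp: length exactly constant
  expect_equal(diff(range(iso_n$sl_um)), 0)
  # heart failure: pointwise weaker isometric tension at equal length
  expect_true(all(iso_h$tension_kpa <= iso_n$tension_kpa + 1e-9))
  expect_lt(max(iso_h$tension_kpa), max(iso_n$tension_kpa))
  # isotonic 10 kPa: shortening occurs; HF shortens less
  it_n <- run_twitch(ctn, "isotonic", load_kpa = 10)
  it_h <- run_twitch(cth, "isotonic", load_kpa = 10)
  expect_lt(min(it_n$sl_norm), 1)
  expect_gt(min(it_h$sl_norm), min(it_n$sl_norm))
  # steady cycling: last two beats' peak shortening differ by < 2%
  ps <- it_n$peak_shortening_by_beat
  expect_lt(abs(ps[10] - ps[9]) / ps[10], 0.02)
})

test_that("high-load isotonic and hard length clamp agree on isometric tension within 1%", {
  ct <- make_transient(transient_params())
  hl <- run_twitch(ct, "isometric", isometric_as = "high_load")  # 1000 kPa
  cl <- run_twitch(ct, "isometric", sl0 = hl$sl_um[1])           # clamp there
  expect_lt(diff(range(hl$sl_um)) / hl$sl_um[1], 0.01)  # barely moves
  expect_equal(max(hl$tension_kpa), max(cl$tension_kpa), tolerance = 0.01)
})

test_that("ATP consumption normalizes to the normal isometric peak and drops under HF", {
  ctn <- make_transient(transient_params())
  cth <- make_transient(apply_hf_remodeling(transient_params()))
  iso_n <- run_twitch(ctn, "isometric")
  ref <- max(iso_n$atp_rate)
  expect_equal(max(atp_consumption(iso_n, ref)), 1.0)
  iso_h <- run_twitch(cth, "isometric")
  expect_lt(max(atp_consumption(iso_h, ref)), 1.0)
  # zero-calcium run consumes nothing
  ct0 <- make_transient(transient_params(ca_dia = 1e-9, ca_amp = 0))
  tw0 <- run_twitch(ct0, "isometric", n_beats = 2)
  expect_lt(max(tw0$atp_rate) / ref, 1e-6)
  expect_error(atp_consumption(iso_n, 0), "> 0")
})

test_that("tension is linear in a uniform scaling of the attached fractions", {
  s <- init_xb_state(2.2)
  s[["xb_prer"]] <- 0.1; s[["xb_postr"]] <- 0.2
  s[["x_prer"]] <- 0.001; s[["x_postr"]] <- 0.007
  s2 <- s; s2[["xb_prer"]] <- 0.2; s2[["xb_postr"]] <- 0.4
  expect_equal(active_tension(s2), 2 * active_tension(s))
})
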