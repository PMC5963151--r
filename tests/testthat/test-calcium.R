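test_that("analytic transient hits its prescribed peak at the closed-form time", {
  tp <- transient_params()                 # 0.1 + 0.9 uM, 20/150 ms, BCL 800
  ct <- make_transient(tp, dt = 0.5)
  # closed-form argmax of the bi-exponential
  tstar <- log(150 / 20) * 20 * 150 / (150 - 20)
  expect_equal(max(ct$ca_uM), 1.0)
  expect_lt(abs(ct$time_ms[which.max(ct$ca_uM)] - tstar), 0.5)
  # single global maximum, non-negative, baseline at diastolic level
  expect_equal(sum(diff(sign(diff(ct$ca_uM))) < 0), 1)
  expect_true(all(ct$ca_uM >= 0))
  expect_equal(min(ct$ca_uM), ct$diastolic_uM, tolerance = 1e-6)
})

test_that("transient generation is linear in amplitude and flat at zero amplitude", {
  t1 <- make_transient(transient_params(ca_amp = 0.9))
  t2 <- make_transient(transient_params(ca_amp = 1.8))
  expect_equal(t2$ca_uM - 0.1, 2 * (t1$ca_uM - 0.1), tolerance = 1e-12)
  t0 <- make_transient(transient_params(ca_amp = 0))
  expect_true(all(t0$ca_uM == 0.1))
})

test_that("grid refinement does not change values at shared nodes", {
  tc <- make_transient(transient_params(), dt = 2)
  tf <- make_transient(transient_params(), dt = 0.5)
  shared <- match(tc$time_ms, tf$time_ms)
  expect_equal(tf$ca_uM[shared], tc$ca_uM, tolerance = 1e-12)
})

test_that("heart-failure remodeling scales amplitude and decay as specified", {
  tp <- transient_params()
  hf <- apply_hf_remodeling(tp)            # defaults 0.7 / 0.7
  expect_equal(hf$ca_amp / tp$ca_amp, 0.7)
  expect_equal(hf$tau_decay, 105)
  expect_equal(hf$ca_dia, tp$ca_dia)
  expect_equal(hf$tau_rise, tp$tau_rise)
  # identity factors leave parameters unchanged
  expect_equal(unlist(apply_hf_remodeling(tp, 1, 1)), unlist(tp))
  # peak-above-diastolic of the generated transients scales exactly
  pk <- function(x) max(make_transient(x)$ca_uM) - x$ca_dia
  expect_equal(pk(hf) / pk(tp), 0.7, tolerance = 1e-12)
  # faster decay pulls the peak earlier
  t_of_peak <- function(x) { ct <- make_transient(x, 0.25); ct$time_ms[which.max(ct$ca_uM)] }
  expect_lte(t_of_peak(hf), t_of_peak(tp))
  expect_error(apply_hf_remodeling(tp, 0, 0.7), "0, 1")
  expect_error(apply_hf_remodeling(tp, 0.7, 1.2), "0, 1")
})

test_that("normalization against a reference peak behaves as documented", {
  ct <- make_transient(transient_params())
  expect_equal(max(normalize_to_reference(ct, max(ct$ca_uM))$ca_uM), 1.0)
  expect_equal(max(normalize_to_reference(ct, 2 * max(ct$ca_uM))$ca_uM), 0.5)
  # HF transient on a zero-diastolic baseline normalized by the normal peak
  tp0 <- transient_params(ca_dia = 1e-9)
  hf0 <- make_transient(apply_hf_remodeling(tp0))
  n0 <- make_transient(tp0)
  expect_equal(max(normalize_to_reference(hf0, max(n0$ca_uM))$ca_uM), 0.7,
               tolerance = 1e-6)
  expect_error(normalize_to_reference(ct, 0), "positive")
})

test_that("periodic sampling wraps and interpolates linearly", {
  ct <- make_transient(transient_params(), dt = 1)
  expect_equal(sample_periodic(ct, 0), sample_periodic(ct, 800))
  expect_equal(sample_periodic(ct, 123), ct$ca_uM[ct$time_ms == 123])
  mid <- sample_periodic(ct, 123.5)
  expect_equal(mid, mean(ct$ca_uM[ct$time_ms %in% c(123, 124)]))
  expect_equal(sample_periodic(ct, 1600 + 42), sample_periodic(ct, 42))
})

test_that("transients round-trip through CSV with JSON sidecar", {
  ct <- make_transient(transient_params(), dt = 4)
  f <- tempfile(fileext = ".csv")
  write_transient_csv(ct, f)
  ct2 <- read_transient_csv(f)
  expect_equal(ct2$ca_uM, ct$ca_uM)
  expect_equal(ct2$bcl_ms, ct$bcl_ms)
  unlink(c(f, paste0(f, ".json")))
})

test_that("invalid transient parameters are rejected", {
  expect_error(transient_params(tau_rise = 200, tau_decay = 150), "less")
  expect_error(transient_params(ca_dia = -1), "positive")
  expect_error(make_transient(transient_params(), dt = 50), "bcl_ms/100")
})
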