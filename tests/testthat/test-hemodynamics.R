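test_that("PV summary arithmetic reproduces printed normal-condition indices", {
  # normal LV row: ESP 110, EDP 5, EDV 112, ESV 61
  beat <- synth_pv_fixture(esp = 110, edp = 5, edv = 112, esv = 61)
  s <- summarize_beat(beat, 800)
  expect_equal(s$lv$edv, 112)
  expect_equal(s$lv$esv, 61)
  expect_equal(s$lv$sv, 51)
  expect_equal(s$lv$esp, 110)
  expect_equal(s$lv$edp, 5)
  expect_equal(s$lv$pp, 105)
  expect_equal(round(s$lv$ef), 46)
  expect_equal(round(s$lv$co, 1), 3.8)
})

test_that("synthetic fixtures round-trip exactly, including negative EDP", {
  cases <- list(c(110, 5, 112, 61), c(43, -1, 89, 69), c(16, 1, 136, 85),
                c(73, 12, 117, 85))
  for (cs in cases) {
    s <- summarize_beat(synth_pv_fixture(cs[1], cs[2], cs[3], cs[4]), 800)
    expect_equal(c(s$lv$esp, s$lv$edp, s$lv$edv, s$lv$esv),
                 cs, tolerance = 1e-12)
  }
  # seeded noise: deterministic, and prescribed extremes preserved
  n1 <- synth_pv_fixture(110, 5, 112, 61, noise_sd = 0.5, seed = 7)
  n2 <- synth_pv_fixture(110, 5, 112, 61, noise_sd = 0.5, seed = 7)
  expect_identical(n1, n2)
  sn <- summarize_beat(n1, 800)
  expect_equal(c(sn$lv$edv, sn$lv$esv), c(112, 61))
  expect_error(synth_pv_fixture(100, 5, 60, 80), "exceed")
})

test_that("stroke work follows the shoelace rule", {
  # rectangular loop: P 0..100 mmHg around V 50..100 mL -> area 5000
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  sq <- function(x) pmin(1, pmax(0, x))
  rect <- data.frame(
    time_ms = seq(0, 800, length.out = 400),
    p_lv = c(rep(0, 100), seq(0, 100, length.out = 100),
             rep(100, 100), seq(100, 0, length.out = 100)),
    v_lv = c(seq(50, 100, length.out = 100), rep(100, 100),
             seq(100, 50, length.out = 100), rep(50, 100)))
  s <- summarize_beat(rect, 800)
  expect_equal(s$lv$sw, 5000, tolerance = 1e-9)
  # fixture area matches independent trapezoidal integration of P dV
  fx <- synth_pv_fixture(110, 5, 112, 61)
  area_trapz <- abs(sum(diff(fx$v_lv) * (utils::head(fx$p_lv, -1) +
                                           utils::tail(fx$p_lv, -1)) / 2))
  expect_equal(summarize_beat(fx, 800)$lv$sw, area_trapz, tolerance = 1e-3)
})

test_that("percent change matches the published condition comparisons", {
  expect_equal(round(percent_change(73, 43)), -41)   # LVESP, HF -> HF+LVAD
  expect_equal(round(percent_change(7, 5)), -29)     # RAESP
  expect_equal(round(percent_change(17, 5)), -71)    # PAESP
  expect_equal(round(percent_change(21, 32)), 52)    # RVEF
  expect_equal(round(percent_change(2.5, 3.5)), 40)  # RVCO
  expect_equal(round(percent_change(411, 137)), -67) # RVSW
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero baseline")
  # multiplicative identity: new = baseline * (1 + p/100)
  p <- percent_change(73, 43)
  expect_equal(73 * (1 + p / 100), 43)
})

test_that("condition comparison table covers both canonical pairs", {
  s1 <- summarize_beat(synth_pv_fixture(110, 5, 112, 61), 800)
  s2 <- summarize_beat(synth_pv_fixture(73, 12, 117, 85), 800)
  s3 <- summarize_beat(synth_pv_fixture(43, -1, 89, 69), 800)
  tab <- compare_conditions(list(normal = s1, hf = s2, hf_lvad = s3))
  expect_setequal(unique(tab$baseline_condition), c("normal", "hf"))
  expect_true(all(c("lvesp", "lvedv", "lvef", "lvsw") %in% tab$quantity))
  lvesp <- tab[tab$quantity == "lvesp" & tab$baseline_condition == "hf", ]
  expect_equal(round(lvesp$pct_change), -41)
  # identical summaries give all-zero changes
  t0 <- compare_conditions(list(a = s1, b = s1), pairs = list(c("a", "b")))
  expect_true(all(t0$pct_change == 0))
  expect_error(compare_conditions(list(a = s1), pairs = list(c("a", "zz"))),
               "unknown condition")
})

test_that("last-beat segmentation returns one aligned cycle, idempotently", {
  t <- seq(0, 4000, by = 2)
  tr <- data.frame(time_ms = t, p_lv = sin(2 * pi * t / 800),
                   v_lv = 80 + 20 * cos(2 * pi * t / 800))
  b <- segment_last_beat(tr, 800)
  expect_equal(range(b$time_ms), c(3200, 4000))
  expect_equal(segment_last_beat(b, 800), b)
  expect_error(segment_last_beat(tr[t < 700, ], 800), "full cycle")
})

test_that("isovolumetric detection distinguishes clamped from pump-drained volume", {
  tm <- seq(0, 800, by = 2)
  # classic beat: two isovolumetric phases (contraction, relaxation)
  fx <- synth_pv_fixture(110, 5, 112, 61)
  expect_gte(nrow(isovolumetric_phases(fx)), 2)
  # constant-volume constant-pressure trace: pressure criterion rejects
  flat <- data.frame(time_ms = tm, p_lv = rep(10, length(tm)),
                     v_lv = rep(100, length(tm)))
  expect_equal(nrow(isovolumetric_phases(flat)), 0)
  # steady pump drain at 0.67 mL / 10 ms with rising pressure: volume is
  # never constant, so no isovolumetric phase even below the rate threshold
  drain <- data.frame(time_ms = tm, p_lv = seq(0, 60, length.out = length(tm)),
                      v_lv = 100 - 0.067 * tm)
  expect_equal(nrow(isovolumetric_phases(drain)), 0)
})
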