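test_that("feature extraction is exact on a linear-repolarization AP", {
  tr <- synthetic_linear_ap(rmp = -80, peak = 20, repol_ms = 200)
  f <- extract_ap_features(tr)
  expect_equal(f$amplitude_mv, 100)
  expect_equal(f$rmp_mv, -80)
  expect_equal(unname(f$apd[["APD50"]]), 100, tolerance = 0.005)
  expect_equal(unname(f$apd[["APD90"]]), 180, tolerance = 0.005)
})

test_that("a constant-voltage trace yields no AP", {
  tt <- seq(0, 500, by = 0.1)
  tr <- as_ap_trace(tt, rep(-80, length(tt)), stim_times = 100)
  expect_error(extract_ap_features(tr), "no AP detected")
})

test_that("an APD level not reached before the next stimulus is flagged undefined", {
  # repolarization takes 300 ms but the next stimulus comes at 200 ms
  tt <- seq(0, 400, by = 0.1)
  vv <- ifelse(tt < 50, -80,
               pmax(20 - 100 * (tt - 50) / 300, -80))
  tr <- as_ap_trace(tt, vv, stim_times = c(50, 250))
  f <- extract_ap_features(tr, 1)
  expect_true(is.na(f$apd[["APD90"]]))
  expect_match(f$apd_undefined_reason[["APD90"]], "not reached")
  expect_false(is.na(f$apd[["APD50"]]))
})

test_that("pacing shorter than one BCL delivers exactly one stimulus", {
  mock <- make_mock_cell(apd = 100)
  tr <- pace(mock, bcl = 1, duration = 0.3)
  expect_identical(length(tr$stim_times), 1L)
})

test_that("mock cell with calibrated APD returns it on every beat", {
  mock <- std_mock()
  tr <- pace(mock, bcl = 0.6, duration = 3)
  apd <- vapply(seq_along(tr$stim_times), function(i)
    extract_ap_features(tr, i)$apd[["APD90"]], numeric(1))
  expect_true(all(abs(apd - 150) <= 3))
})

test_that("feature extraction is sampling-rate stable", {
  m <- atrial_model("courtemanche")
  amp <- table_trace("courtemanche")$stim_amp
  a <- pace(m, bcl = 1, duration = 2, stim_amp = amp, sample_dt = 0.1)
  b <- pace(m, bcl = 1, duration = 2, stim_amp = amp, sample_dt = 0.05)
  fa <- extract_ap_features(a, 2)$apd[["APD90"]]
  fb <- extract_ap_features(b, 2)$apd[["APD90"]]
  expect_lt(abs(fa - fb), 0.5)
})

test_that("alternans classifier matches constructed periodic sequences", {
  expect_identical(detect_alternans(rep(100, 8))$class, "none")
  r <- detect_alternans(rep(c(120, 80), 4))
  expect_identical(r$class, "period-2")
  expect_equal(r$amplitude, 40)
  expect_identical(detect_alternans(rep(c(90, 90, 120), 3))$class,
                   "period-3")
  expect_error(detect_alternans(c(100, 100)), "at least 8")
})

test_that("alternans classifier agrees with a periodogram oracle on generated cases", {
  set.seed(42)
  for (rep_i in 1:20) {
    period <- sample(c(1, 2, 3), 1)
    base <- 100 + switch(period,
                         rep(0, 12),
                         rep(c(10, -10), 6),
                         rep(c(12, -4, -4), 4))
    x <- base + rnorm(12, sd = 0.3)
    got <- detect_alternans(x)$class
    # oracle: periodogram of the demeaned sequence
    sp <- Mod(fft(x - mean(x)))[2:7]^2  # through the Nyquist bin
    fr <- (1:6) / 12
    dominant <- fr[which.max(sp)]
    oracle <- if (sd(x) < 1) "none"
      else if (abs(dominant - 0.5) < 0.1) "period-2"
      else if (abs(dominant - 1 / 3) < 0.05) "period-3"
      else "irregular"
    expect_identical(got, oracle,
                     label = paste("case", rep_i, "period", period))
  }
})

test_that("cAF variants have shorter APD90 and more negative RMP than control", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    fc <- table_features(nm, "control")
    ff <- table_features(nm, "caf")
    expect_lt(ff$apd[["APD90"]], fc$apd[["APD90"]])
    expect_lt(ff$rmp_mv, fc$rmp_mv)
  }
})

test_that("the quiescent-then-paced stability schedule reports RMP and beat features", {
  mock <- make_mock_cell(apd = 100)
  st <- long_term_stability(mock, "quiescent_paced",
                            quiescent_minutes = 0.2, post_minutes = 0.1,
                            bcl = 1)
  # RMP is sampled through the quiescent phase and stays at rest
  quiet <- st$rmp[st$rmp$t_min < 0.2, ]
  expect_gt(nrow(quiet), 5)
  expect_lt(diff(range(quiet$rmp)), 0.1)
  # paced phase contributes per-beat APDs near the calibrated value
  expect_true(all(abs(st$beats$apd90 - 100) < 5))
})

test_that("a zero-stimulus quiescent run holds all series constant (mock at rest)", {
  mock <- make_mock_cell(apd = 100)
  r <- cell_step(mock, mock$initial_state, dt = 0.1, n = 10000)
  expect_equal(unname(r), unname(mock$initial_state), tolerance = 1e-9)
})
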