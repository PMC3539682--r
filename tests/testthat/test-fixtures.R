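test_that("mock cell calibration recovers the requested APD within 2%", {
  mock <- std_mock()
  tr <- pace(mock, bcl = 0.6, duration = 1.2)
  f <- extract_ap_features(tr, 2)
  expect_lt(abs(f$apd[["APD90"]] - 150) / 150, 0.02)
  expect_equal(f$rmp_mv, -80, tolerance = 0.5)
  expect_equal(f$amplitude_mv, 100, tolerance = 8)
})

test_that("unattainable mock parameter combinations raise errors", {
  expect_error(make_mock_cell(amplitude = 0), "inexcitable")
  expect_error(make_mock_cell(apd = 150, refractory = 50), "half the APD")
  expect_error(make_mock_cell(rmp = -80, amplitude = 50), "exceed 10 mV")
})

test_that("the mock cell conforms to the plugin contract used by all protocols", {
  mock <- std_mock()
  expect_s3_class(mock, "ionic_model")
  d <- cell_derivatives(mock, mock$initial_state)
  expect_identical(length(d), length(mock$initial_state))
  expect_true(2L %in% mock$gating_index)
  thr <- find_threshold(mock)
  expect_gt(thr, 0)
})

test_that("vortex fixture ground truth is recovered by the tracking chain", {
  vx <- make_vortex_phase_movie(center = c(10, 30), chirality = 1,
                                frequency = 8, nx = 40, ny = 40, dx = 1,
                                duration = 500)
  tr <- track_singularities(vx)
  expect_true(all(abs(tr$x - 10) <= 1))
  expect_true(all(abs(tr$y - 30) <= 1))
  expect_true(all(tr$charge == 1))
  expect_equal(dominant_frequency(attr(vx, "signal"), attr(vx, "fs_hz")),
               8, tolerance = 0.05)
})
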