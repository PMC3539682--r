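test_that("a uniform resting grid stays spatially uniform", {
  m <- atrial_model("courtemanche")
  g <- tissue_grid(m, nx = 30, sigma = 0.3)
  g <- step_tissue(g, dt = 0.01, duration = 5)
  expect_lt(diff(range(g$state[1, ])), 1e-12)
})

test_that("sigma = 0 decouples voxels into exact single-cell runs", {
  m <- atrial_model("nygren")
  g <- tissue_grid(m, nx = 5, sigma = 0)
  stim <- cbind(t0 = 0, dur = 2, amp = 1500, from = 1, to = 5)
  g <- step_tissue(g, dt = 0.01, duration = 20, stims = stim)
  single <- atrialbench:::run_cell_cpp(m$id, unname(m$params),
                                       unname(m$initial_state), 20, 0.01,
                                       0, 2, 1500, 20, -1L, FALSE,
                                       integer(0))$state
  for (v in 1:5) expect_identical(unname(g$state[, v]), unname(single))
})

test_that("no-flux diffusion conserves the spatial mean with zero membrane current", {
  inert <- atrialbench:::.mock_model(c(rmp = -80, amplitude = 100,
                                       tau_in = 1e300, tau_out = 1e300,
                                       tau_open = 100, tau_close = 50,
                                       v_gate = 0.13))
  st <- matrix(rep(c(-80, 1), 50), nrow = 2)
  st[1, ] <- -80 + 40 * exp(-((1:50) - 25)^2 / 20)  # a voltage bump
  g <- tissue_grid(inert, nx = 50, sigma = 0.3, state = st)
  m0 <- mean(g$state[1, ])
  g <- step_tissue(g, dt = 0.01, duration = 20)
  expect_equal(mean(g$state[1, ]), m0, tolerance = 1e-10)
  expect_lt(diff(range(g$state[1, ])), diff(range(st[1, ])))  # smoothing
})

test_that("the CFL-style stability bound warns at setup", {
  m <- atrial_model("courtemanche")
  expect_warning(tissue_grid(m, nx = 30, sigma = 3, dt = 0.05),
                 "stability bound")
})

test_that("measure_cv is exact on a linear activation map", {
  act <- activation_map((seq_len(200) - 0.5) * 0.1 / 0.75, dx = 0.1)
  expect_equal(measure_cv(act), 750)
})

test_that("an unactivated distal half raises a conduction-block error", {
  tt <- c(seq(0.1, 10, length.out = 100), rep(NA_real_, 100))
  expect_error(measure_cv(activation_map(tt, 0.1)), "conduction block")
})

test_that("plane-wave fixture speed is recovered exactly and reverses with direction", {
  mv <- make_plane_wave_movie(speed = 750, n = 200, dx = 0.1)
  expect_equal(measure_cv(attr(mv, "activation")), 750)
  rev <- make_plane_wave_movie(speed = 500, direction = -1, n = 200,
                               dx = 0.1)
  a_f <- attr(mv, "activation")$times
  a_r <- attr(rev, "activation")$times
  expect_true(all(diff(a_f) > 0))
  expect_true(all(diff(a_r) < 0))
})

test_that("mock strand CV is independent of strand length (20 vs 40 mm)", {
  mock <- std_mock()
  seed <- mock$initial_state
  cv20 <- atrialbench:::.single_beat_cv(mock, seed, 0.05, 100, 0.2, 0.01,
                                        amp = 2, window = 200)
  cv40 <- atrialbench:::.single_beat_cv(mock, seed, 0.05, 200, 0.2, 0.01,
                                        amp = 2, window = 400)
  expect_lt(abs(cv20 - cv40) / cv40, 0.01)
})

test_that("doubling sigma after tuning increases CV (monotonicity)", {
  mock <- std_mock()
  seed <- mock$initial_state
  cv1 <- atrialbench:::.single_beat_cv(mock, seed, 0.05, 100, 0.2, 0.01,
                                       amp = 2, window = 300)
  cv2 <- atrialbench:::.single_beat_cv(mock, seed, 0.10, 100, 0.2, 0.01,
                                       amp = 2, window = 300)
  expect_gt(cv2, cv1)
  # approximate sqrt(sigma) scaling for a diffusion-driven front
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.15)
})
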