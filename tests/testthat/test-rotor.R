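test_that("analytic-signal phase of a sinusoidal voxel advances linearly and wraps", {
  tt <- seq(0, 2000, by = 2)
  f <- 4 / 1000  # 4 Hz in 1/ms
  vm <- array(rep(sin(2 * pi * f * tt), each = 4), dim = c(2, 2, length(tt)))
  ph <- compute_phase(vm_movie(vm, tt, 1))
  p <- ph$phase[1, 1, ]
  expect_true(all(abs(p) <= pi + 1e-9))
  dp <- diff(p[100:200])
  dp <- dp[abs(dp) < pi]          # drop wrap points
  expect_equal(mean(dp), 2 * pi * f * 2, tolerance = 0.05)
})

test_that("constant voxels carry undefined phase", {
  tt <- seq(0, 100, by = 2)
  vm <- array(-80, dim = c(3, 3, length(tt)))
  vm[1, 1, ] <- -80 + 10 * sin(2 * pi * 0.01 * tt)
  ph <- compute_phase(vm_movie(vm, tt, 1))
  expect_true(all(is.na(ph$phase[2, 2, ])))
  expect_true(all(is.finite(ph$phase[1, 1, ])))
})

test_that("an ideal vortex yields one singularity at the center with the seeded chirality", {
  for (chi in c(1, -1)) {
    vx <- make_vortex_phase_movie(center = c(25, 25), chirality = chi,
                                  frequency = 5, nx = 50, ny = 50, dx = 1,
                                  duration = 400)
    tr <- track_singularities(vx)
    expect_true(all(tr$charge == chi))
    expect_identical(length(unique(tr$id)), 1L)
    expect_true(all(abs(tr$x - 25) <= 1 & abs(tr$y - 25) <= 1))
  }
})

test_that("two opposite vortices carry zero net charge; a uniform field none", {
  a <- make_vortex_phase_movie(center = c(15, 25), chirality = 1,
                               nx = 60, ny = 50, dx = 1, duration = 100)
  b <- make_vortex_phase_movie(center = c(45, 25), chirality = -1,
                               nx = 60, ny = 50, dx = 1, duration = 100)
  combined <- a
  combined$phase <- atrialbench:::.wrap_angle(a$phase + b$phase +
                                                2 * pi * 5 *
                                                rep(a$times, each = 60 * 50) /
                                                1000)
  tr <- track_singularities(combined)
  net <- tapply(tr$charge, tr$t, sum)
  expect_true(all(net == 0))
  uni <- a
  uni$phase[] <- 0.3
  expect_identical(nrow(track_singularities(uni)), 0L)
})

test_that("the singularity detector equals the brute-force winding oracle frame by frame", {
  vx <- make_vortex_phase_movie(center = c(12.3, 17.7), chirality = -1,
                                nx = 30, ny = 35, dx = 1, duration = 60)
  for (k in seq_along(vx$times)) {
    got <- atrialbench:::.frame_singularities(vx$phase[, , k], 1)
    ora <- oracle_singularities(vx$phase[, , k], 1)
    expect_equal(got[order(got$x, got$y), ], ora[order(ora$x, ora$y), ],
                 ignore_attr = TRUE)
  }
  # and on irregular smooth random fields (no false disagreements)
  set.seed(7)
  for (rep_i in 1:5) {
    z <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
    big <- matrix(0, 40, 40)
    for (i in 1:5) for (j in 1:5)
      big <- big + outer(sin(seq(0, i, length.out = 40) + Re(z[i, j])),
                         cos(seq(0, j, length.out = 40) + Im(z[i, j])))
    P <- atrialbench:::.wrap_angle(big)
    got <- atrialbench:::.frame_singularities(P, 0.5)
    ora <- oracle_singularities(P, 0.5)
    expect_equal(got[order(got$x, got$y), ], ora[order(ora$x, ora$y), ],
                 ignore_attr = TRUE)
  }
})

test_that("colliding plane waves produce no phase defect", {
  mv <- make_plane_wave_movie(speed = 500, n = 60, dx = 0.5,
                              dt_frame = 2, collide = TRUE,
                              duration = 400)
  # lift the 1D movie into a thin 2D sheet
  vm <- array(rep(mv$vm[, 1, ], each = 1), dim = c(60, 1, length(mv$times)))
  vm4 <- array(0, dim = c(60, 4, length(mv$times)))
  for (j in 1:4) vm4[, j, ] <- vm[, 1, ]
  ph <- compute_phase(vm_movie(vm4, mv$times, 0.5))
  expect_identical(nrow(track_singularities(ph)), 0L)
})

test_that("pseudo-ECG is zero for uniform fields and for an equidistant source", {
  tt <- seq(0, 100, by = 2)
  uni <- array(rep(-80 + 30 * sin(tt / 10), each = 400),
               dim = c(20, 20, length(tt)))
  pe <- pseudo_ecg(vm_movie(uni, tt, 1))
  expect_true(all(abs(pe$signal) < 1e-9))
  # single depolarized voxel on the midline between the electrodes
  vm <- array(-80, dim = c(21, 21, length(tt)))
  vm[11, 11, ] <- -80 + 100 * exp(-((tt - 50) / 10)^2)
  pe2 <- pseudo_ecg(vm_movie(vm, tt, 1))
  expect_true(all(abs(pe2$signal) < 1e-9))
})

test_that("pseudo-ECG of a plane wave is biphasic and antisymmetric under electrode swap", {
  mv1 <- make_plane_wave_movie(speed = 400, n = 40, dx = 1, dt_frame = 2,
                               apd = 80)
  vm <- array(0, dim = c(40, 40, length(mv1$times)))
  for (j in 1:40) vm[, j, ] <- mv1$vm[, 1, ]
  movie <- vm_movie(vm, mv1$times, 1)
  pe <- pseudo_ecg(movie)
  expect_gt(max(pe$signal), 0)
  expect_lt(min(pe$signal), 0)  # biphasic deflection
  el <- pe$electrodes
  pe_sw <- pseudo_ecg(movie, electrodes = el[2:1, ])
  expect_equal(pe_sw$signal, -pe$signal)
  # direct dipole-sum oracle at one frame
  k <- which.max(abs(pe$signal))
  V <- movie$vm[, , k]
  lap <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    ip <- if (i < 40) i + 1 else i; im <- if (i > 1) i - 1 else i
    jp <- if (j < 40) j + 1 else j; jm <- if (j > 1) j - 1 else j
    lap[i, j] <- V[ip, j] + V[im, j] + V[i, jp] + V[i, jm] - 4 * V[i, j]
  }
  phi <- function(e) {
    s <- 0
    for (i in 1:40) for (j in 1:40)
      s <- s + lap[i, j] / sqrt((i - 0.5 - e[1])^2 + (j - 0.5 - e[2])^2 +
                                  e[3]^2)
    s
  }
  expect_equal(pe$signal[k], phi(el[1, ]) - phi(el[2, ]),
               tolerance = 1e-10)
})

test_that("dominant frequency is exact on synthetic tones", {
  fs <- 1000
  tt <- seq(0, 4, by = 1 / fs)[-1]
  expect_equal(dominant_frequency(sin(2 * pi * 6 * tt), fs), 6,
               tolerance = 0.25 / 6)
  two <- sin(2 * pi * 3 * tt) + 2 * sin(2 * pi * 7 * tt)
  expect_equal(dominant_frequency(two, fs), 7, tolerance = 0.25 / 7)
  expect_error(dominant_frequency(rep(0, 1000), fs), "no oscillation")
})

test_that("vortex point-signal dominant frequency equals the rotation frequency", {
  vx <- make_vortex_phase_movie(frequency = 5, duration = 2000,
                                dt_frame = 2)
  df <- dominant_frequency(attr(vx, "signal"), attr(vx, "fs_hz"))
  expect_equal(df, 5, tolerance = 0.02)
  static <- make_vortex_phase_movie(frequency = 0, duration = 500)
  expect_error(dominant_frequency(attr(static, "signal"),
                                  attr(static, "fs_hz")),
               "no oscillation")
})

test_that("an S2 of zero amplitude leaves planar S1 waves without singularities", {
  mock <- std_mock()
  sim <- s1s2_cross_field(mock, sigma = 0.05, patch_mm = 20, dx = 0.5,
                          bcl = 0.5, n_s1 = 1, s2_coupling = 220,
                          s2_amp = 0, post_s2 = 300, dt = 0.02,
                          movie_dt = 4, stim_amp = 2)
  ph <- compute_phase(sim$movie)
  tr <- track_singularities(ph)
  expect_identical(nrow(tr[tr$t > sim$s2_time, ]), 0L)
})
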