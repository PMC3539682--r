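test_that("model registry exposes the three implemented models and guards plugin slots", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    m <- atrial_model(nm)
    expect_s3_class(m, "ionic_model")
    expect_equal(length(m$initial_state), length(m$state_names))
    expect_true(all(m$params >= 0 | names(m$params) == "phi_Na_en"))
  }
  expect_error(atrial_model("grandi"), "plugin slot")
  expect_error(atrial_model("noatrium"), "unknown model")
  m <- atrial_model("nygren-caf")
  expect_identical(m$variant, "caf")
})

test_that("cAF remodeling applies exactly the four stated factors and guards double application", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    ctl <- atrial_model(nm)
    caf <- apply_caf_remodeling(ctl)
    sc <- caf$params / ctl$params
    sc[is.nan(sc)] <- 1  # 0/0 for zeroed parameters
    scaled <- names(sc)[abs(sc - 1) > 1e-12]
    expect_equal(sort(unname(sc[scaled])), sort(c(0.35, 0.35, 0.51, 2.10)),
                 tolerance = 1e-12)
    untouched <- setdiff(names(ctl$params), scaled)
    expect_identical(caf$params[untouched], ctl$params[untouched])
    expect_error(apply_caf_remodeling(caf), "double-scaling")
  }
  # worked examples of the scaling factors
  ctl <- atrial_model("courtemanche")
  ctl$params[["g_CaL"]] <- 0.1
  expect_equal(apply_caf_remodeling(ctl)$params[["g_CaL"]], 0.035)
  ctl2 <- atrial_model("nygren")
  ctl2$params[["g_K1"]] <- 1.0
  expect_equal(apply_caf_remodeling(ctl2)$params[["g_K1"]], 2.10)
})

test_that("models relax to a true resting state with near-zero net current", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    m <- atrial_model(nm)
    s <- cell_step(m, m$initial_state, dt = 0.01, n = 1e6)  # 10 s free
    d <- cell_derivatives(m, s)
    # |dV/dt| < 1e-2 V/s = 1e-2 mV/ms
    expect_lt(abs(d[["V"]]), 1e-2)
    # charge-conservation sanity: net sarcolemmal current at rest is below
    # 0.5% of the peak |I_Na| of a paced beat
    cur <- current_snapshot(m, s)
    tr <- pace(m, bcl = 1, duration = 1, sample_dt = 0.05, init = s,
               record_currents = TRUE)
    peak_ina <- max(abs(tr$currents[, "I_Na"]))
    expect_lt(abs(sum(cur)), 0.005 * peak_ina)
  }
})

test_that("zero conductances give exactly zero sarcolemmal voltage change", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    m <- atrial_model(nm)
    m$params[] <- 0
    d <- cell_derivatives(m, m$initial_state)
    expect_identical(d[["V"]], 0)
  }
})

test_that("derivatives reject non-finite states with a named diagnostic", {
  m <- atrial_model("courtemanche")
  bad <- m$initial_state
  bad[["K_i"]] <- NaN
  expect_error(cell_derivatives(m, bad), "K_i")
})

test_that("Rush-Larsen equals the exact exponential gate solution", {
  # closed form on a constructed gate
  expect_equal(rush_larsen_update(0, 0.5, 1, 0.2), 0.5 * (1 - exp(-0.2)))
  # the compiled stepper's gate update matches the R closed form computed
  # from the exposed (inf, tau) pairs, at machine precision
  m <- atrial_model("nygren")
  y <- m$initial_state
  d <- cell_derivatives(m, y)
  inf <- attr(d, "inf"); tau <- attr(d, "tau"); gate <- attr(d, "gate")
  stepped <- cell_step(m, y, dt = 0.01)
  expected <- unname(y)
  for (i in which(gate))
    expected[i] <- rush_larsen_update(y[[i]], inf[i], tau[i], 0.01)
  expect_equal(unname(stepped)[gate], expected[gate], tolerance = 1e-8)
})

test_that("step-halving converges: free evolution differs < 1e-3 mV at dt/10", {
  m <- atrial_model("courtemanche")
  a <- cell_step(m, m$initial_state, dt = 0.01, n = 100)   # 1 ms
  b <- cell_step(m, m$initial_state, dt = 0.001, n = 1000)
  expect_lt(abs(a[["V"]] - b[["V"]]), 1e-3)
})

test_that("gates stay in [0,1] and concentrations positive over 50 s pacing", {
  for (nm in c("courtemanche", "nygren", "maleckar")) {
    m <- atrial_model(nm)
    s <- table_trace(nm)$final_state
    g <- s[m$gating_index]
    expect_true(all(g >= 0 & g <= 1))
    conc <- s[grep("^(Na|K|Ca)_", m$state_names)]
    expect_true(all(conc > 0))
    expect_true(all(is.finite(table_trace(nm)$vm)))
  }
})

test_that("threshold bisection recovers the mock rheobase within 1%", {
  mock <- make_mock_cell(apd = 120)
  thr <- find_threshold(mock)
  # dense amplitude sweep oracle
  fires <- vapply(seq(0.5, 1.5, by = 0.005) * thr, function(a) {
    tr <- pace(mock, bcl = 0.1, duration = 0.06, stim_amp = a)
    max(tr$vm) > 0
  }, logical(1))
  amps <- seq(0.5, 1.5, by = 0.005) * thr
  oracle <- amps[which(fires)[1]]
  expect_lt(abs(thr - oracle) / oracle, 0.011)
  # just below threshold: no AP
  tr <- pace(mock, bcl = 0.1, duration = 0.06, stim_amp = 0.97 * thr)
  expect_lt(max(tr$vm), 0)
})

test_that("voltage clamp self-normalization gives I_K1 of exactly 1", {
  m <- atrial_model("courtemanche")
  vc <- voltage_clamp(m, duration = 5)
  cur <- current_snapshot(m, vc$state, normalize = vc$divisor)
  expect_equal(abs(cur[["I_K1"]]), 1.0, tolerance = 1e-12)
})

test_that("the RK4 stiff-state override reproduces forward Euler in the smooth limit", {
  m <- atrial_model("courtemanche")
  m$stiff_index <- c(19L, 20L, 21L)  # Ca_i, Ca_up, Ca_rel
  m2 <- atrial_model("courtemanche")
  a <- cell_step(m, m$initial_state, dt = 0.01, n = 100)
  b <- cell_step(m2, m2$initial_state, dt = 0.01, n = 100)
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
  expect_false(identical(unname(a), unname(b)))  # genuinely different path
})
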