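# Synthetic fixtures with known ground truth: a mock excitable cell that
# conforms to the ionic-model plugin contract, analytic traces, plane-wave
# movies and ideal vortex phase fields.  Everything here is deterministic.

.mock_model <- function(params) {
  init <- c(V = params[["rmp"]], h = 1)
  structure(list(
    name = "mock", id = 3L, variant = "control",
    params = params, initial_state = init, state_names = names(init),
    gating_index = 2L, stiff_index = integer(0),
    stim_factor = params[["amplitude"]], cai_index = 0L,
    stim_unit = "activator/ms"), class = "ionic_model")
}

# Standard test strand on which the mock's refractoriness is defined:
# refractory periods in tissue are loaded by source-sink effects, so the
# calibrated quantity is the strand ERP measured by the same S1-S2 protocol
# used for the ionic models, on this canonical geometry.
.mock_strand <- list(sigma = 0.05, nv = 100, dx = 0.2)

.mock_strand_erp <- function(model, bcl_s) {
  p <- run_strand_protocol(model, bcl = bcl_s,
                           sigma = .mock_strand$sigma,
                           nv = .mock_strand$nv, dx = .mock_strand$dx)
  if (!all(p$capture)) return(NA_real_)
  tryCatch(as.numeric(measure_erp(p)), error = function(e) NA_real_)
}

#' Create a mock excitable cell with known AP properties
#'
#' A two-variable excitable cell (fast activator, slow recovery gate;
#' Mitchell-Schaeffer kinetics mapped onto a configurable voltage range)
#' that conforms to the ionic-model plugin contract, so every protocol in
#' the package runs on it unchanged. The recovery time constants are
#' calibrated at construction by simulate-and-adjust so that the paced
#' APD90 equals `apd` and (optionally) the single-cell S1-S2 refractory
#' interval equals `refractory`.
#'
#' @param rmp resting potential (mV).
#' @param amplitude AP amplitude (mV); must exceed `-rmp + 20` so that an
#'   AP peaks above 0 mV, and must be positive (an amplitude of 0 is an
#'   inexcitable cell and raises an error).
#' @param apd target APD90 (ms).
#' @param refractory target refractory period (ms), at least half the
#'   APD; `NULL` skips refractoriness calibration.
#' @param tau_in,tau_out,v_gate excitation kinetics (advanced knobs).
#' @param tol calibration tolerance (ms).
#' @return an `ionic_model` named `"mock"`.
#' @export
make_mock_cell <- function(rmp = -80, amplitude = 100, apd = 150,
                           refractory = NULL, tau_in = 0.3, tau_out = 6,
                           v_gate = 0.13, tol = 1) {
  if (amplitude <= 0) stop("inexcitable: amplitude must be positive")
  if (rmp + amplitude <= 10)
    stop("rmp + amplitude must exceed 10 mV for AP detection")
  stopifnot(apd > 0)
  if (!is.null(refractory) && refractory < 0.5 * apd)
    stop("refractory must be at least half the APD")

  mk <- function(tau_open, tau_close)
    .mock_model(c(rmp = rmp, amplitude = amplitude, tau_in = tau_in,
                  tau_out = tau_out, tau_open = tau_open,
                  tau_close = tau_close, v_gate = v_gate))
  paced_apd <- function(m) {
    bcl_s <- max(1, 4 * apd / 1000)
    tr <- pace(m, bcl = bcl_s, duration = 2 * bcl_s, sample_dt = 0.05)
    extract_ap_features(tr, 2)$apd[["APD90"]]
  }
  # calibrate tau_close against the paced APD90 (monotone; bisection)
  t_open <- if (is.null(refractory)) max(60, apd / 2) else refractory
  lo <- apd / 8; hi <- apd * 3
  for (i in 1:40) {
    mid <- 0.5 * (lo + hi)
    a <- paced_apd(mk(t_open, mid))
    if (!is.finite(a)) { lo <- mid; next }
    if (abs(a - apd) < 0.25 * tol) break
    if (a > apd) hi <- mid else lo <- mid
    if (hi - lo < 1e-3)
      stop(sprintf("mock APD calibration failed: achieved %.1f ms for target %.1f",
                   a, apd))
  }
  tau_close <- mid
  model <- mk(t_open, tau_close)

  if (!is.null(refractory)) {
    # calibrate tau_open against the strand ERP measured by the tissue
    # S1-S2 protocol on the standard test strand (the tissue ERP, not the
    # isolated-cell one, is what the protocols report)
    bcl_s <- max(0.6, 1.5 * (refractory + 100) / 1000)
    lo <- 2; hi <- max(4 * refractory, 200)
    e <- NA_real_
    for (i in 1:30) {
      mid <- 0.5 * (lo + hi)
      e <- .mock_strand_erp(mk(mid, tau_close), bcl_s)
      if (is.finite(e) && abs(e - refractory) < tol) break
      if (!is.finite(e) || e > refractory) hi <- mid else lo <- mid
      if (hi - lo < 0.05)
        stop(sprintf(
          "mock refractory calibration failed: achieved %.1f ms for target %.1f",
          e, refractory))
    }
    model <- mk(mid, tau_close)
  }
  achieved <- paced_apd(model)
  if (abs(achieved - apd) > max(tol, 0.02 * apd))
    stop(sprintf("mock APD calibration failed: achieved %.1f ms for target %.1f",
                 achieved, apd))
  attr(model, "achieved_apd") <- achieved
  model
}

# stereotyped AP waveform: 1 ms upstroke, brief plateau, linear
# repolarization ending at `apd` ms, smooth tail
.ap_shape <- function(s, apd = 150) {
  v <- numeric(length(s))
  up <- s >= 0 & s < 1
  v[up] <- s[up]
  rep_ <- s >= 1 & s < apd
  v[rep_] <- 1 - 0.9 * (s[rep_] - 1) / (apd - 1)
  tail_ <- s >= apd & s < apd + 30
  v[tail_] <- 0.1 * (1 - (s[tail_] - apd) / 30)
  v
}

#' Analytic plane-wave voltage movie with known speed
#'
#' A stereotyped AP waveform travelling at `speed`; the analytic
#' activation map is attached so that [measure_cv()] recovers the speed
#' exactly.
#'
#' @param speed wave speed (mm/s).
#' @param direction `+1` (left to right) or `-1`.
#' @param n,dx strand size (voxels) and spacing (mm).
#' @param dt_frame frame period (ms).
#' @param duration movie length (ms); defaults to transit time + APD.
#' @param rmp,amplitude,apd waveform parameters.
#' @param collide when TRUE, launch a second, opposite wave so the two
#'   annihilate mid-strand (no phase defect).
#' @return a [vm_movie()] (ny = 1) with attribute `activation`
#'   (an [activation_map()]).
#' @export
make_plane_wave_movie <- function(speed = 750, direction = 1, n = 200,
                                  dx = 0.1, dt_frame = 1, duration = NULL,
                                  rmp = -80, amplitude = 100, apd = 150,
                                  collide = FALSE) {
  stopifnot(speed > 0)
  x <- (seq_len(n) - 0.5) * dx
  L <- n * dx
  act <- if (direction > 0) x / speed * 1000 else (L - x) / speed * 1000
  if (is.null(duration)) duration <- max(act) + apd + 60
  times <- seq(0, duration, by = dt_frame)
  vm <- array(rmp, dim = c(n, 1, length(times)))
  for (k in seq_along(times)) {
    v <- .ap_shape(times[k] - act, apd)
    if (collide) {
      act2 <- if (direction > 0) (L - x) / speed * 1000 else x / speed * 1000
      v <- pmax(v, .ap_shape(times[k] - act2, apd))
    }
    vm[, 1, k] <- rmp + amplitude * v
  }
  out <- vm_movie(vm, times, dx)
  attr(out, "activation") <- activation_map(act, dx)
  out
}

#' Ideal rigidly rotating vortex phase field
#'
#' theta(x, y, t) = chirality * atan2(y - cy, x - cx) - 2 pi f t, wrapped
#' to (-pi, pi]. [track_singularities()] recovers the center within one
#' voxel with charge equal to the chirality; the synthesized point signal
#' `cos(theta)` at the `probe` has dominant frequency `frequency`.
#'
#' @param center vortex center (mm, length 2).
#' @param chirality +1 or -1.
#' @param frequency rotation frequency (Hz).
#' @param nx,ny,dx grid.
#' @param dt_frame frame period (ms).
#' @param duration movie length (ms).
#' @param probe voxel index (length 2) for the synthesized signal.
#' @return a `phase_movie` with attributes `signal` (numeric),
#'   `fs_hz`, `center`, `chirality`, `frequency`.
#' @export
make_vortex_phase_movie <- function(center = c(25, 25), chirality = 1,
                                    frequency = 5, nx = 50, ny = 50,
                                    dx = 1, dt_frame = 2, duration = 1000,
                                    probe = c(5, 5)) {
  stopifnot(chirality %in% c(-1, 1))
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  base <- chirality * outer(xs - center[1], ys - center[2],
                            function(a, b) atan2(b, a))
  times <- seq(0, duration, by = dt_frame)
  ph <- array(NA_real_, dim = c(nx, ny, length(times)))
  for (k in seq_along(times))
    ph[, , k] <- .wrap_angle(base - 2 * pi * frequency * times[k] / 1000)
  sig <- cos(ph[probe[1], probe[2], ])
  structure(list(phase = ph, times = times, dx = dx,
                 dt_frame = dt_frame, method = "analytic"),
            class = "phase_movie",
            signal = sig, fs_hz = 1000 / dt_frame, center = center,
            chirality = chirality, frequency = frequency)
}

#' Synthetic single-beat trace with linear repolarization
#'
#' Rest at `rmp`, instantaneous jump to `peak` at the stimulus, linear
#' return to `rmp` over `repol_ms`; by construction APD50 is half and
#' APD90 nine-tenths of `repol_ms`.
#'
#' @param rmp,peak voltages (mV).
#' @param repol_ms repolarization duration (ms).
#' @param pre_ms,post_ms quiet padding.
#' @param dt_sample sampling period (ms).
#' @export
synthetic_linear_ap <- function(rmp = -80, peak = 20, repol_ms = 200,
                                pre_ms = 20, post_ms = 100,
                                dt_sample = 0.05) {
  tt <- seq(0, pre_ms + repol_ms + post_ms, by = dt_sample)
  t0 <- pre_ms
  vv <- ifelse(tt < t0, rmp,
               ifelse(tt <= t0 + repol_ms,
                      peak - (peak - rmp) * (tt - t0) / repol_ms, rmp))
  as_ap_trace(tt, vv, stim_times = t0)
}
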