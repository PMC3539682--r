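#' Movie of membrane voltage on a 2D patch
#'
#' Container used by the rotor analysis chain: a 3D array `vm[nx, ny, nt]`
#' (mV) with frame times (ms) and voxel size (mm).
#'
#' @param vm 3D array (nx, ny, nt).
#' @param times frame times (ms), uniform.
#' @param dx voxel size (mm).
#' @export
vm_movie <- function(vm, times, dx) {
  stopifnot(length(dim(vm)) == 3, dim(vm)[3] == length(times))
  structure(list(vm = vm, times = times, dx = dx,
                 dt_frame = if (length(times) > 1) times[2] - times[1]
                 else NA_real_),
            class = "vm_movie")
}

#' @export
print.vm_movie <- function(x, ...) {
  d <- dim(x$vm)
  cat(sprintf("<vm_movie> %d x %d voxels (dx %g mm), %d frames @ %g ms\n",
              d[1], d[2], x$dx, d[3], x$dt_frame))
  invisible(x)
}

#' S1-S2 cross-field rotor initiation on a 2D patch
#'
#' The patch is seeded with the state of a single cell pre-paced for 50
#' beats at the S1 BCL; planar S1 beats are delivered from the left edge,
#' then a premature S2 is applied to the lower half of the patch
#' (cross-field geometry). Returns the voltage movie from the final S1
#' onward for phase-singularity and pseudo-ECG analysis. Failure to
#' initiate a rotor is a result, not an error.
#'
#' @param model an `ionic_model`.
#' @param sigma tissue conductivity (mS/mm); for cAF use 0.70x the
#'   control-tuned value (or any further reduction for scaled-down
#'   patches).
#' @param patch_mm patch edge length (mm); the full-scale experiment uses
#'   100 mm, desk-scale runs use smaller patches.
#' @param dx voxel size (mm).
#' @param bcl S1 cycle length (s), default 0.4.
#' @param n_s1 number of S1 beats (protocol default 4).
#' @param s2_coupling S2 coupling interval after the last S1 (ms).
#' @param s2_amp,stim_amp S2 / S1 amplitudes (native units); `stim_amp`
#'   defaults to 1.2x the tissue threshold measured on an equivalent
#'   strand, `s2_amp` to twice that.
#' @param post_s2 recorded time after S2 (ms).
#' @param dt integration step (ms).
#' @param movie_dt frame period of the returned movie (ms).
#' @param prepace_beats single-cell pre-pacing beats.
#' @return a `rotor_sim` list: `movie` (a [vm_movie()] starting at the
#'   final S1), `s2_time` (ms on the movie clock), geometry and stimulus
#'   metadata.
#' @export
s1s2_cross_field <- function(model, sigma, patch_mm = 100, dx = 0.1,
                             bcl = 0.4, n_s1 = 4, s2_coupling = 180,
                             stim_amp = NULL, s2_amp = NULL,
                             post_s2 = 1000, dt = 0.01, movie_dt = 4,
                             prepace_beats = 50) {
  stopifnot(inherits(model, "ionic_model"))
  n <- round(patch_mm / dx)
  bcl_ms <- bcl * 1000
  seed <- prepaced_state(model, bcl, n_beats = prepace_beats, dt = dt)
  if (is.null(stim_amp))
    stim_amp <- 1.2 * find_tissue_threshold(model, seed, nv = n, dx = dx,
                                            sigma = sigma, dt = dt,
                                            window = 300)
  if (is.null(s2_amp)) s2_amp <- 2 * stim_amp
  D <- .sigma_to_D(sigma)
  if (dt > dx^2 / (4 * D))
    warning(sprintf("dt = %g ms violates the 2D stability bound %g ms",
                    dt, dx^2 / (4 * D)))
  seed_m <- matrix(seed, nrow = length(seed), ncol = 1)
  rk4 <- as.integer(model$stiff_index) - 1L

  # S1 beats 1..(n_s1-1): no recording needed, carry the state
  if (n_s1 > 1) {
    stims_a <- cbind(t0 = (seq_len(n_s1 - 1) - 1) * bcl_ms, dur = 2,
                     amp = stim_amp, x0 = 1, x1 = 2, y0 = 1, y1 = n)
    ra <- run_patch_cpp(model$id, unname(model$params), seed_m, n, n, dx,
                        D, dt, (n_s1 - 1) * bcl_ms,
                        .patch_stim_matrix(stims_a),
                        (n_s1 - 1) * bcl_ms, TRUE, rk4)
    state <- ra$state
  } else state <- seed_m

  # final S1 + cross-field S2 on the lower half, recorded as a movie
  dur_b <- s2_coupling + post_s2
  stims_b <- rbind(
    cbind(t0 = 0, dur = 2, amp = stim_amp, x0 = 1, x1 = 2, y0 = 1, y1 = n),
    cbind(t0 = s2_coupling, dur = 2, amp = s2_amp, x0 = 1, x1 = n,
          y0 = 1, y1 = floor(n / 2)))
  rb <- run_patch_cpp(model$id, unname(model$params), state, n, n, dx, D,
                      dt, dur_b, .patch_stim_matrix(stims_b), movie_dt,
                      FALSE, rk4)
  mv <- vm_movie(array(rb$movie, dim = c(n, n, ncol(rb$movie))),
                 rb$movie_t, dx)
  structure(list(movie = mv, s2_time = s2_coupling, bcl = bcl,
                 n_s1 = n_s1, patch_mm = patch_mm, sigma = sigma,
                 stim_amp = stim_amp, s2_amp = s2_amp,
                 model_name = model$name, variant = model$variant),
            class = "rotor_sim")
}

# principal value of an angle difference (same convention as Arg())
.wrap_angle <- function(x) atan2(sin(x), cos(x))

#' Phase field of a voltage movie (analytic-signal construction)
#'
#' Per-voxel phase of the mean-subtracted V_m time series via the Hilbert
#' transform (FFT construction of the analytic signal). Voxels whose
#' peak-to-peak oscillation is below `amp_floor` carry undefined (NA)
#' phase. A time-delay-embedding variant
#' (`method = "delay"`, phase = atan2(V(t+tau) - mean, V(t) - mean)) is
#' available for cross-checks.
#'
#' @param movie a [vm_movie()].
#' @param amp_floor minimum peak-to-peak V_m (mV) for a defined phase.
#' @param method `"hilbert"` (default) or `"delay"`.
#' @param tau embedding delay (ms) for the delay method (about half an
#'   APD).
#' @return a `phase_movie`: array `phase[nx, ny, nt]` in (-pi, pi] plus
#'   frame times and dx.
#' @export
compute_phase <- function(movie, amp_floor = 1, method = c("hilbert",
                                                           "delay"),
                          tau = 60) {
  stopifnot(inherits(movie, "vm_movie"))
  method <- match.arg(method)
  d <- dim(movie$vm)
  nt <- d[3]
  if (nt < 4) stop("need at least 4 frames")
  x <- matrix(movie$vm, nrow = d[1] * d[2], ncol = nt)  # voxels x time
  rng <- apply(x, 1, function(v) diff(range(v)))
  x <- x - rowMeans(x)
  if (method == "hilbert") {
    # analytic signal via FFT on each voxel's series
    h <- numeric(nt)
    if (nt %% 2 == 0) {
      h[1] <- 1; h[nt / 2 + 1] <- 1; h[2:(nt / 2)] <- 2
    } else {
      h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
    }
    X <- t(stats::mvfft(t(x)))
    X <- sweep(X, 2, h, `*`)
    a <- t(stats::mvfft(t(X), inverse = TRUE)) / nt
    ph <- matrix(atan2(Im(a), Re(a)), nrow = nrow(x))
  } else {
    k <- max(1L, round(tau / movie$dt_frame))
    ph <- matrix(NA_real_, nrow = nrow(x), ncol = nt)
    idx <- seq_len(nt - k)
    ph[, idx] <- atan2(x[, idx + k], x[, idx])
  }
  ph[rng < amp_floor, ] <- NA_real_
  structure(list(phase = array(ph, dim = d), times = movie$times,
                 dx = movie$dx, dt_frame = movie$dt_frame,
                 method = method),
            class = "phase_movie")
}

# phase singularities of one phase frame: plaquettes whose discrete line
# integral of wrapped phase differences is +-2*pi
.frame_singularities <- function(P, dx) {
  nx <- nrow(P); ny <- ncol(P)
  a <- P[-nx, -ny]; b <- P[-1, -ny]; c <- P[-1, -1]; d <- P[-nx, -1]
  w <- .wrap_angle(b - a) + .wrap_angle(c - b) + .wrap_angle(d - c) +
    .wrap_angle(a - d)
  q <- round(w / (2 * pi))
  q[!is.finite(q)] <- 0L
  hit <- which(q != 0, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(x = numeric(0), y = numeric(0), charge = integer(0)))
  data.frame(x = hit[, 1] * dx, y = hit[, 2] * dx,
             charge = as.integer(q[hit]))
}

#' Track phase singularities through a phase movie
#'
#' A singularity sits on a 2x2 plaquette where the discrete line integral
#' of wrapped phase differences equals +-2*pi (topological charge +-1).
#' Singularities are linked across frames by nearest-neighbour matching
#' within a radius scaled to the frame period.
#'
#' @param phase a `phase_movie` from [compute_phase()].
#' @param link_radius linking radius in mm per ms of frame period
#'   (default 2).
#' @return a `SingularityTrack` data.frame with columns `t` (ms), `x`,
#'   `y` (mm), `charge`, `id`.
#' @export
track_singularities <- function(phase, link_radius = 2) {
  stopifnot(inherits(phase, "phase_movie"))
  d <- dim(phase$phase)
  radius <- max(link_radius * phase$dt_frame, phase$dx * 2)
  rows <- list(); prev <- NULL; next_id <- 1L
  for (k in seq_len(d[3])) {
    s <- .frame_singularities(phase$phase[, , k], phase$dx)
    if (nrow(s)) {
      s$t <- phase$times[k]
      s$id <- NA_integer_
      if (!is.null(prev) && nrow(prev)) {
        for (i in seq_len(nrow(s))) {
          dd <- sqrt((prev$x - s$x[i])^2 + (prev$y - s$y[i])^2)
          dd[prev$charge != s$charge[i]] <- Inf
          j <- which.min(dd)
          if (length(j) && dd[j] <= radius) {
            s$id[i] <- prev$id[j]
            prev <- prev[-j, , drop = FALSE]
          }
        }
      }
      new <- is.na(s$id)
      if (any(new)) {
        s$id[new] <- seq(next_id, length.out = sum(new))
        next_id <- next_id + sum(new)
      }
      rows[[length(rows) + 1]] <- s
      prev <- s
    } else prev <- NULL
  }
  if (!length(rows))
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      charge = integer(0), id = integer(0)))
  out <- do.call(rbind, rows)[, c("t", "x", "y", "charge", "id")]
  rownames(out) <- NULL
  out
}

#' Pseudo-ECG of a voltage movie
#'
#' Infinite-volume-conductor lead field: the potential at an electrode is
#' the sum over voxels of the intercellular current source density
#' (the discrete Laplacian of V_m) weighted by 1/r; the signal is the
#' difference between two electrodes placed 5 mm above the patch plane and
#' 10 mm apart, centered over the patch. Amplitudes are in arbitrary
#' units (the constant prefactor cancels in dominant-frequency analysis).
#'
#' @param movie a [vm_movie()].
#' @param electrodes 2x3 matrix of electrode positions (mm; columns x, y,
#'   z with the patch in the z = 0 plane); default geometry as above.
#' @return a `pseudo_ecg` list: `t` (ms), `signal`, `fs_hz`, `electrodes`.
#' @export
pseudo_ecg <- function(movie, electrodes = NULL) {
  stopifnot(inherits(movie, "vm_movie"))
  d <- dim(movie$vm)
  nx <- d[1]; ny <- d[2]; nt <- d[3]; dx <- movie$dx
  if (is.null(electrodes)) {
    cx <- nx * dx / 2; cy <- ny * dx / 2
    electrodes <- rbind(c(cx - 5, cy, 5), c(cx + 5, cy, 5))
  }
  if (any(electrodes[, 3] == 0))
    stop("electrode lies in the tissue plane")
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  w <- lapply(1:2, function(e) {
    r <- sqrt(outer((xs - electrodes[e, 1])^2,
                    (ys - electrodes[e, 2])^2, `+`) + electrodes[e, 3]^2)
    1 / r
  })
  sig <- numeric(nt)
  for (k in seq_len(nt)) {
    V <- movie$vm[, , k]
    up <- V[c(2:nx, nx), ]; dn <- V[c(1, 1:(nx - 1)), ]
    lf <- V[, c(1, 1:(ny - 1))]; rt <- V[, c(2:ny, ny)]
    lap <- up + dn + lf + rt - 4 * V
    sig[k] <- sum(lap * w[[1]]) - sum(lap * w[[2]])
  }
  structure(list(t = movie$times, signal = sig,
                 fs_hz = 1000 / movie$dt_frame, electrodes = electrodes),
            class = "pseudo_ecg")
}

#' Dominant frequency of a signal
#'
#' Largest spectral magnitude peak in the `band` (default 1-30 Hz) of the
#' mean-removed, Hann-windowed signal, zero-padded to at least 0.1 Hz
#' resolution. At least ~2 s of signal is recommended for rotor analysis;
#' shorter segments raise a warning.
#'
#' @param x a `pseudo_ecg` or numeric signal.
#' @param fs_hz sampling rate (Hz) when `x` is numeric.
#' @param band frequency search band (Hz).
#' @param min_seconds advisory minimum duration (s).
#' @return dominant frequency (Hz).
#' @export
dominant_frequency <- function(x, fs_hz = NULL, band = c(1, 30),
                               min_seconds = 2) {
  if (inherits(x, "pseudo_ecg")) {
    fs_hz <- x$fs_hz
    x <- x$signal
  }
  stopifnot(is.numeric(x), !is.null(fs_hz))
  if (all(abs(x - x[1]) < 1e-12)) stop("no oscillation in signal")
  n <- length(x)
  if (n / fs_hz < min_seconds)
    warning(sprintf("signal is %.2f s; at least %g s recommended",
                    n / fs_hz, min_seconds))
  x <- x - mean(x)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  x <- x * hann
  nfft <- max(2^ceiling(log2(n)), 2^ceiling(log2(fs_hz / 0.1)))
  X <- abs(stats::fft(c(x, numeric(nfft - n))))[1:(nfft %/% 2)]
  fr <- (seq_len(nfft %/% 2) - 1) * fs_hz / nfft
  sel <- fr >= band[1] & fr <= band[2]
  if (!any(sel)) stop("band is empty at this sampling rate")
  fr[sel][which.max(X[sel])]
}

#' Did a simulation initiate a sustained rotor?
#'
#' Success means a phase singularity persists for at least `persist_ms`
#' after the S2 stimulus.
#'
#' @param sim a `rotor_sim` from [s1s2_cross_field()].
#' @param persist_ms persistence requirement (ms), default 1000 (the
#'   full-scale criterion; scaled-down runs pass a shorter window).
#' @param amp_floor phase amplitude floor (mV).
#' @return logical with attribute `tracks` (the singularity table).
#' @export
rotor_initiated <- function(sim, persist_ms = 1000, amp_floor = 1) {
  stopifnot(inherits(sim, "rotor_sim"))
  ph <- compute_phase(sim$movie, amp_floor = amp_floor)
  tr <- track_singularities(ph)
  post <- tr[tr$t > sim$s2_time, , drop = FALSE]
  ok <- FALSE
  if (nrow(post)) {
    span <- tapply(post$t, post$id, function(t) diff(range(t)))
    last <- max(post$t)
    horizon <- max(sim$movie$times)
    ok <- any(span >= persist_ms) ||
      (last >= horizon - 2 * sim$movie$dt_frame &&
         diff(range(post$t)) >= min(persist_ms, horizon - sim$s2_time -
                                      4 * sim$movie$dt_frame))
  }
  structure(ok, tracks = tr)
}
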