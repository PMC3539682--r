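#' Pace a single cell at a fixed basic cycle length
#'
#' Runs the single-cell pacing protocol: rectangular stimuli of
#' `stim_dur` ms at `stim_scale` times the diastolic threshold, delivered
#' every `bcl` seconds for `duration` seconds (a run shorter than one BCL
#' still delivers exactly one stimulus). The default protocol for
#' steady-state characterization is 50 s at BCL 1 s with dt = 0.01 ms.
#'
#' @param model an `ionic_model` (see [atrial_model()]).
#' @param bcl basic cycle length (s).
#' @param duration total paced time (s).
#' @param dt integration step (ms).
#' @param stim_scale stimulus amplitude as a multiple of threshold
#'   (ignored when `stim_amp` is given).
#' @param stim_amp explicit stimulus amplitude in native units.
#' @param stim_dur stimulus pulse duration (ms).
#' @param sample_dt trace sampling period (ms); must be at most 0.1 ms for
#'   accurate feature extraction.
#' @param init initial state (defaults to the model's published state).
#' @param record_currents record the 12 common sarcolemmal currents at each
#'   sample.
#' @return an `ap_trace`: uniformly sampled `time` (ms), `vm` (mV), `cai`
#'   (mM, when the model carries intracellular calcium), stimulus event
#'   times, per-beat upstroke statistics, per-beat capture flags and the
#'   final state.
#' @export
pace <- function(model, bcl = 1, duration = 50, dt = 0.01, stim_scale = 2,
                 stim_amp = NULL, stim_dur = 2, sample_dt = 0.05,
                 init = NULL, record_currents = FALSE) {
  stopifnot(inherits(model, "ionic_model"), bcl > 0, duration > 0)
  if (is.null(init)) init <- model$initial_state
  if (is.null(stim_amp))
    stim_amp <- stim_scale * find_threshold(model, state = init,
                                            pulse_duration = stim_dur,
                                            dt = dt)
  bcl_ms <- bcl * 1000
  n_stim <- max(1L, ceiling((duration * 1000 - 1e-6) / bcl_ms))
  stim_times <- (seq_len(n_stim) - 1) * bcl_ms
  r <- run_cell_cpp(model$id, unname(model$params), unname(init),
                    duration * 1000, dt, stim_times, stim_dur, stim_amp,
                    sample_dt, model$cai_index - 1L, record_currents,
                    as.integer(model$stiff_index) - 1L)
  beats <- r$beats
  colnames(beats) <- c("t_dvdt_max", "dvdt_max", "d_prev", "d_next",
                       "v_peak", "v_pre")
  state <- r$state
  names(state) <- model$state_names
  # a captured beat shows a genuine regenerative upstroke: ionic dV/dt
  # well above passive charging and a peak well above the take-off level
  # (at fast pacing real APs may peak below 0 mV)
  capture <- beats[, "dvdt_max"] > 5 &
    beats[, "v_peak"] > beats[, "v_pre"] + 40
  if (!all(capture))
    message(sum(!capture), " of ", length(capture),
            " stimuli failed to elicit an AP")
  out <- list(time = r$time, vm = r$vm,
              cai = if (model$cai_index > 0) r$cai else NULL,
              stim_times = stim_times, beats = beats, capture = capture,
              dt_sample = sample_dt, bcl_ms = bcl_ms, stim_amp = stim_amp,
              stim_dur = stim_dur, model_name = model$name,
              variant = model$variant, final_state = state)
  if (record_currents) {
    colnames(r$currents) <- atrial_current_names()
    out$currents <- r$currents
  }
  class(out) <- "ap_trace"
  out
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %s (%s): %d beats @ BCL %g ms, %d samples\n",
              x$model_name, x$variant, length(x$stim_times), x$bcl_ms,
              length(x$time)))
  invisible(x)
}

#' Build an `ap_trace` from raw series (synthetic traces, file import)
#'
#' @param time,vm sampled time base (ms, uniform) and voltage (mV).
#' @param cai optional intracellular calcium (mM).
#' @param stim_times stimulus event times (ms).
#' @export
as_ap_trace <- function(time, vm, cai = NULL, stim_times = 0) {
  stopifnot(length(time) == length(vm))
  structure(list(time = time, vm = vm, cai = cai, stim_times = stim_times,
                 beats = NULL, capture = NULL,
                 dt_sample = if (length(time) > 1) time[2] - time[1] else NA,
                 bcl_ms = if (length(stim_times) > 1)
                   diff(stim_times)[1] else NA,
                 model_name = "synthetic", variant = "control"),
            class = "ap_trace")
}

# locate a beat's sample window [stim_i, stim_{i+1}) in a trace
.beat_window <- function(trace, beat) {
  t0 <- trace$stim_times[beat]
  t1 <- if (beat < length(trace$stim_times))
    trace$stim_times[beat + 1] else trace$time[length(trace$time)] + 1e-9
  which(trace$time >= t0 - 1e-9 & trace$time < t1)
}

# parabolic refinement of the upstroke time from (prev, max, next) dV/dt
.refine_tmax <- function(tmax, dmax, dprev, dnext, dt) {
  den <- dprev - 2 * dmax + dnext
  if (!is.finite(den) || abs(den) < 1e-12 || !is.finite(dprev) ||
      !is.finite(dnext)) return(tmax)
  tmax + 0.5 * (dprev - dnext) / den * dt
}

#' Extract action-potential and calcium-transient features from one beat
#'
#' Measurement conventions: RMP is the membrane voltage immediately before
#' the stimulus; amplitude is peak minus RMP; APDx runs from the time of
#' maximum upstroke velocity to the first crossing of
#' (peak - x% of amplitude) on the repolarizing limb (linear interpolation
#' between samples); dV/dt_max is taken from the integrator's per-step
#' maximum when available, otherwise from finite differences. CaT diastolic
#' level is the pre-stimulus calcium, CaT amplitude the beat peak minus
#' diastolic level (both in uM).
#'
#' @param trace an `ap_trace`.
#' @param beat_index which beat (default: the terminal beat).
#' @param apd_levels repolarization percentages to report (APD at each).
#' @return an `ap_features` list: `amplitude_mv`, `rmp_mv`, `apd` (named
#'   vector, ms; `NA` with reason when a level is not reached before the
#'   next stimulus), `dvdt_max_v_per_s`, `peak_mv`, `t_upstroke_ms`,
#'   `cat_diastolic_um`, `cat_amplitude_um`.
#' @export
extract_ap_features <- function(trace, beat_index = NULL,
                                apd_levels = c(50, 90)) {
  stopifnot(inherits(trace, "ap_trace"))
  nb <- length(trace$stim_times)
  if (is.null(beat_index)) beat_index <- nb
  stopifnot(beat_index >= 1, beat_index <= nb)
  idx <- .beat_window(trace, beat_index)
  tt <- trace$time[idx]; vv <- trace$vm[idx]
  if (length(idx) < 5) stop("beat not fully contained in trace")

  if (!is.null(trace$beats)) {
    b <- trace$beats[beat_index, ]
    rmp <- b[["v_pre"]]
    dvdt_max <- b[["dvdt_max"]]
    t_up <- .refine_tmax(b[["t_dvdt_max"]], b[["dvdt_max"]], b[["d_prev"]],
                         b[["d_next"]], trace$time[2] - trace$time[1])
  } else {
    # pre-stimulus voltage: the last sample before the window opens (the
    # window itself starts at the stimulus), which also lets the finite
    # difference see an upstroke landing on the first window sample
    lo <- max(idx[1] - 1, 1)
    rmp <- trace$vm[lo]
    tt2 <- trace$time[lo:idx[length(idx)]]
    vv2 <- trace$vm[lo:idx[length(idx)]]
    dv <- diff(vv2) / diff(tt2)
    k <- which.max(dv)
    dvdt_max <- dv[k]
    t_up <- tt2[k]
  }
  pk <- which.max(vv)
  peak <- vv[pk]
  amplitude <- peak - rmp
  if (amplitude < 10 || peak < rmp + 10)
    stop("no AP detected in beat ", beat_index,
         " (amplitude ", signif(amplitude, 3), " mV)")

  apd <- setNames(rep(NA_real_, length(apd_levels)),
                  paste0("APD", apd_levels))
  reason <- setNames(rep(NA_character_, length(apd_levels)), names(apd))
  for (q in seq_along(apd_levels)) {
    target <- peak - apd_levels[q] / 100 * amplitude
    below <- which(vv[pk:length(vv)] <= target)
    if (!length(below)) {
      reason[q] <- "level not reached before next stimulus"
      next
    }
    j <- pk + below[1] - 1
    if (j == pk) { t_cross <- tt[j] } else {
      f <- (vv[j - 1] - target) / (vv[j - 1] - vv[j])
      t_cross <- tt[j - 1] + f * (tt[j] - tt[j - 1])
    }
    apd[q] <- t_cross - t_up
  }

  cat_dia <- cat_amp <- NA_real_
  if (!is.null(trace$cai)) {
    cc <- trace$cai[idx]
    cat_dia <- cc[1] * 1000
    cat_amp <- max(cc) * 1000 - cat_dia
  }
  structure(list(amplitude_mv = amplitude, rmp_mv = rmp, apd = apd,
                 apd_undefined_reason = reason,
                 dvdt_max_v_per_s = dvdt_max, peak_mv = peak,
                 t_upstroke_ms = t_up, cat_diastolic_um = cat_dia,
                 cat_amplitude_um = cat_amp, beat_index = beat_index),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf(
    "<ap_features> beat %d: amp %.2f mV, RMP %.2f mV, APD %s, dV/dt_max %.1f V/s\n",
    x$beat_index, x$amplitude_mv, x$rmp_mv,
    paste(sprintf("%s=%.1f", names(x$apd), x$apd), collapse = " "),
    x$dvdt_max_v_per_s))
  invisible(x)
}

#' Classify beat-to-beat APD alternans
#'
#' Successive-beat APD differences above `threshold` (default 2 ms, above
#' numerical jitter) count as alternating. A consistently sign-alternating
#' difference sequence is period-2 (amplitude = mean |APD_n - APD_(n+1)|);
#' a repeating long-short-short pattern is period-3; anything else with
#' large differences is irregular.
#'
#' @param apd numeric APD sequence from a steady pacing window (>= 8 beats).
#' @param threshold alternation threshold (ms).
#' @return list with `class` (`"none"`, `"period-2"`, `"period-3"`,
#'   `"irregular"`) and `amplitude` (ms).
#' @export
detect_alternans <- function(apd, threshold = 2) {
  apd <- apd[is.finite(apd)]
  if (length(apd) < 8) stop("need at least 8 steady-window beats")
  d <- diff(apd)
  amp <- mean(abs(d))
  if (all(abs(d) <= threshold))
    return(list(class = "none", amplitude = amp))
  # period-3 first (a long-short-short pattern has sign-alternating
  # above-threshold differences and would otherwise masquerade as
  # period-2): one residue class consistently longer than the other two
  n3 <- (length(apd) %/% 3) * 3
  if (n3 >= 9) {
    x <- apd[seq_len(n3)]
    cls <- rep(1:3, length.out = n3)
    mu <- tapply(x, cls, mean)
    sdw <- max(tapply(x, cls, sd))
    top <- which.max(mu)
    sep <- mu[top] - max(mu[-top])
    if (is.finite(sdw) && sep > threshold && sdw < sep / 2)
      return(list(class = "period-3", amplitude = sep))
  }
  # period-2: differences alternate in sign (small differences from
  # amplitude modulation of the alternans are ignored by the sign test)
  s <- sign(d[abs(d) > threshold / 2])
  p2 <- length(s) > 3 && mean(s[-1] * s[-length(s)] < 0) > 0.9 &&
    amp > threshold
  if (p2) return(list(class = "period-2", amplitude = amp))
  list(class = "irregular", amplitude = amp)
}

#' Single-cell APD restitution over a BCL grid with alternans classification
#'
#' Each BCL is run independently from the model's published initial state
#' for `duration` seconds; the APD50 of every beat in the final
#' `analysis_window` seconds is reported together with the alternans class
#' of that window. Stimuli that fail to capture are recorded, not raised.
#'
#' @param model an `ionic_model`.
#' @param bcl_grid BCLs (s), defaults to 1.0-0.3 in 0.1 steps plus 0.25
#'   and 0.2.
#' @param duration run length per BCL (s).
#' @param analysis_window trailing window (s) used for APD reporting and
#'   classification.
#' @param dt integration step (ms).
#' @return list with `beats` (data.frame: bcl, beat, t_stim_ms, apd50) and
#'   `summary` (data.frame: bcl, class, amplitude, capture_ok).
#' @export
restitution_single_cell <- function(model,
                                    bcl_grid = c(seq(1, 0.3, by = -0.1),
                                                 0.25, 0.2),
                                    duration = 30, analysis_window = 10,
                                    dt = 0.01) {
  beats <- list(); summ <- list()
  for (bcl in bcl_grid) {
    tr <- pace(model, bcl = bcl, duration = duration, dt = dt,
               sample_dt = 0.1)
    nb <- length(tr$stim_times)
    sel <- which(tr$stim_times >= (duration - analysis_window) * 1000)
    apd50 <- vapply(sel, function(i) {
      f <- tryCatch(extract_ap_features(tr, i, apd_levels = 50),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$apd[["APD50"]]
    }, numeric(1))
    alt <- if (sum(is.finite(apd50)) >= 8)
      detect_alternans(apd50) else list(class = NA_character_,
                                        amplitude = NA_real_)
    beats[[length(beats) + 1]] <- data.frame(
      bcl = bcl, beat = sel, t_stim_ms = tr$stim_times[sel], apd50 = apd50)
    summ[[length(summ) + 1]] <- data.frame(
      bcl = bcl, class = alt$class, amplitude = alt$amplitude,
      capture_ok = all(tr$capture))
  }
  list(beats = do.call(rbind, beats), summary = do.call(rbind, summ))
}

#' Long-term stability protocol
#'
#' Either 20 min of pacing at BCL 1 s with per-beat AP features, or 20 min
#' quiescent followed by 10 min of pacing with the resting membrane
#' potential sampled throughout. Runs are chunked to bound memory.
#'
#' @param model an `ionic_model`.
#' @param schedule `"paced"` or `"quiescent_paced"`.
#' @param pace_minutes,quiescent_minutes,post_minutes schedule durations.
#' @param bcl pacing BCL (s).
#' @param dt integration step (ms).
#' @param chunk_beats beats per integration chunk.
#' @return a `stability_record` list with `beats` (data.frame: beat,
#'   t_min, apd50, apd90, amplitude, rmp) and/or `rmp` (data.frame: t_min,
#'   rmp sampled at 1 Hz or faster).
#' @export
long_term_stability <- function(model,
                                schedule = c("paced", "quiescent_paced"),
                                pace_minutes = 20, quiescent_minutes = 20,
                                post_minutes = 10, bcl = 1, dt = 0.01,
                                chunk_beats = 50) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(model, "ionic_model"))
  amp <- 2 * find_threshold(model)
  state <- model$initial_state
  out <- list(schedule = schedule)
  rmp_series <- NULL

  if (schedule == "quiescent_paced") {
    tq <- quiescent_minutes * 60 * 1000
    chunk <- 60 * 1000
    rows <- list(); done <- 0
    while (done < tq) {
      len <- min(chunk, tq - done)
      r <- run_cell_cpp(model$id, unname(model$params), unname(state),
                        len, dt, numeric(0), 0, 0, 100,
                        model$cai_index - 1L, FALSE,
                        as.integer(model$stiff_index) - 1L)
      keep <- seq(1, length(r$time), by = 10)  # 1 Hz
      rows[[length(rows) + 1]] <- data.frame(
        t_min = (done + r$time[keep]) / 60000, rmp = r$vm[keep])
      state <- setNames(r$state, model$state_names)
      done <- done + len
    }
    rmp_series <- do.call(rbind, rows)
    n_paced_min <- post_minutes
  } else {
    n_paced_min <- pace_minutes
  }

  total_beats <- round(n_paced_min * 60 / bcl)
  feat_rows <- list(); rmp_rows <- list(); beat0 <- 0
  while (beat0 < total_beats) {
    nb <- min(chunk_beats, total_beats - beat0)
    tr <- pace(model, bcl = bcl, duration = nb * bcl, dt = dt,
               stim_amp = amp, sample_dt = 0.1, init = state)
    for (i in seq_len(nb)) {
      f <- tryCatch(extract_ap_features(tr, i), error = function(e) NULL)
      feat_rows[[length(feat_rows) + 1]] <- data.frame(
        beat = beat0 + i,
        t_min = ((beat0 + i - 1) * bcl) / 60 +
          if (schedule == "quiescent_paced") quiescent_minutes else 0,
        apd50 = if (is.null(f)) NA_real_ else f$apd[["APD50"]],
        apd90 = if (is.null(f)) NA_real_ else f$apd[["APD90"]],
        amplitude = if (is.null(f)) NA_real_ else f$amplitude_mv,
        rmp = tr$beats[i, "v_pre"])
    }
    state <- tr$final_state
    beat0 <- beat0 + nb
  }
  out$beats <- do.call(rbind, feat_rows)
  if (schedule == "quiescent_paced") {
    paced_rmp <- data.frame(t_min = out$beats$t_min, rmp = out$beats$rmp)
    out$rmp <- rbind(rmp_series, paced_rmp)
  }
  class(out) <- "stability_record"
  out
}
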