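#' Steady-state strand protocol at one BCL: APD90 and CV
#'
#' The 1D restitution protocol: 50 beats in a single-cell environment
#' adapt the model to the BCL; the resulting state seeds every voxel of a
#' 20 mm strand (dx 0.1 mm); five consecutive beats are stimulated from
#' the left end at 1.2x the tissue threshold. APD90 is measured at the
#' voxel three-quarters of the distance down the strand on beat 5; CV from
#' the activation-time difference between the centers of the two strand
#' halves on beat 5. Results are valid only if all five beats propagate;
#' a capture failure is recorded (with the failing beat) rather than
#' raised.
#'
#' @param model an `ionic_model` (control or cAF variant).
#' @param bcl basic cycle length (s).
#' @param sigma strand conductivity (mS/mm); for cAF variants pass
#'   0.70x the control-tuned value.
#' @param nv,dx strand size (voxels) and spacing (mm).
#' @param dt integration step (ms).
#' @param n_beats number of strand beats (protocol default 5).
#' @param stim_amp explicit stimulus amplitude; defaults to 1.2x the
#'   tissue threshold measured on the seeded strand.
#' @return a `strand_protocol` list: `apd90` (ms or NA), `cv` (mm/s or
#'   NA), `capture` (per-beat logical), `failed_beat`, the pre-beat-5
#'   state (`state_s1`), stimulus amplitude, distal upstroke reference,
#'   and geometry.
#' @export
run_strand_protocol <- function(model, bcl, sigma, nv = 200, dx = 0.1,
                                dt = 0.01, n_beats = 5, stim_amp = NULL) {
  stopifnot(inherits(model, "ionic_model"), bcl > 0)
  bcl_ms <- bcl * 1000
  seed <- prepaced_state(model, bcl, dt = dt)
  if (is.null(stim_amp))
    stim_amp <- 1.2 * find_tissue_threshold(model, seed, nv = nv, dx = dx,
                                            sigma = sigma, dt = dt)
  site_cv1 <- round(nv / 4); site_ap <- round(3 * nv / 4)

  # beats 1..(n-1)
  stims_a <- .edge_stim((seq_len(n_beats - 1) - 1) * bcl_ms, stim_amp)
  ra <- .run_strand(model, seed, nv, dx, sigma, dt,
                    (n_beats - 1) * bcl_ms, stims_a,
                    record_sites = site_ap, sample_dt = bcl_ms)
  capture <- vapply(ra$windows, .site_captured, logical(1), site = site_ap)

  # beat n from the saved pre-beat state (also the ERP reference state)
  rb <- .run_strand(model, ra$state, nv, dx, sigma, dt, bcl_ms,
                    .edge_stim(0, stim_amp),
                    record_sites = c(site_cv1, site_ap), sample_dt = dt)
  win_b <- rb$windows[[1]]
  capture <- c(capture, .site_captured(win_b, site_ap))

  apd90 <- cv <- t_act_distal <- NA_real_
  failed <- if (all(capture)) NA_integer_ else which(!capture)[1]
  if (all(capture)) {
    act <- .window_activation(win_b, dt)
    t_act_distal <- act[site_ap]
    cv <- tryCatch(measure_cv(activation_map(act, dx)),
                   error = function(e) NA_real_)
    tr <- as_ap_trace(rb$site_t, rb$site_vm[, 2], stim_times = 0)
    apd90 <- tryCatch(extract_ap_features(tr, 1)$apd[["APD90"]],
                      error = function(e) NA_real_)
  }
  structure(list(model = model, model_name = model$name,
                 variant = model$variant,
                 bcl = bcl, sigma = sigma, nv = nv, dx = dx, dt = dt,
                 apd90 = apd90, cv = cv, capture = capture,
                 failed_beat = failed, state_s1 = ra$state,
                 stim_amp = stim_amp, t_act_distal = t_act_distal,
                 dvdt_ref = win_b[site_ap, 2]),
            class = "strand_protocol")
}

#' @export
print.strand_protocol <- function(x, ...) {
  cat(sprintf(
    "<strand_protocol> %s (%s) BCL %g s: APD90 %.1f ms, CV %.1f mm/s, capture %s\n",
    x$model_name, x$variant, x$bcl, x$apd90, x$cv,
    if (all(x$capture)) "every beat" else paste("failed at beat",
                                                x$failed_beat)))
  invisible(x)
}

#' Effective refractory period on the strand
#'
#' From the steady beat-5 state of [run_strand_protocol()], a premature S2
#' is applied at the S1 site; the ERP is the shortest S1-S2 coupling
#' interval whose stimulus produces a propagated AP detected at the center
#' of the second half of the strand (upstroke dV/dt above 10% of the S1
#' reference and peak above -20 mV), located by bisection to 1 ms.
#' The S2 follows the final S1 of the pre-conditioning train.
#'
#' @param proto result of [run_strand_protocol()] (run it first), or a
#'   model (then the protocol is run internally with `...`).
#' @param resolution scan resolution (ms), default 1.
#' @param ci_min lower bracket of the coupling interval (ms).
#' @param ... forwarded to [run_strand_protocol()] when `proto` is a model.
#' @return ERP (ms), with attribute `ci_conducted` (earliest conducted
#'   coupling interval found).
#' @export
measure_erp <- function(proto, resolution = 1, ci_min = 40, ...) {
  if (inherits(proto, "ionic_model"))
    proto <- run_strand_protocol(proto, ...)
  stopifnot(inherits(proto, "strand_protocol"))
  if (!all(proto$capture))
    stop("ERP undefined: S1 train failed at beat ", proto$failed_beat)
  m <- proto$model
  nv <- proto$nv
  site <- round(3 * nv / 4)
  bcl_ms <- proto$bcl * 1000
  conducts <- function(ci) {
    stims <- rbind(.edge_stim(0, proto$stim_amp),
                   .edge_stim(ci, proto$stim_amp))
    r <- .run_strand(m, proto$state_s1, nv, proto$dx, proto$sigma,
                     proto$dt, ci + 150, stims, record_sites = site,
                     sample_dt = ci + 150)
    w2 <- r$windows[[2]]
    if (!.site_captured(w2, site, dvdt_ref = proto$dvdt_ref))
      return(FALSE)
    # the distal upstroke must belong to the S2 wave, not the still-
    # travelling S1 front: it must arrive after the coupling interval and
    # after the S1 wave's own distal arrival
    t_act <- w2[site, 1]
    is.finite(t_act) && t_act >= ci &&
      t_act > proto$t_act_distal + 5
  }
  hi <- bcl_ms
  if (!conducts(hi))
    stop("ERP >= BCL: premature beat never conducts up to the cycle length")
  lo <- ci_min
  if (conducts(lo)) {
    warning("premature beat already conducts at ci_min = ", ci_min, " ms")
    return(structure(lo, ci_conducted = lo))
  }
  while (hi - lo > resolution) {
    mid <- round(0.5 * (lo + hi))
    if (conducts(mid)) hi <- mid else lo <- mid
  }
  structure(hi, ci_conducted = hi)
}

#' Wavelength as the product of ERP and CV
#'
#' @param erp effective refractory period (ms).
#' @param cv conduction velocity (mm/s).
#' @return wavelength (mm); NA if either input is undefined.
#' @export
wavelength <- function(erp, cv) {
  if (!is.finite(erp) || !is.finite(cv)) return(NA_real_)
  erp * cv / 1000
}

#' Steady-state restitution curves of APD90, CV, ERP and wavelength
#'
#' Runs the strand protocol plus ERP measurement on a BCL grid for the
#' control and/or cAF variant of a model. Conductivity is tuned to
#' ~750 mm/s at BCL 1 s on the control variant; the cAF variant uses
#' 0.70x the same tuned value (gap-junctional remodeling).
#'
#' @param model_name one of `"courtemanche"`, `"nygren"`, `"maleckar"`.
#' @param variant `"control"` or `"caf"`.
#' @param bcl_grid BCLs (s); default matches the plotted restitution range.
#' @param sigma optional pre-tuned control conductivity (skips tuning).
#' @param with_erp include ERP/WL (the slow part).
#' @param nv,dx,dt strand geometry and step.
#' @return a `RestitutionCurve` data.frame with columns `bcl`, `apd90`,
#'   `cv`, `erp`, `wl`, `capture`, plus attribute `sigma`.
#' @export
restitution_curve <- function(model_name, variant = c("control", "caf"),
                              bcl_grid = c(seq(1, 0.3, by = -0.1), 0.25,
                                           0.2),
                              sigma = NULL, with_erp = TRUE, nv = 200,
                              dx = 0.1, dt = 0.01) {
  variant <- match.arg(variant)
  if (is.null(sigma))
    sigma <- as.numeric(tune_conductivity(atrial_model(model_name),
                                          nv = nv, dx = dx, dt = dt))
  sig_run <- if (variant == "caf") 0.70 * sigma else sigma
  model <- atrial_model(model_name, variant)
  # the stimulus amplitude is adapted per model (1.2x the tissue threshold
  # of the BCL 1 s steady state) and then held fixed across the BCL grid
  amp <- 1.2 * find_tissue_threshold(model, prepaced_state(model, 1,
                                                           dt = dt),
                                     nv = nv, dx = dx, sigma = sig_run,
                                     dt = dt)
  rows <- lapply(bcl_grid, function(bcl) {
    p <- run_strand_protocol(model, bcl, sig_run, nv = nv, dx = dx,
                             dt = dt, stim_amp = amp)
    erp <- NA_real_
    if (with_erp && all(p$capture))
      erp <- tryCatch(as.numeric(measure_erp(p)),
                      error = function(e) NA_real_)
    data.frame(bcl = bcl, apd90 = p$apd90, cv = p$cv, erp = erp,
               wl = wavelength(erp, p$cv), capture = all(p$capture))
  })
  out <- do.call(rbind, rows)
  attr(out, "sigma") <- sig_run
  out
}
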