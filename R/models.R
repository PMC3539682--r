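#' @useDynLib atrialbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft sd
#' @importFrom utils read.csv write.csv
NULL

.model_registry <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .init_registry()
}

.crn_params <- c(
  g_Na = 7.8, g_K1 = 0.09, g_to = 0.1652, g_Kur_scale = 1.0,
  g_Kr = 0.029411765, g_Ks = 0.12941176, g_CaL = 0.12375,
  g_bCa = 0.001131, g_bNa = 0.0006744375, I_NaK_max = 0.59933874,
  I_NaCa_max = 1600, I_PMCA_max = 0.275, I_up_max = 0.005, k_rel = 30)

.crn_state <- c(
  V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775, oa = 0.03043,
  oi = 0.9992, ua = 0.004966, ui = 0.9986, xr = 3.296e-05, xs = 0.01869,
  d = 1.367e-04, f = 0.9996, f_Ca = 0.7755, u = 0, v = 1, w = 0.9992,
  Na_i = 11.17, K_i = 139.0, Ca_i = 1.013e-04, Ca_up = 1.488,
  Ca_rel = 1.488)

.nyg_params <- c(
  P_Na = 0.0016, g_CaL = 6.75, g_t = 7.5, g_Kur = 2.75, g_Ks = 1.0,
  g_Kr = 0.5, g_K1 = 3.0, g_bNa = 0.060599, g_bCa = 0.078681,
  I_NaK_max = 70.8253, I_PMCA_max = 4.0, k_NaCa = 0.0374842,
  I_up_max = 2800, alpha_rel = 200000, phi_Na_en = -1.68, ACh = 0)

.nyg_state <- c(
  V = -74.2525, m = 0.0032017, h1 = 0.8814, h2 = 0.8742, d_L = 1.3005e-05,
  f_L1 = 0.9986, f_L2 = 0.9986, r = 0.0010678, s = 0.949,
  r_sus = 1.5949e-04, s_sus = 0.9912, n = 0.0048357, p_a = 0.0001,
  Na_c = 130.011, K_c = 5.3581, Ca_c = 1.8147, Na_i = 8.5547,
  K_i = 129.435, Ca_i = 6.729e-05, Ca_d = 7.2495e-05, O_C = 0.0275,
  O_TC = 0.0133, O_TMgC = 0.1961, O_TMgMg = 0.7094, O_Calse = 0.4369,
  Ca_up = 0.6646, Ca_rel = 0.6465, F1 = 0.4284, F2 = 0.0028)

.mal_params <- c(
  P_Na = 0.0018, g_CaL = 6.75, g_t = 8.25, g_Kur = 2.25, g_Ks = 1.0,
  g_Kr = 0.5, g_K1 = 3.0, g_bNa = 0.060599, g_bCa = 0.078681,
  I_NaK_max = 68.55, I_PMCA_max = 4.0, k_NaCa = 0.0374842,
  I_up_max = 2800, alpha_rel = 200000, phi_Na_en = 0, ACh = 0)

.mal_state <- c(
  V = -74.031982, m = 0.0033837, h1 = 0.8814, h2 = 0.8742,
  d_L = 1.3005e-05, f_L1 = 0.9986, f_L2 = 0.9986, r = 0.0010678,
  s = 0.949, a_ur = 3.67e-04, i_ur = 0.96729, n = 0.0046, p_a = 5.9e-05,
  Na_c = 130.022096, K_c = 5.560224, Ca_c = 1.815768, Na_i = 8.516766,
  K_i = 129.485991, Ca_i = 6.5e-05, Ca_d = 7.1e-05, O_C = 0.026766,
  O_TC = 0.012922, O_TMgC = 0.190369, O_TMgMg = 0.714463,
  O_Calse = 0.465921, Ca_up = 0.649195, Ca_rel = 0.632613,
  F1 = 0.470055, F2 = 0.002814)

#' Names of the sarcolemmal currents common to all implemented models
#'
#' Order matches the rows of the normalized current-extrema table produced by
#' [current_extrema_table()].
#' @export
atrial_current_names <- function() {
  c("I_Na", "I_bNa", "I_CaL", "I_bCa", "I_NCX", "I_NKA", "I_PMCA",
    "I_to", "I_Kur", "I_Kr", "I_Ks", "I_K1")
}

# conductance scalings representing chronic-AF electrical remodeling:
# I_to and I_CaL reduced by 65%, I_Kur by 49%, I_K1 increased by 110%
.caf_scaling <- list(
  courtemanche = c(g_to = 0.35, g_CaL = 0.35, g_Kur_scale = 0.51, g_K1 = 2.10),
  nygren       = c(g_t = 0.35, g_CaL = 0.35, g_Kur = 0.51, g_K1 = 2.10),
  maleckar     = c(g_t = 0.35, g_CaL = 0.35, g_Kur = 0.51, g_K1 = 2.10))

.register_builtin <- function(name, id, params, state, stim_factor,
                              cai_index, stim_unit) {
  assign(name, list(
    name = name, id = id, params = params, initial_state = state,
    stim_factor = stim_factor, cai_index = cai_index,
    stim_unit = stim_unit, stiff = integer(0), available = TRUE),
    envir = .model_registry)
}

.init_registry <- function() {
  .register_builtin("courtemanche", 0L, .crn_params, .crn_state, 1.0,
                    19L, "pA/pF")
  .register_builtin("nygren", 1L, .nyg_params, .nyg_state, 0.02, 19L, "pA")
  .register_builtin("maleckar", 2L, .mal_params, .mal_state, 0.02, 19L, "pA")
  # optional plugin slots: the full Koivumaki and Grandi equation sets are
  # not shipped; registering them here reserves the names and documents the
  # plugin contract (a plugin supplies params, initial_state and either a
  # compiled model id or an R rates function, plus optional stiff indices
  # that the integrator advances with an RK4 sub-step).
  assign("koivumaki", list(name = "koivumaki", available = FALSE),
         envir = .model_registry)
  assign("grandi", list(name = "grandi", available = FALSE),
         envir = .model_registry)
}

#' Register an ionic model plugin
#'
#' Reserved names (`"koivumaki"`, `"grandi"`) can be filled in by supplying a
#' full definition; any new name can also be registered. A definition needs
#' `params`, `initial_state` (named numeric), `id` (compiled model id) or a
#' `rates` R function, and may flag `stiff` state indices for the per-state
#' RK4 sub-integrator override.
#'
#' @param name model name.
#' @param definition list as described above.
#' @export
register_atrial_model <- function(name, definition) {
  stopifnot(is.character(name), length(name) == 1L, is.list(definition))
  definition$name <- name
  if (is.null(definition$available)) definition$available <- TRUE
  if (is.null(definition$stiff)) definition$stiff <- integer(0)
  assign(name, definition, envir = .model_registry)
  invisible(name)
}

#' Construct an ionic model of the human atrial myocyte
#'
#' Returns a model object holding the published parameter set and initial
#' conditions of one of the implemented human atrial myocyte models, in either
#' its control form or with chronic atrial fibrillation (cAF) electrical
#' remodeling applied (see [apply_caf_remodeling()]).
#'
#' Implemented models: `"courtemanche"` (Courtemanche-Ramirez-Nattel 1998),
#' `"nygren"` (Nygren et al. 1998) and `"maleckar"` (Maleckar et al. 2009).
#' The names `"koivumaki"` and `"grandi"` are reserved plugin slots; asking
#' for them raises an error until a plugin is registered via
#' [register_atrial_model()]. A variant suffix `"-caf"` in `name` is
#' equivalent to `variant = "caf"`.
#'
#' @param name model name, optionally with a `"-caf"` suffix.
#' @param variant `"control"` or `"caf"`.
#' @return an object of class `ionic_model` with elements `name`, `variant`,
#'   `params` (named maximal conductances/fluxes in the model's native
#'   units), `initial_state` (published initial conditions; `V` in mV,
#'   gates dimensionless, concentrations in mM), `gating_index`, and
#'   `stiff_index`.
#' @export
atrial_model <- function(name, variant = c("control", "caf")) {
  if (grepl("-caf$", name)) {
    variant <- "caf"
    name <- sub("-caf$", "", name)
  } else {
    variant <- match.arg(variant)
  }
  if (!exists(name, envir = .model_registry))
    stop("unknown model '", name, "'; known: ",
         paste(sort(ls(.model_registry)), collapse = ", "))
  def <- get(name, envir = .model_registry)
  if (!isTRUE(def$available))
    stop("model '", name, "' is a plugin slot with no registered definition")
  m <- structure(list(
    name = name, id = def$id, variant = "control",
    params = def$params, initial_state = def$initial_state,
    state_names = names(def$initial_state),
    gating_index = which(rates_cpp(def$id, unname(def$params),
                                   unname(def$initial_state))$gate),
    stiff_index = def$stiff,
    stim_factor = def$stim_factor, cai_index = def$cai_index,
    stim_unit = def$stim_unit), class = "ionic_model")
  if (variant == "caf") m <- apply_caf_remodeling(m)
  m
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("<ionic_model> %s (%s), %d states, %d gates\n",
              x$name, x$variant, length(x$initial_state),
              length(x$gating_index)))
  invisible(x)
}

#' Apply chronic-AF electrical remodeling to a model's conductances
#'
#' Scales the maximal conductances of I_to and I_CaL by 0.35, I_Kur by 0.51
#' and I_K1 by 2.10; every other parameter is untouched. Applying the scaling
#' twice is an error (the variant tag guards against double remodeling).
#'
#' @param model an `ionic_model` (or a named parameter vector carrying a
#'   `variant` attribute).
#' @return the remodeled model tagged `variant = "caf"`.
#' @export
apply_caf_remodeling <- function(model) {
  if (inherits(model, "ionic_model")) {
    if (model$variant == "caf")
      stop("cAF remodeling already applied (double-scaling guard)")
    sc <- .caf_scaling[[model$name]]
    if (is.null(sc))
      stop("no cAF scaling table registered for model '", model$name, "'")
    model$params[names(sc)] <- model$params[names(sc)] * sc
    model$variant <- "caf"
    return(model)
  }
  # bare parameter-set form
  if (identical(attr(model, "variant"), "caf"))
    stop("cAF remodeling already applied (double-scaling guard)")
  sc <- .caf_scaling[[attr(model, "model")]]
  model[names(sc)] <- model[names(sc)] * sc
  attr(model, "variant") <- "caf"
  model
}

#' Time derivatives of the model state
#'
#' Evaluates the ionic model ODE right-hand side. For Hodgkin-Huxley gating
#' states, the returned object also carries the (steady-state, time-constant)
#' pairs used by the Rush-Larsen update.
#'
#' @param model an `ionic_model`.
#' @param state named state vector.
#' @param t time (ms); the models are autonomous, kept for interface
#'   completeness.
#' @param i_stim stimulus amplitude in the model's native stimulus unit
#'   (depolarizing positive).
#' @return named vector of d(state)/dt in units per ms, with attributes
#'   `inf`, `tau` (ms) and `gate`.
#' @export
cell_derivatives <- function(model, state, t = 0, i_stim = 0) {
  stopifnot(inherits(model, "ionic_model"))
  if (any(!is.finite(state))) {
    bad <- model$state_names[which(!is.finite(state))[1]]
    stop("non-finite state '", bad, "' at t = ", t, " ms")
  }
  r <- rates_cpp(model$id, unname(model$params), unname(state))
  dy <- r$dy
  dy[1] <- dy[1] + i_stim * model$stim_factor
  names(dy) <- model$state_names
  structure(dy, inf = r$inf, tau = r$tau, gate = r$gate)
}

#' Advance a cell state by explicit integration steps
#'
#' Gating states are advanced with the Rush-Larsen exponential update,
#' all other states with forward Euler (states in `stiff_index` with an RK4
#' sub-integrator). Gates are clamped to \[0, 1\] against round-off.
#'
#' @inheritParams cell_derivatives
#' @param dt step size (ms), default 0.01.
#' @param n number of steps.
#' @return the updated named state vector.
#' @export
cell_step <- function(model, state, dt = 0.01, i_stim = 0, n = 1L) {
  stopifnot(inherits(model, "ionic_model"), dt > 0)
  out <- step_cell_cpp(model$id, unname(model$params), unname(state),
                       dt, as.integer(n), i_stim,
                       as.integer(model$stiff_index) - 1L)
  names(out) <- model$state_names
  out
}

#' Rush-Larsen update for a Hodgkin-Huxley gate
#'
#' Exact solution of dy/dt = (y_inf - y)/tau over one step with frozen
#' voltage: `y_inf + (y - y_inf) * exp(-dt/tau)`.
#'
#' @param y gate value, `y_inf` steady state, `tau` time constant (ms),
#'   `dt` step (ms).
#' @param y_inf,tau,dt see above.
#' @export
rush_larsen_update <- function(y, y_inf, tau, dt) {
  y_inf + (y - y_inf) * exp(-dt / tau)
}

#' Instantaneous sarcolemmal currents
#'
#' @inheritParams cell_derivatives
#' @param normalize optional divisor (e.g. the clamped |I_K1| from
#'   [voltage_clamp()]) applied to all currents.
#' @return named vector of the 12 currents common to all models, in the
#'   model's native convention (pA/pF for Courtemanche, pA for the Nygren
#'   lineage) unless normalized.
#' @export
current_snapshot <- function(model, state, normalize = NULL) {
  stopifnot(inherits(model, "ionic_model"))
  cur <- currents_cpp(model$id, unname(model$params), unname(state))
  names(cur) <- atrial_current_names()
  if (!is.null(normalize)) cur <- cur / normalize
  cur
}

#' Voltage-clamp a model and return end-of-clamp currents
#'
#' Holds the membrane voltage fixed while all other states evolve; used to
#' obtain the I_K1 normalization divisor (|I_K1| after 50 s clamped to
#' -75 mV) for cross-model current comparison.
#'
#' @param model an `ionic_model`.
#' @param v_hold holding potential (mV), default -75.
#' @param duration clamp duration (s), default 50.
#' @param dt step (ms).
#' @return list with `currents` (named), `divisor` (= |I_K1| at end of
#'   clamp), `state`, and `max_drift` (largest |d(concentration)/dt| at the
#'   end; a warning is raised if it exceeds `drift_tol`).
#' @param drift_tol tolerance (units/ms) for residual concentration drift.
#' @export
voltage_clamp <- function(model, v_hold = -75, duration = 50, dt = 0.01,
                          drift_tol = 1e-5) {
  stopifnot(inherits(model, "ionic_model"))
  r <- clamp_cell_cpp(model$id, unname(model$params),
                      unname(model$initial_state), v_hold,
                      duration * 1000, dt, as.integer(model$stiff_index) - 1L)
  cur <- r$currents
  names(cur) <- atrial_current_names()
  if (r$max_drift > drift_tol)
    warning(sprintf("concentrations still drifting at end of clamp (%.3g/ms)",
                    r$max_drift))
  state <- r$state
  names(state) <- model$state_names
  list(currents = cur, divisor = abs(cur[["I_K1"]]), state = state,
       max_drift = r$max_drift)
}

#' Diastolic stimulus threshold of a cell
#'
#' Minimal amplitude of a rectangular pulse that elicits an action potential
#' (peak V_m above `ap_level` within `window` ms), found by doubling and
#' bisection to 1% relative precision. Protocol stimuli are scaled from
#' this threshold (2x in single cells, 1.2x in tissue).
#'
#' @param model an `ionic_model`.
#' @param state state to probe from (defaults to the published initial
#'   state; protocols probe their pre-paced state).
#' @param pulse_duration rectangular pulse length (ms), default 2.
#' @param dt step (ms).
#' @param ap_level voltage (mV) the peak must exceed to count as an AP.
#' @param window observation window (ms).
#' @param guess initial amplitude guess in native stimulus units.
#' @return threshold amplitude (native stimulus units).
#' @export
find_threshold <- function(model, state = model$initial_state,
                           pulse_duration = 2, dt = 0.01, ap_level = 0,
                           window = 50, guess = 1) {
  stopifnot(inherits(model, "ionic_model"))
  fires <- function(amp) {
    r <- run_cell_cpp(model$id, unname(model$params), unname(state),
                      window, dt, 0, pulse_duration, amp, 0.1,
                      -1L, FALSE, as.integer(model$stiff_index) - 1L)
    max(r$vm) > ap_level
  }
  hi <- guess
  n_dbl <- 0
  while (!fires(hi)) {
    hi <- hi * 2
    n_dbl <- n_dbl + 1
    if (n_dbl > 14) stop("inexcitable: no AP at ", hi, " (>100x initial guess)")
  }
  lo <- hi / 2
  if (n_dbl == 0) {
    while (lo > 1e-9 && fires(lo)) { hi <- lo; lo <- lo / 2 }
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- 0.5 * (lo + hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

.model_ids <- function() c(courtemanche = 0L, nygren = 1L, maleckar = 2L)
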