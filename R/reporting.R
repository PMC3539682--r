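#' Validated benchmark configuration
#'
#' Checks model names, variants and numerics before any simulation starts;
#' the validated configuration is carried into every report for
#' provenance.
#'
#' @param models character vector of model names.
#' @param variants subset of `c("control", "caf")`.
#' @param protocols subset of `c("table1", "table2", "table4",
#'   "restitution")`.
#' @param dt,dx numerics (ms, mm).
#' @param bcl_grid restitution BCL grid (s).
#' @param pace_duration single-cell pacing length (s).
#' @param strand_nv strand length in voxels.
#' @export
benchmark_config <- function(models = c("courtemanche", "nygren",
                                        "maleckar"),
                             variants = c("control", "caf"),
                             protocols = c("table1", "table2"),
                             dt = 0.01, dx = 0.1,
                             bcl_grid = c(seq(1, 0.3, by = -0.1), 0.25,
                                          0.2),
                             pace_duration = 50, strand_nv = 200) {
  known <- c("courtemanche", "nygren", "maleckar", "koivumaki", "grandi")
  bad <- setdiff(models, known)
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  for (m in models) atrial_model(m)  # errors early on empty plugin slots
  stopifnot(all(variants %in% c("control", "caf")),
            all(protocols %in% c("table1", "table2", "table4",
                                 "restitution")),
            dt > 0, dx > 0, all(bcl_grid > 0), pace_duration > 0,
            strand_nv >= 20)
  structure(list(models = models, variants = variants,
                 protocols = protocols, dt = dt, dx = dx,
                 bcl_grid = bcl_grid, pace_duration = pace_duration,
                 strand_nv = strand_nv), class = "benchmark_config")
}

# single-cell feature row for one model/variant
.feature_row <- function(name, variant, duration, dt) {
  m <- atrial_model(name, variant)
  tr <- pace(m, bcl = 1, duration = duration, dt = dt, sample_dt = 0.1)
  f <- extract_ap_features(tr)
  data.frame(model = name, variant = variant,
             amplitude_mv = f$amplitude_mv, rmp_mv = f$rmp_mv,
             apd50_ms = f$apd[["APD50"]], apd90_ms = f$apd[["APD90"]],
             dvdt_max_v_per_s = f$dvdt_max_v_per_s,
             cat_diastolic_um = f$cat_diastolic_um,
             cat_amplitude_um = f$cat_amplitude_um)
}

#' Normalized current-extrema table for one model
#'
#' Signed extrema of the 12 common sarcolemmal currents over the terminal
#' beat of a 50 s, BCL 1 s run, normalized to |I_K1| after 50 s of
#' voltage clamp at -75 mV (I_NCX is reported with separate max and min,
#' being strongly biphasic).
#'
#' @param name model name.
#' @param variant `"control"` or `"caf"`.
#' @param duration pacing length (s).
#' @param dt step (ms).
#' @return one-row data.frame of normalized extrema.
#' @export
current_extrema_table <- function(name, variant = "control",
                                  duration = 50, dt = 0.01) {
  m <- atrial_model(name, variant)
  div <- voltage_clamp(m, dt = dt)$divisor
  tr <- pace(m, bcl = 1, duration = duration - 1, dt = dt,
             sample_dt = 0.1)
  tr2 <- pace(m, bcl = 1, duration = 1, dt = dt, sample_dt = 0.05,
              stim_amp = tr$stim_amp, init = tr$final_state,
              record_currents = TRUE)
  cur <- tr2$currents
  mx <- apply(cur, 2, max); mn <- apply(cur, 2, min)
  signed <- ifelse(abs(mx) >= abs(mn), mx, mn) / div
  out <- as.data.frame(as.list(signed))
  out$I_NCX_max <- mx[["I_NCX"]] / div
  out$I_NCX_min <- mn[["I_NCX"]] / div
  out$I_NCX <- NULL
  cbind(data.frame(model = name, variant = variant), out)
}

#' Run a benchmark configuration and collect its report bundle
#'
#' Emits single-cell feature tables for control and cAF variants, the
#' normalized current-extrema table and/or strand restitution tables,
#' as requested by the configuration. Failures are isolated per model:
#' a failing cell is reported as NA rather than aborting the bundle.
#' Re-running the same configuration reproduces the outputs bit-
#' identically (the pipeline has no random element).
#'
#' @param config a [benchmark_config()].
#' @return a `benchmark_report` list of data.frames plus the config.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  out <- list(config = config, tables = list())
  safe <- function(expr, fallback) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e)); fallback
  })
  if ("table1" %in% config$protocols)
    out$tables$table1 <- do.call(rbind, lapply(config$models, function(m)
      safe(.feature_row(m, "control", config$pace_duration, config$dt),
           data.frame(model = m, variant = "control"))))
  if ("table2" %in% config$protocols && "caf" %in% config$variants)
    out$tables$table2 <- do.call(rbind, lapply(config$models, function(m)
      safe(.feature_row(m, "caf", config$pace_duration, config$dt),
           data.frame(model = m, variant = "caf"))))
  if ("table4" %in% config$protocols)
    out$tables$table4 <- do.call(rbind, lapply(config$models, function(m)
      do.call(rbind, lapply(intersect(c("control", "caf"),
                                      config$variants), function(v)
        safe(current_extrema_table(m, v, config$pace_duration,
                                   config$dt), NULL)))))
  if ("restitution" %in% config$protocols)
    out$tables$restitution <- do.call(rbind, lapply(config$models,
      function(m) do.call(rbind, lapply(intersect(c("control", "caf"),
                                                  config$variants),
        function(v) {
          df <- safe(restitution_curve(m, v, config$bcl_grid,
                                       nv = config$strand_nv,
                                       dx = config$dx, dt = config$dt),
                     NULL)
          if (!is.null(df)) cbind(model = m, variant = v, df) else NULL
        }))))
  class(out) <- "benchmark_report"
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> tables:", paste(names(x$tables),
                                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a benchmark report bundle as CSV files with a manifest
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(report$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- report$config
  manifest <- data.frame(
    key = c("models", "variants", "protocols", "dt_ms", "dx_mm",
            "pace_duration_s", "strand_nv", "bcl_grid_s"),
    value = c(paste(cfg$models, collapse = ";"),
              paste(cfg$variants, collapse = ";"),
              paste(cfg$protocols, collapse = ";"),
              cfg$dt, cfg$dx, cfg$pace_duration, cfg$strand_nv,
              paste(cfg$bcl_grid, collapse = ";")))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(c(files, file.path(dir, "manifest.csv")))
}

#' Published reference values shipped with the package
#'
#' The printed single-cell feature tables (control and cAF), the
#' normalized current-extrema table, and the strand restitution values at
#' BCL 0.4 s, for all five models of the original benchmark (values for
#' the two models outside this package's scope are carried for context;
#' cells the benchmark could not analyze are NA).
#'
#' @param which one of `"table1"`, `"table2"`, `"table4"`,
#'   `"restitution_bcl04"`.
#' @export
reference_tables <- function(which = c("table1", "table2", "table4",
                                       "restitution_bcl04")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("reference_", which, ".csv"),
                   package = "atrialbench")
  utils::read.csv(f, check.names = FALSE)
}

#' Default tolerance policy for comparison against the printed tables
#'
#' APD and ERP: 5% or 5 ms, whichever is larger; RMP: 2 mV; CV: 3%;
#' amplitude: 5%; other quantities: 10%. A reimplementation from the
#' original model publications with unspecified stimulus details cannot
#' guarantee exact agreement with the benchmark's own code.
#' @export
tolerance_policy <- function() {
  list(apd = list(rel = 0.05, abs = 5), erp = list(rel = 0.05, abs = 5),
       rmp = list(abs = 2), cv = list(rel = 0.03),
       amplitude = list(rel = 0.05), default = list(rel = 0.10))
}

.tolerance_for <- function(property, policy) {
  p <- tolower(property)
  if (grepl("apd", p)) policy$apd
  else if (grepl("erp", p)) policy$erp
  else if (grepl("rmp", p)) policy$rmp
  else if (grepl("cv", p)) policy$cv
  else if (grepl("amplitude", p)) policy$amplitude
  else policy$default
}

#' Compare computed values against a reference table
#'
#' Per-cell relative (or absolute, for RMP-like quantities) error against
#' packaged reference values, with pass/fail per the tolerance policy.
#' Reference cells that are NA (quantities the benchmark could not
#' analyze) are skipped, not failed.
#'
#' @param computed data.frame with columns `property`, `value`.
#' @param reference data.frame with columns `property`, `value`.
#' @param policy tolerance policy, see [tolerance_policy()].
#' @return data.frame with per-property error and `status`
#'   (`"pass"`, `"fail"`, `"skipped"`).
#' @export
compare_to_reference <- function(computed, reference,
                                 policy = tolerance_policy()) {
  stopifnot(all(c("property", "value") %in% names(computed)),
            all(c("property", "value") %in% names(reference)))
  if (!setequal(computed$property, reference$property))
    stop("mismatched table shapes: properties differ")
  ref <- reference$value[match(computed$property, reference$property)]
  out <- data.frame(property = computed$property,
                    computed = computed$value, reference = ref)
  out$abs_error <- abs(out$computed - out$reference)
  out$rel_error <- out$abs_error / abs(out$reference)
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    if (!is.finite(out$reference[i])) return("skipped")
    if (!is.finite(out$computed[i])) return("fail")
    tol <- .tolerance_for(out$property[i], policy)
    ok <- FALSE
    if (!is.null(tol$rel)) ok <- ok || out$rel_error[i] <= tol$rel
    if (!is.null(tol$abs)) ok <- ok || out$abs_error[i] <= tol$abs
    if (ok) "pass" else "fail"
  }, character(1))
  out
}
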