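## Two-arm sensitivity analysis:
##  (A) perturb MCL/LCL stiffness until the simulated strain difference
##      matches the ultrasound-vs-DIC residual strain errors;
##  (B) perturb implant internal-external rotation by a clinical
##      malrotation magnitude;
## then compare per-DOF kinematics against the nominal (optimal) run.

#' Strain-error target
#'
#' Target strain difference for one collateral ligament, matching the
#' residual error of ultrasound-based strain estimation against digital
#' image correlation (defaults 0.27% strain for the MCL, 0.57% for the
#' LCL).
#'
#' @param ligament `"MCL"` or `"LCL"`.
#' @param delta_eps target strain difference (strain units, > 0); default
#'   by ligament.
#' @param direction `"increase"` or `"decrease"`: perturb stiffness up or
#'   down.
#' @return An object of class `strain_error_target`.
#' @export
strain_error_target <- function(ligament = c("MCL", "LCL"),
                                delta_eps = NULL,
                                direction = c("increase", "decrease")) {
  ligament <- match.arg(ligament)
  direction <- match.arg(direction)
  if (is.null(delta_eps))
    delta_eps <- c(MCL = 0.0027, LCL = 0.0057)[[ligament]]
  if (!is.finite(delta_eps) || delta_eps <= 0)
    stop("strain_error_target: delta_eps must be > 0")
  structure(list(ligament = ligament, delta_eps = delta_eps,
                 direction = direction), class = "strain_error_target")
}

ligament_strain_series <- function(trace, ligament) {
  cols <- grep(paste0("^eps_", ligament_bundle_prefix(ligament)),
               names(trace), value = TRUE)
  if (length(cols) == 0L)
    stop("ligament ", ligament, " absent from trace")
  rowMeans(trace[cols])
}

ligament_force_series <- function(trace, ligament) {
  cols <- grep(paste0("^f_", ligament_bundle_prefix(ligament)),
               names(trace), value = TRUE)
  if (length(cols) == 0L)
    stop("ligament ", ligament, " absent from trace")
  rowSums(trace[cols])
}

ligament_bundle_prefix <- function(ligament) {
  switch(ligament, MCL = "MCL_", LCL = "LCL", MPFL = "MPFL", LPFL = "LPFL",
         patellar = "PL_", ligament)
}

#' Strain difference between two squat traces
#'
#' Summarizes the difference between the (bundle-averaged) strain series
#' of one ligament in two traces. The default summary is the maximum of
#' the absolute difference over the cycle; `"mean"` and
#' `"at_peak_flexion"` are selectable alternatives.
#'
#' @param trace_a,trace_b `squat_trace`s on the same cycle grid.
#' @param ligament ligament name (e.g. `"MCL"`).
#' @param summary summary statistic.
#' @return Scalar strain difference (strain units, >= 0 for max/mean).
#' @export
strain_difference <- function(trace_a, trace_b, ligament,
                              summary = c("max", "mean", "at_peak_flexion")) {
  summary <- match.arg(summary)
  if (nrow(trace_a) != nrow(trace_b))
    stop("strain_difference: traces are not on the same cycle grid")
  ea <- ligament_strain_series(trace_a, ligament)
  eb <- ligament_strain_series(trace_b, ligament)
  d <- abs(ea - eb)
  switch(summary,
         max = max(d),
         mean = mean(d),
         at_peak_flexion = d[which.max(trace_a$FE)])
}

#' Is a ligament active over a squat cycle?
#'
#' A ligament is inactive when it carries zero tensile force over the
#' whole range of motion (every bundle shorter than its zero-load length
#' throughout).
#'
#' @param trace a `squat_trace` with per-bundle force columns.
#' @param ligament ligament name.
#' @return Logical.
#' @export
ligament_active <- function(trace, ligament) {
  max(ligament_force_series(trace, ligament)) > 0
}

#' Find the stiffness window matching a strain-error target
#'
#' Bisection (Brent root search) on the stiffness of one collateral
#' ligament until the cycle-maximum strain difference between the nominal
#' and the perturbed simulation matches the target, in the decreased- and
#' increased-stiffness directions. Reference strains are held fixed
#' (reference lengths are those of the settled nominal model).
#'
#' If the ligament is inactive in the nominal simulation, the `"/"`
#' sentinel is returned: a slack ligament produces no force, so no
#' stiffness change can alter the kinematics. If the target is not
#' reachable within the search bounds, the bound is returned with
#' `bound_hit = TRUE`.
#'
#' @param model a settled `knee_model`.
#' @param ligament `"MCL"` or `"LCL"`.
#' @param target a [strain_error_target()] (its `direction` selects which
#'   side to search when `directions` is not given).
#' @param protocol a [squat_protocol()].
#' @param nominal_trace optional precomputed nominal trace.
#' @param k_bounds_factor search bounds `[k/f, k*f]`.
#' @param tol relative tolerance on the achieved strain difference.
#' @param directions which directions to solve.
#' @return List with per-direction results: `k`, `achieved`, `bound_hit`,
#'   plus `active`, `k_nominal`, and `sentinel` (`"/"`) when inactive.
#' @export
stiffness_for_strain_error <- function(model, ligament, target = strain_error_target(ligament),
                                       protocol = squat_protocol(),
                                       nominal_trace = NULL,
                                       k_bounds_factor = 8,
                                       tol = 0.02,
                                       directions = c("decrease", "increase")) {
  if (!isTRUE(model$settled)) stop("stiffness_for_strain_error: settle the model first")
  if (is.null(nominal_trace)) nominal_trace <- run_squat(model, protocol)
  k_nom <- ligament_stiffness(model, ligament)
  if (!ligament_active(nominal_trace, ligament)) {
    return(list(ligament = ligament, active = FALSE, sentinel = "/",
                k_nominal = k_nom,
                note = paste0(ligament, " carries no force over the cycle; ",
                              "stiffness perturbation cannot change the kinematics")))
  }
  dlt <- target$delta_eps
  achieved <- function(k) {
    tr <- run_squat(set_ligament_stiffness(model, ligament, k), protocol)
    list(d = strain_difference(nominal_trace, tr, ligament), trace = tr)
  }
  solve_dir <- function(dir) {
    bound <- if (dir == "increase") k_nom * k_bounds_factor else k_nom / k_bounds_factor
    at_bound <- achieved(bound)
    if (at_bound$d < dlt) {
      return(list(direction = dir, k = bound, achieved = at_bound$d,
                  bound_hit = TRUE, converged = FALSE, trace = at_bound$trace))
    }
    f <- function(k) achieved(k)$d - dlt
    root <- stats::uniroot(f, interval = sort(c(k_nom, bound)),
                           f.lower = if (dir == "increase") -dlt else at_bound$d - dlt,
                           f.upper = if (dir == "increase") at_bound$d - dlt else -dlt,
                           tol = k_nom * 1e-3)
    got <- achieved(root$root)
    list(direction = dir, k = root$root, achieved = got$d,
         bound_hit = FALSE, converged = abs(got$d - dlt) <= tol * dlt,
         trace = got$trace)
  }
  out <- list(ligament = ligament, active = TRUE, k_nominal = k_nom,
              target = dlt)
  for (dir in directions) out[[dir]] <- solve_dir(dir)
  out
}

#' Get or set the stiffness of a ligament's bundles
#'
#' Multi-bundle ligaments share one per-bundle stiffness; the setter
#' assigns `k` to every bundle of the ligament.
#'
#' @param model a `knee_model`.
#' @param ligament ligament name (`"MCL"`, `"LCL"`, `"MPFL"`, `"LPFL"`,
#'   `"patellar"`).
#' @param k new per-bundle stiffness, N.
#' @return `ligament_stiffness()` the current per-bundle stiffness;
#'   `set_ligament_stiffness()` the modified model.
#' @export
ligament_stiffness <- function(model, ligament) {
  ks <- vapply(model$bundles, function(b)
    if (b$ligament == ligament) b$k else NA_real_, numeric(1))
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0L) stop("unknown ligament: ", ligament)
  ks[[1]]
}

#' @rdname ligament_stiffness
#' @export
set_ligament_stiffness <- function(model, ligament, k) {
  hit <- FALSE
  for (i in seq_along(model$bundles)) {
    if (model$bundles[[i]]$ligament == ligament) {
      model$bundles[[i]]$k <- k
      hit <- TRUE
    }
  }
  if (!hit) stop("unknown ligament: ", ligament)
  model
}

#' Per-DOF kinematic difference between two traces
#'
#' Mean and standard deviation over the cycle of (optimal - perturbed)
#' for varus-valgus, internal-external rotation and the three
#' translations. Flexion-extension is excluded: the cycle is
#' flexion-driven.
#'
#' @param trace_opt,trace_pert `squat_trace`s on the same cycle grid.
#' @return Data frame with columns `dof, mean, sd` (deg for VV/IE, mm for
#'   AP/ML/IS).
#' @export
kinematic_difference <- function(trace_opt, trace_pert) {
  if (nrow(trace_opt) != nrow(trace_pert))
    stop("kinematic_difference: traces are not on the same cycle grid")
  dofs <- c("VV", "IE", "AP", "ML", "IS")
  d <- lapply(dofs, function(ch) trace_opt[[ch]] - trace_pert[[ch]])
  data.frame(dof = dofs,
             mean = vapply(d, mean, numeric(1)),
             sd = vapply(d, stats::sd, numeric(1)))
}

#' Run the two-arm sensitivity study
#'
#' Simulates the nominal model, each requested stiffness-perturbed
#' variant (stiffness found by [stiffness_for_strain_error()], reference
#' strains fixed) and each implant-malrotation variant (nominal ligament
#' parameters), and assembles the full report: stiffness windows,
#' per-scenario per-DOF mean +- SD differences (optimal - perturbed),
#' flexion-resolved difference curves, and the differences between the
#' strain-perturbed ("US") and implant-perturbed ("IMP") kinematics.
#'
#' @param model a settled `knee_model`.
#' @param protocol a [squat_protocol()].
#' @param targets list of [strain_error_target()]s (default: MCL and LCL
#'   at their reported residual errors).
#' @param implant_angles implant internal-external rotations to test,
#'   degrees (default `c(-3.2, 3.2)`).
#' @param directions stiffness perturbation directions per target.
#' @return An object of class `sensitivity_report`.
#' @export
run_sensitivity_study <- function(model, protocol = squat_protocol(),
                                  targets = list(strain_error_target("MCL"),
                                                 strain_error_target("LCL")),
                                  implant_angles = c(-3.2, 3.2),
                                  directions = c("decrease", "increase")) {
  if (!isTRUE(model$settled)) stop("run_sensitivity_study: settle the model first")
  nominal <- run_squat(model, protocol)
  scen <- list()
  windows <- list()
  for (tg in targets) {
    lig <- tg$ligament
    res <- tryCatch(
      stiffness_for_strain_error(model, lig, tg, protocol,
                                 nominal_trace = nominal,
                                 directions = directions),
      error = function(e) list(ligament = lig, error = conditionMessage(e)))
    if (!is.null(res$error)) { windows[[lig]] <- res; next }
    if (!isTRUE(res$active)) {
      windows[[lig]] <- list(k_low = "/", k_high = "/", active = FALSE,
                             note = res$note)
      next
    }
    windows[[lig]] <- list(
      k_low = if (!is.null(res$decrease)) res$decrease$k else NA,
      k_high = if (!is.null(res$increase)) res$increase$k else NA,
      k_nominal = res$k_nominal, active = TRUE,
      bound_hit = c(decrease = isTRUE(res$decrease$bound_hit),
                    increase = isTRUE(res$increase$bound_hit)),
      achieved = c(decrease = if (!is.null(res$decrease)) res$decrease$achieved else NA,
                   increase = if (!is.null(res$increase)) res$increase$achieved else NA))
    for (dir in directions) {
      r <- res[[dir]]
      if (is.null(r)) next
      tr <- if (!is.null(r$trace)) r$trace
            else run_squat(set_ligament_stiffness(model, lig, r$k), protocol)
      scen[[paste0(lig, "_k_", round(r$k))]] <- list(
        arm = "stiffness", ligament = lig, direction = dir, k = r$k,
        bound_hit = isTRUE(r$bound_hit), trace = tr)
    }
  }
  for (a in implant_angles) {
    mi <- apply_implant_ie_rotation(model, a)
    tr <- tryCatch(run_squat(mi, protocol), error = function(e) e)
    if (inherits(tr, "error")) {
      scen[[sprintf("implant_IE_%+.1f", a)]] <- list(
        arm = "implant", angle = a, failed = TRUE,
        error = conditionMessage(tr))
    } else {
      scen[[sprintf("implant_IE_%+.1f", a)]] <- list(
        arm = "implant", angle = a, trace = tr)
    }
  }
  diffs <- lapply(scen, function(s) {
    if (isTRUE(s$failed)) return(NULL)
    kinematic_difference(nominal, s$trace)
  })
  curves <- lapply(scen, function(s) {
    if (isTRUE(s$failed)) return(NULL)
    data.frame(FE = nominal$FE,
               dVV = nominal$VV - s$trace$VV,
               dIE = nominal$IE - s$trace$IE)
  })
  ## US-vs-IMP comparison: stiffness-perturbed vs implant-perturbed traces
  us <- names(scen)[vapply(scen, function(s) s$arm == "stiffness" && !isTRUE(s$failed), logical(1))]
  imp <- names(scen)[vapply(scen, function(s) s$arm == "implant" && !isTRUE(s$failed), logical(1))]
  us_vs_imp <- list()
  for (u in us) for (v in imp)
    us_vs_imp[[paste(u, "vs", v)]] <-
      kinematic_difference(scen[[u]]$trace, scen[[v]]$trace)
  structure(list(windows = windows,
                 scenarios = lapply(scen, function(s) s[setdiff(names(s), "trace")]),
                 differences = diffs, curves = curves,
                 us_vs_imp = us_vs_imp,
                 nominal_trace = nominal,
                 traces = lapply(scen, `[[`, "trace")),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report\n  stiffness windows:\n")
  for (lig in names(x$windows)) {
    w <- x$windows[[lig]]
    if (identical(w$k_low, "/")) {
      cat(sprintf("    %s: / (inactive)\n", lig))
    } else {
      cat(sprintf("    %s: %.0f - %.0f N (nominal %.0f)%s\n", lig,
                  as.numeric(w$k_low), as.numeric(w$k_high), w$k_nominal,
                  if (any(w$bound_hit)) " [bound hit]" else ""))
    }
  }
  cat("  per-scenario mean differences (optimal - perturbed):\n")
  for (s in names(x$differences)) {
    d <- x$differences[[s]]
    if (is.null(d)) next
    cat(sprintf("    %-22s %s\n", s,
                paste(sprintf("%s %+0.2f+-%0.2f", d$dof, d$mean, d$sd),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Serialize a sensitivity report to JSON (and back)
#'
#' The JSON round trip preserves windows, per-scenario differences and
#' curves (traces are not serialized).
#'
#' @param report a `sensitivity_report`.
#' @param path file path.
#' @return `read_sensitivity_report()` returns the deserialized list.
#' @export
write_sensitivity_report <- function(report, path) {
  out <- list(windows = report$windows, scenarios = report$scenarios,
              differences = report$differences, curves = report$curves,
              us_vs_imp = report$us_vs_imp)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sensitivity_report
#' @export
read_sensitivity_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
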