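## Ligament fine-tuning against a reference trace: minimize per-channel
## RMSE while maximizing Pearson correlation, scalarized as a
## range-normalized weighted sum and searched derivative-free (coordinate
## descent with golden-section line search; the simulator response is
## piecewise-smooth across contact/slack transitions, so no gradients).

#' Calibration specification
#'
#' @param free_parameters list of entries `list(ligament=, what=("k" or
#'   "eps_r"), lower=, upper=)` describing the search space.
#' @param weights named channel weights (channels: the six DOFs plus
#'   `F_ankle`, `F_quad`); defaults to 1 for each. Must not be all zero.
#' @param max_cycles full coordinate-descent sweeps.
#' @param tol stop when a full sweep improves the objective by less.
#' @param line_evals golden-section evaluations per parameter per sweep.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(free_parameters,
                             weights = NULL,
                             max_cycles = 3L, tol = 1e-4,
                             line_evals = 10L) {
  channels <- c("FE", "VV", "IE", "AP", "ML", "IS", "F_ankle", "F_quad")
  w <- stats::setNames(rep(1, length(channels)), channels)
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)
  if (any(w < 0) || all(w == 0))
    stop("calibration_spec: weights must be >= 0 and not all zero")
  for (fp in free_parameters) {
    if (!fp$what %in% c("k", "eps_r"))
      stop("calibration_spec: free parameter must tune 'k' or 'eps_r'")
    if (!is.finite(fp$lower) || !is.finite(fp$upper) || fp$lower >= fp$upper)
      stop("calibration_spec: bounds must be finite with lower < upper")
  }
  structure(list(free_parameters = free_parameters, weights = w,
                 max_cycles = as.integer(max_cycles), tol = tol,
                 line_evals = as.integer(line_evals)),
            class = "calibration_spec")
}

#' Calibration objective
#'
#' Scalarizes the fit of a simulated trace against a reference:
#' `sum_c w_c * (RMSE_c / range_c + (1 - rho_c) / 2)`, where `range_c` is
#' the reference channel range (floored at a small value for flat
#' channels). A constant simulated channel has no defined correlation;
#' its rho term takes the worst case (1) with a warning.
#'
#' @param sim,ref traces on the same cycle grid.
#' @param weights named channel weights.
#' @return Non-negative scalar; 0 for a perfect fit.
#' @export
calibration_objective <- function(sim, ref,
                                  weights = stats::setNames(rep(1, 8),
                                    c("FE", "VV", "IE", "AP", "ML", "IS",
                                      "F_ankle", "F_quad"))) {
  if (nrow(sim) != nrow(ref))
    stop("calibration_objective: traces are not on the same cycle grid")
  total <- 0
  for (ch in names(weights)) {
    w <- weights[[ch]]
    if (w == 0 || is.null(sim[[ch]]) || is.null(ref[[ch]])) next
    e <- rmse(sim[[ch]], ref[[ch]])
    rng <- max(ref[[ch]]) - min(ref[[ch]])
    scale <- max(rng, 1e-9)
    rho <- if (stats::sd(sim[[ch]]) == 0 || stats::sd(ref[[ch]]) == 0) {
      warning("calibration_objective: constant channel ", ch,
              "; correlation term set to worst case")
      -1
    } else stats::cor(sim[[ch]], ref[[ch]])
    total <- total + w * (e / scale + (1 - rho) / 2)
  }
  total
}

apply_free_parameters <- function(model, free_parameters, x) {
  for (j in seq_along(free_parameters)) {
    fp <- free_parameters[[j]]
    for (i in seq_along(model$bundles)) {
      if (model$bundles[[i]]$ligament == fp$ligament) {
        if (fp$what == "k") {
          model$bundles[[i]]$k <- x[j]
        } else {
          model$bundles[[i]]$eps_r <- x[j]
          model$bundles[[i]]$L0 <-
            zero_load_length(model$bundles[[i]]$Lr, x[j])
        }
      }
    }
  }
  model
}

#' Calibrate ligament parameters against a reference trace
#'
#' Bounded derivative-free search: coordinate descent over the free
#' parameters, one golden-section line search per parameter per sweep,
#' accepting only improvements (the objective history is non-increasing).
#' Simulation failures at trial points score `+Inf` and the search
#' continues.
#'
#' @param model a settled `knee_model` (starting parameters are taken
#'   from it).
#' @param reference_trace reference `squat_trace` on the protocol's grid.
#' @param spec a [calibration_spec()].
#' @param protocol a [squat_protocol()].
#' @return An object of class `calibration_result`: `parameters` (fitted
#'   vector), `model` (with fitted parameters applied), `objective_history`,
#'   `converged`, `report` (per-channel RMSE/rho table of the final fit).
#' @export
calibrate <- function(model, reference_trace, spec,
                      protocol = squat_protocol()) {
  if (!isTRUE(model$settled)) stop("calibrate: settle the model first")
  fps <- spec$free_parameters
  x <- vapply(fps, function(fp) {
    v <- vapply(model$bundles, function(b)
      if (b$ligament == fp$ligament) b[[fp$what]] else NA_real_, numeric(1))
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("calibrate: unknown ligament ", fp$ligament)
    min(max(v[[1]], fp$lower), fp$upper)
  }, numeric(1))

  n_evals <- 0L
  score <- function(x) {
    mx <- apply_free_parameters(model, fps, x)
    tr <- tryCatch(run_squat(mx, protocol), error = function(e) NULL)
    n_evals <<- n_evals + 1L
    if (is.null(tr)) return(list(J = Inf, trace = NULL))
    list(J = calibration_objective(tr, reference_trace, spec$weights),
         trace = tr)
  }

  best <- score(x)
  if (!is.finite(best$J))
    stop("calibrate: simulation failed at the starting parameters")
  history <- best$J
  converged <- FALSE
  gr <- (sqrt(5) - 1) / 2
  if (spec$max_cycles > 0) {
    for (cycle in seq_len(spec$max_cycles)) {
      J_before <- best$J
      for (j in seq_along(fps)) {
        a <- fps[[j]]$lower; b <- fps[[j]]$upper
        x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
        f_at <- function(v) { xx <- x; xx[j] <- v; score(xx) }
        s1 <- f_at(x1); s2 <- f_at(x2)
        evals <- 2L
        while (evals < spec$line_evals && (b - a) > 1e-9 * (fps[[j]]$upper - fps[[j]]$lower)) {
          if (s1$J <= s2$J) {
            b <- x2; x2 <- x1; s2 <- s1
            x1 <- b - gr * (b - a); s1 <- f_at(x1)
          } else {
            a <- x1; x1 <- x2; s1 <- s2
            x2 <- a + gr * (b - a); s2 <- f_at(x2)
          }
          evals <- evals + 1L
        }
        cand <- if (s1$J <= s2$J) list(v = x1, s = s1) else list(v = x2, s = s2)
        if (is.finite(cand$s$J) && cand$s$J < best$J) {   # accept-only-improvement
          x[j] <- cand$v
          best <- cand$s
        }
        history <- c(history, best$J)
      }
      if (J_before - best$J < spec$tol) { converged <- TRUE; break }
    }
  }
  fitted_model <- apply_free_parameters(model, fps, x)
  report <- if (!is.null(best$trace))
    compare_traces(best$trace, reference_trace) else NULL
  structure(list(parameters = stats::setNames(
    x, vapply(fps, function(fp) paste0(fp$ligament, "_", fp$what), character(1))),
    model = fitted_model, objective = best$J,
    objective_history = history, converged = converged,
    n_evals = n_evals, report = report),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result\n  parameters:\n")
  for (nm in names(x$parameters))
    cat(sprintf("    %s = %.4g\n", nm, x$parameters[[nm]]))
  cat(sprintf("  objective %.5g after %d simulations (converged: %s)\n",
              x$objective, x$n_evals, x$converged))
  invisible(x)
}

#' Write a calibration result to JSON
#'
#' @param result a `calibration_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calibration_result <- function(result, path) {
  out <- list(parameters = as.list(result$parameters),
              objective = result$objective,
              objective_history = result$objective_history,
              converged = result$converged, n_evals = result$n_evals,
              report = result$report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
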