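# Shared fixtures. Expensive artefacts (the settled default model, the
# default-protocol nominal trace, the MCL stiffness search) are computed
# once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# default study conditions: shipped parameter set, fixed seed
default_model <- function() {
  memo("default_model",
       equilibrium_settle(generate_synthetic_knee(synthetic_knee_params(seed = 7))))
}

# short protocol for unit tests (coarser cycle, single pass; duration
# shortened so the discrete controller keeps its per-sample loop gain)
fast_protocol <- function(...) {
  squat_protocol(cycle_samples = 31L, cycles = 1L, duration = 5, ...)
}

fast_trace <- function() {
  memo("fast_trace", run_squat(default_model(), fast_protocol()))
}

# default-protocol artefacts shared by the acceptance checks
nominal_trace <- function() {
  memo("nominal_trace", run_squat(default_model(), squat_protocol()))
}

mcl_search_increase <- function() {
  memo("mcl_search_increase",
       stiffness_for_strain_error(default_model(), "MCL",
                                  strain_error_target("MCL"),
                                  squat_protocol(),
                                  nominal_trace = nominal_trace(),
                                  directions = "increase"))
}

# model whose LCL is deeply slack (negative reference strain) throughout:
# it never tautens, not even at equilibrium-solver trial points, so a
# stiffness change cannot touch any evaluated quantity
slack_lcl_model <- function() {
  memo("slack_lcl_model", {
    lp <- kneesim:::default_ligament_params()
    lp$LCL$eps_r <- -0.15
    equilibrium_settle(generate_synthetic_knee(synthetic_knee_params(seed = 7),
                                               ligament_params = lp))
  })
}

# parameter-recovery experiment (shared by the calibration unit test and
# the acceptance property suite): truth k_MCL = 400 N, search from 650 N
calibration_recovery <- function() {
  memo("calibration_recovery", {
    m <- default_model()
    ref <- fast_trace()
    start <- scale_ligament_k(m, "MCL", 650 / 400)
    spec <- calibration_spec(list(list(ligament = "MCL", what = "k",
                                       lower = 150, upper = 900)),
                             max_cycles = 2L, line_evals = 12L)
    calibrate(start, ref, spec, fast_protocol())
  })
}

scale_ligament_k <- function(model, ligament, factor) {
  set_ligament_stiffness(
    model, ligament, ligament_stiffness(model, ligament) * factor)
}
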