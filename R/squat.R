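#' PID controller
#'
#' Discrete PID controller with clamped output and integral anti-windup
#' (the integral state is bounded so that the integral term alone cannot
#' exceed the output clamp). Used to regulate the quadriceps tension that
#' maintains the vertical ankle load setpoint.
#'
#' @param kp,ki,kd gains.
#' @param setpoint target value (N for the ankle-load loop).
#' @param clamp length-2 numeric, output bounds.
#' @return An object of class `pid_controller`.
#' @export
pid_controller <- function(kp, ki = 0, kd = 0, setpoint = 0,
                           clamp = c(-4000, 4000)) {
  structure(list(kp = kp, ki = ki, kd = kd, setpoint = setpoint,
                 clamp = sort(clamp), integral = 0, prev_error = NA_real_),
            class = "pid_controller")
}

#' Advance a PID controller by one sample
#'
#' @param ctrl a [pid_controller()].
#' @param measured measured process value.
#' @param dt time step, s (> 0).
#' @return List with the updated `ctrl` and the control `output`.
#' @export
pid_step <- function(ctrl, measured, dt) {
  if (!is.finite(dt) || dt <= 0) stop("pid_step: dt must be > 0")
  e <- ctrl$setpoint - measured
  ctrl$integral <- ctrl$integral + e * dt
  if (ctrl$ki > 0) {
    imax <- max(abs(ctrl$clamp)) / ctrl$ki
    ctrl$integral <- max(-imax, min(imax, ctrl$integral))
  }
  d <- if (is.na(ctrl$prev_error)) 0 else (e - ctrl$prev_error) / dt
  ctrl$prev_error <- e
  out <- ctrl$kp * e + ctrl$ki * ctrl$integral + ctrl$kd * d
  out <- max(ctrl$clamp[1], min(ctrl$clamp[2], out))
  list(ctrl = ctrl, output = out)
}

#' Squat protocol
#'
#' One cyclic squat: the hip carriage descends and returns along a raised
#' cosine in knee flexion between `start_flexion` and `max_flexion`, while
#' the quadriceps PID maintains the vertical ankle load setpoint and the
#' hamstrings pull with constant force.
#'
#' @param cycle_samples samples over the cycle (default 101, i.e. 0-100%).
#' @param duration cycle duration, s.
#' @param start_flexion knee flexion at cycle start/end, degrees.
#' @param max_flexion peak knee flexion, degrees.
#' @param ankle_load_setpoint vertical ankle load target, N.
#' @param hamstring_force constant hamstring force per side, N.
#' @param preload quadriceps preload applied at the starting position, N.
#' @param quad_pid named numeric `c(kp, ki, kd)`, quadriceps-loop gains
#'   (defaults from a relay-style tuning on the default synthetic model).
#' @param hip_kp hip displacement-tracking proportional gain, N/mm.
#' @param initial_quad_tension quadriceps tension during the lead-in ramp
#'   into the start-flexion configuration, N.
#' @param leadin_steps tension-ramp steps of the lead-in.
#' @param cycles number of squat cycles executed back to back; the
#'   quadriceps tension profile of each cycle feeds forward into the next
#'   (as on a repetitive rig) and the returned trace is the final cycle.
#' @return An object of class `squat_protocol`.
#' @export
squat_protocol <- function(cycle_samples = 101L, duration = 10,
                           start_flexion = 35, max_flexion = 90,
                           ankle_load_setpoint = 90, hamstring_force = 50,
                           preload = 0,
                           quad_pid = c(kp = 1.2, ki = 14, kd = 0.02),
                           hip_kp = 500, initial_quad_tension = 150,
                           leadin_steps = 12L, cycles = 2L) {
  if (cycle_samples < 3L) stop("squat_protocol: need at least 3 cycle samples")
  if (max_flexion < start_flexion)
    stop("squat_protocol: max_flexion must be >= start_flexion")
  if (ankle_load_setpoint <= 0)
    stop("squat_protocol: ankle load setpoint must be > 0")
  structure(list(cycle_samples = as.integer(cycle_samples), duration = duration,
                 start_flexion = start_flexion, max_flexion = max_flexion,
                 ankle_load_setpoint = ankle_load_setpoint,
                 hamstring_force = hamstring_force, preload = preload,
                 quad_pid = quad_pid, hip_kp = hip_kp,
                 initial_quad_tension = initial_quad_tension,
                 leadin_steps = as.integer(leadin_steps),
                 cycles = max(1L, as.integer(cycles))),
            class = "squat_protocol")
}

## hip height for a target knee flexion, from the two-link closure of the
## rig (hip rides the vertical axis through the ankle)
hip_height_for_flexion <- function(model, flexion_deg) {
  Lt <- model$params$bone_segment_lengths[["tibia"]]
  Lf <- model$params$bone_segment_lengths[["femur"]]
  L1 <- Lt + model$primitives$pivot_z
  L2 <- Lf - model$primitives$pivot_z
  sqrt(L1^2 + L2^2 + 2 * L1 * L2 * cos(deg2rad(flexion_deg)))
}

## initial guess for the generalized coordinates at a given flexion
q_guess_for_flexion <- function(model, flexion_deg) {
  phi <- deg2rad(flexion_deg)
  Lt <- model$params$bone_segment_lengths[["tibia"]]
  Lf <- model$params$bone_segment_lengths[["femur"]]
  L1 <- Lt + model$primitives$pivot_z
  L2 <- Lf - model$primitives$pivot_z
  ## split the flexion so horizontal offsets cancel: L1 sin(at) = L2 sin(af)
  at <- stats::uniroot(function(a) L1 * sin(a) - L2 * sin(phi - a),
                       c(0, phi + 1e-12), tol = 1e-12)$root
  af <- phi - at
  zh <- L1 * cos(at) + L2 * cos(af)
  Rt <- rot_y(at)
  Rf <- rot_y(-af)
  pivot_w <- as.numeric(Rt %*% c(0, 0, L1))
  ## patella: carried on the trochlear circle, advanced by ~60% of flexion
  ## plus the engagement ride of the (slack-at-reference) patellar tendon
  prim <- model$primitives
  r_pf <- prim$trochlea_radius + prim$patella_radius
  ride <- if (!is.na(model$quad_len0)) 0.33 * model$bundles$PL_c$Lr else 15
  ang0 <- deg2rad(20) + ride / r_pf
  ang <- ang0 + 0.6 * phi
  pat_w <- pivot_w + as.numeric(Rf %*% c(r_pf * cos(ang), 0, r_pf * sin(ang)))
  c(zh, -af, at, 0, 0, 0, pat_w, -af + 0.5 * phi, 0, 0)
}

#' Settle a knee model at full extension
#'
#' Static equilibrium at full extension under gravity and contact alone,
#' with the femoral component seating into the insert dishes (the patella
#' is carried with the femur; ligaments exert no force because their
#' reference lengths are defined *by* this pose). Each bundle's reference
#' length `Lr` is then set to its attachment distance, the zero-load
#' length follows from the reference strain, and the quadriceps excursion
#' baseline is recorded.
#'
#' @param model a `knee_model`.
#' @param tol residual vertical force tolerance on the femur, N.
#' @return The settled `knee_model` (poses updated, `Lr`/`L0` set,
#'   `settled = TRUE`).
#' @export
equilibrium_settle <- function(model, tol = 1e-6) {
  gen <- model$poses
  rel_patella <- pose_compose(pose_inverse(gen$femur), gen$patella)
  prim <- model$primitives
  cp <- model$contact
  mg <- (model$masses[["femur"]] + model$masses[["patella"]]) * GRAV
  z0 <- model$hip_height_extension
  ## net upward force on the femur+patella unit as a function of hip height
  fz <- function(zh) {
    dz <- zh - z0
    f <- -mg
    for (s in c("medial", "lateral")) {
      cs <- prim$condyle_center[[s]] + gen$femur$translation + c(0, 0, dz)
      cd <- prim$dish_center[[s]] + gen$tibia$translation
      d <- sqrt(sum((cs - cd)^2))
      depth <- prim$condyle_radius[[s]] + d - prim$dish_radius[[s]]
      if (depth > 0) {
        u <- (cs - cd) / d
        f <- f - cp$kc * depth^cp$tau * u[3]
      }
    }
    f
  }
  sol <- stats::uniroot(fz, c(z0 - 2, z0 + 0.5), tol = 1e-12)
  if (abs(fz(sol$root)) > tol)
    stop(sprintf("equilibrium_settle: residual vertical force %.3g N exceeds %.3g N",
                 abs(fz(sol$root)), tol))
  dz <- sol$root - z0
  poses <- list(
    femur = rigid_pose(gen$femur$rotation, gen$femur$translation + c(0, 0, dz)),
    tibia = gen$tibia,
    patella = NULL)
  poses$patella <- pose_compose(poses$femur, rel_patella)
  ## total tibiofemoral contact force must be positive (condyles seated)
  patches <- detect_contacts(model, poses)
  tf <- sum(vapply(patches, function(p)
    if (grepl("condyle", p$pair[1])) contact_force(p, cp)$magnitude else 0,
    numeric(1)))
  if (tf <= 0)
    stop("equilibrium_settle: condyles failed to seat (no tibiofemoral contact force)")
  ## fix reference lengths at the settled pose
  for (i in seq_along(model$bundles)) {
    bd <- model$bundles[[i]]
    p1 <- pose_apply(poses[[bd$origin_body]], bd$origin_pt)
    p2 <- pose_apply(poses[[bd$insertion_body]], bd$insertion_pt)
    Lr <- sqrt(sum((p2 - p1)^2))
    model$bundles[[i]]$Lr <- Lr
    model$bundles[[i]]$L0 <- zero_load_length(Lr, bd$eps_r)
  }
  zh <- sol$root
  qlen <- mean(vapply(model$actuators$quadriceps$bundles, function(b) {
    p1 <- pose_apply(poses$patella, b$patella_pt)
    p2 <- c(b$carriage_pt[1], b$carriage_pt[2], zh + b$carriage_pt[3])
    sqrt(sum((p2 - p1)^2))
  }, numeric(1)))
  model$poses <- poses
  model$quad_len0 <- qlen
  model$hip_height_settled <- zh
  model$settled <- TRUE
  model
}

#' Run one squat cycle
#'
#' Quasi-static continuation squat: at each cycle sample the hip-height
#' target follows the flexion profile, static equilibrium of the
#' unconstrained pose coordinates is solved (damped quasi-Newton on the
#' total potential, warm-started from the previous sample), and the
#' quadriceps tension is assembled as passive exponential force + PID
#' output + preload, with the PID regulating the vertical ankle load to
#' its setpoint.
#'
#' @param model a settled `knee_model` (see [equilibrium_settle()]).
#' @param protocol a [squat_protocol()].
#' @param record_bundles include per-bundle strain/force columns.
#' @return A `squat_trace`: data frame with columns `t, FE, VV, IE, AP,
#'   ML, IS, F_ankle, F_quad, hip_disp` and per-bundle `eps_*`, `f_*`
#'   columns; attributes `protocol` and `solver` (iterations, residuals).
#' @export
run_squat <- function(model, protocol = squat_protocol(),
                      record_bundles = TRUE) {
  if (!isTRUE(model$settled))
    stop("run_squat: settle the model first (equilibrium_settle)")
  pr <- protocol
  act <- model$actuators$quadriceps
  n <- pr$cycle_samples
  dt <- pr$duration / (n - 1)
  tt <- seq(0, 1, length.out = n)
  phi <- pr$start_flexion +
    (pr$max_flexion - pr$start_flexion) * (1 - cos(2 * pi * tt)) / 2

  ## lead-in: settle into the start-flexion configuration with a ramped
  ## quadriceps tension (the forward-flexed basin; near full extension the
  ## forward and backward buckling branches of the rig merge, so the
  ## continuation starts at the cycle's start flexion directly)
  q <- q_guess_for_flexion(model, pr$start_flexion)
  z0 <- hip_height_for_flexion(model, pr$start_flexion)
  for (Tq in seq(50, pr$initial_quad_tension,
                 length.out = max(2L, pr$leadin_steps))) {
    sys <- build_system(model, Tq, z0, hip_kp = pr$hip_kp,
                        hamstring_force = pr$hamstring_force)
    sol <- solve_equilibrium(sys, q)
    q <- sol$q
  }

  ctrl <- pid_controller(kp = pr$quad_pid[["kp"]], ki = pr$quad_pid[["ki"]],
                         kd = pr$quad_pid[["kd"]],
                         setpoint = pr$ankle_load_setpoint)
  ## prime the controller at the start pose
  det <- knee_eval(q, sys, detail = TRUE)
  st <- pid_step(ctrl, det$ankle_load, dt)
  ctrl <- st$ctrl

  rows <- vector("list", n)
  iters <- integer(n); resid <- numeric(n)
  feedfwd <- NULL                 # previous cycle's tension profile
  for (cyc in seq_len(pr$cycles)) {
    Tq_profile <- numeric(n)
    for (i in seq_len(n)) {
      base <- if (is.null(feedfwd)) {
        passive_quadriceps_force(det$quad_length - model$quad_len0,
                                 act$alpha, act$beta) + pr$preload
      } else feedfwd[i]
      Tq <- max(0, base + st$output)
      sys <- build_system(model, Tq, hip_height_for_flexion(model, phi[i]),
                          hip_kp = pr$hip_kp,
                          hamstring_force = pr$hamstring_force)
      sol <- solve_equilibrium(sys, q)
      q <- sol$q
      det <- knee_eval(q, sys, detail = TRUE)
      if (!all(is.finite(q)) || max(det$contact_depths) > 5 ||
          sol$residual > 1)
        stop(sprintf("run_squat: simulation failure at sample %d (penetration %.2f mm, residual %.3g N)",
                     i, max(det$contact_depths), sol$residual))
      Tq_profile[i] <- Tq
      if (cyc == pr$cycles) {
        jk <- grood_suntay(det$poses$femur, det$poses$tibia,
                           model$frames$femur, model$frames$tibia)
        row <- c(t = tt[i] * pr$duration, unclass(jk),
                 F_ankle = det$ankle_load, F_quad = Tq,
                 hip_disp = q[1] - model$hip_height_settled)
        if (record_bundles) {
          eps <- det$bundles[, "eps"]; ff <- det$bundles[, "force"]
          names(eps) <- paste0("eps_", rownames(det$bundles))
          names(ff) <- paste0("f_", rownames(det$bundles))
          row <- c(row, eps, ff)
        }
        rows[[i]] <- row
        iters[i] <- sol$counts[["function"]]
        resid[i] <- sol$residual
      }
      st <- pid_step(ctrl, det$ankle_load, dt)
      ctrl <- st$ctrl
    }
    feedfwd <- Tq_profile
  }
  tr <- as.data.frame(do.call(rbind, rows))
  class(tr) <- c("squat_trace", "data.frame")
  attr(tr, "protocol") <- pr
  attr(tr, "solver") <- list(fn_evals = iters, residual = resid)
  tr
}

#' @export
print.squat_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("squat_trace: %d samples, FE %.1f..%.1f deg\n",
              n, min(x$FE), max(x$FE)))
  half <- x$F_ankle[seq.int(ceiling(n / 2), n)]
  cat(sprintf("  mean ankle load (2nd half): %.2f N; quad force %.0f..%.0f N\n",
              mean(half), min(x$F_quad), max(x$F_quad)))
  invisible(x)
}

#' Mean ankle load over the converged part of a squat trace
#'
#' @param trace a `squat_trace`.
#' @param from start of the averaging window as a fraction of the cycle
#'   (default 0.5: the second half, once the load controller has settled).
#' @return Mean vertical ankle load, N.
#' @export
mean_ankle_load <- function(trace, from = 0.5) {
  n <- nrow(trace)
  idx <- seq.int(max(1L, ceiling(from * (n - 1)) + 1L), n)
  mean(trace$F_ankle[idx])
}
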