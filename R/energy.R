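## Quasi-static mechanics core.
##
## Generalized coordinates (12), angles in radians internally:
##   q[1]  z_h    hip carriage height (mm)
##   q[2]  th_f   femur sagittal rotation
##   q[3:5] tibia rotation (y-x-z factorization), q[6] tibia ankle ML (mm)
##   q[7:9] patella translation (mm), q[10:12] patella rotation (y-x-z)
##
## Rig constraints are built into the parametrization: the hip rides a
## vertical axis and rotates in the sagittal plane only; the ankle point
## is fixed in the anterior-posterior and vertical directions (free
## medio-lateral translation, free rotations via the tibia coordinates).
## Everything that loads the system has a potential for a fixed
## quadriceps tension, so static equilibrium is an energy minimum; the
## gradient is assembled analytically from the force elements.

GRAV <- 9.80665e0   # N per kg (forces in N, masses in kg)

poses_from_q <- function(model, q) {
  Rf <- rot_y(q[2])
  Rt <- rot_y(q[3]) %*% rot_x(q[4]) %*% rot_z(q[5])
  Rp <- rot_y(q[10]) %*% rot_x(q[11]) %*% rot_z(q[12])
  list(
    femur = rigid_pose(Rf, c(0, 0, q[1]) - as.numeric(Rf %*% model$hip_local)),
    tibia = rigid_pose(Rt, c(0, q[6], 0) - as.numeric(Rt %*% model$ankle_local)),
    patella = rigid_pose(Rp, q[7:9]))
}

q_from_poses <- function(model, poses) {
  yxz <- function(R) {
    b <- asin(max(-1, min(1, -R[2, 3])))
    c(atan2(R[1, 3], R[3, 3]), b, atan2(R[2, 1], R[2, 2]))
  }
  zh <- pose_apply(poses$femur, model$hip_local)[3]
  thf <- atan2(poses$femur$rotation[1, 3], poses$femur$rotation[3, 3])
  ta <- yxz(poses$tibia$rotation)
  ya <- pose_apply(poses$tibia, model$ankle_local)[2]
  pa <- yxz(poses$patella$rotation)
  c(zh, thf, ta, ya, poses$patella$translation, pa)
}

## Build the static per-solve system description.
build_system <- function(model, quad_tension, z_target,
                         hip_kp = 500, hamstring_force = 50,
                         require_settled = TRUE) {
  if (require_settled) {
    L0 <- vapply(model$bundles, `[[`, numeric(1), "L0")
    if (any(is.na(L0)))
      stop("model is not settled: ligament reference lengths undefined")
  }
  list(model = model, quad_T = quad_tension, z_target = z_target,
       hip_kp = hip_kp, ham_F = hamstring_force)
}

## Full evaluation: potential energy V, analytic gradient G = dV/dq, and
## (detail = TRUE) measured quantities: tibia net applied force (for the
## ankle reaction), bundle states, contact depths, quadriceps length.
knee_eval <- function(q, sys, detail = FALSE) {
  model <- sys$model
  zh <- q[1]; thf <- q[2]
  Rf <- rot_y(thf); dRf <- drot_y(thf)
  Ry <- rot_y(q[3]); Rx <- rot_x(q[4]); Rz <- rot_z(q[5])
  Rt <- Ry %*% Rx %*% Rz
  dRt1 <- drot_y(q[3]) %*% Rx %*% Rz
  dRt2 <- Ry %*% drot_x(q[4]) %*% Rz
  dRt3 <- Ry %*% Rx %*% drot_z(q[5])
  Py <- rot_y(q[10]); Px <- rot_x(q[11]); Pz <- rot_z(q[12])
  Rp <- Py %*% Px %*% Pz
  dRp1 <- drot_y(q[10]) %*% Px %*% Pz
  dRp2 <- Py %*% drot_x(q[11]) %*% Pz
  dRp3 <- Py %*% Px %*% drot_z(q[12])

  h <- model$hip_local; a <- model$ankle_local
  t_f <- c(0, 0, zh) - as.numeric(Rf %*% h)
  t_t <- c(0, q[6], 0) - as.numeric(Rt %*% a)
  t_p <- q[7:9]

  fem_pt <- function(x) as.numeric(Rf %*% x) + t_f
  tib_pt <- function(x) as.numeric(Rt %*% x) + t_t
  pat_pt <- function(x) as.numeric(Rp %*% x) + t_p
  car_pt <- function(x) c(x[1], x[2], zh + x[3])

  V <- 0
  G <- numeric(12)
  tib_F <- c(0, 0, 0)     # net applied force on the tibia (world)

  ## accumulate a world force F applied at local point x of a body
  addF <- function(body, x, F) {
    if (body == "femur") {
      G[1] <<- G[1] - F[3]
      G[2] <<- G[2] - sum(F * (dRf %*% (x - h)))
    } else if (body == "tibia") {
      G[3] <<- G[3] - sum(F * (dRt1 %*% (x - a)))
      G[4] <<- G[4] - sum(F * (dRt2 %*% (x - a)))
      G[5] <<- G[5] - sum(F * (dRt3 %*% (x - a)))
      G[6] <<- G[6] - F[2]
      tib_F <<- tib_F + F
    } else if (body == "patella") {
      G[7:9] <<- G[7:9] - F
      G[10] <<- G[10] - sum(F * (dRp1 %*% x))
      G[11] <<- G[11] - sum(F * (dRp2 %*% x))
      G[12] <<- G[12] - sum(F * (dRp3 %*% x))
    } else if (body == "carriage") {
      G[1] <<- G[1] - F[3]
    }
  }
  world_pt <- function(body, x)
    switch(body, femur = fem_pt(x), tibia = tib_pt(x),
           patella = pat_pt(x), carriage = car_pt(x))

  ## gravity
  for (b in c("femur", "tibia", "patella")) {
    m <- model$masses[[b]]
    com <- model$com_local[[b]]
    p <- world_pt(b, com)
    V <- V + m * GRAV * p[3]
    addF(b, com, c(0, 0, -m * GRAV))
  }

  ## hip tracking spring (PD proportional part; quasi-static)
  V <- V + 0.5 * sys$hip_kp * (zh - sys$z_target)^2
  G[1] <- G[1] + sys$hip_kp * (zh - sys$z_target)

  ## passive ligament bundles
  bundle_state <- if (detail) vector("list", length(model$bundles)) else NULL
  for (i in seq_along(model$bundles)) {
    bd <- model$bundles[[i]]
    p1 <- world_pt(bd$origin_body, bd$origin_pt)
    p2 <- world_pt(bd$insertion_body, bd$insertion_pt)
    d <- p2 - p1
    L <- sqrt(sum(d^2))
    eps <- (L - bd$L0) / bd$L0
    f <- if (eps <= 0) 0
         else if (eps <= 2 * bd$eps_l) 0.25 * bd$k * eps^2 / bd$eps_l
         else bd$k * (eps - bd$eps_l)
    V <- V + blankevoort_energy(eps, bd$k, bd$eps_l, bd$L0)
    if (f > 0) {
      u <- d / L
      addF(bd$origin_body, bd$origin_pt, f * u)
      addF(bd$insertion_body, bd$insertion_pt, -f * u)
    }
    if (detail)
      bundle_state[[i]] <- c(length = L, eps = eps, force = f)
  }

  ## quadriceps (fixed total tension, split over bundles)
  qb <- model$actuators$quadriceps$bundles
  Tq <- sys$quad_T / length(qb)
  quad_len <- 0
  for (b in qb) {
    p1 <- pat_pt(b$patella_pt)
    p2 <- car_pt(b$carriage_pt)
    d <- p2 - p1
    L <- sqrt(sum(d^2))
    quad_len <- quad_len + L / length(qb)
    V <- V + Tq * L
    if (Tq > 0 && L > 1e-9) {
      u <- d / L
      addF("patella", b$patella_pt, Tq * u)
      addF("carriage", b$carriage_pt, -Tq * u)
    }
  }

  ## hamstrings (constant force)
  for (b in model$actuators$hamstrings$bundles) {
    p1 <- tib_pt(b$tibia_pt)
    p2 <- car_pt(b$carriage_pt)
    d <- p2 - p1
    L <- sqrt(sum(d^2))
    V <- V + sys$ham_F * L
    if (sys$ham_F > 0 && L > 1e-9) {
      u <- d / L
      addF("tibia", b$tibia_pt, sys$ham_F * u)
      addF("carriage", b$carriage_pt, -sys$ham_F * u)
    }
  }

  ## contacts (elastic term only; quasi-static)
  cp <- model$contact
  prim <- model$primitives
  depths <- if (detail) c(dish_medial = 0, dish_lateral = 0, post_cam = 0,
                          patellofemoral = 0) else NULL
  ## conforming dish treated as a full socket: restoring whenever the
  ## centre distance exceeds the radial clearance, in every direction.
  ## The squat rig keeps the tibiofemoral joint compressed throughout, so
  ## at the solution this coincides with unilateral dish contact while
  ## closing the nonphysical escape routes in the energy landscape.
  for (s in c("medial", "lateral")) {
    cs <- fem_pt(prim$condyle_center[[s]])
    cd <- tib_pt(prim$dish_center[[s]])
    dd <- cs - cd
    dist <- sqrt(sum(dd^2))
    if (dist > 1e-12) {
      u <- dd / dist
      depth <- prim$condyle_radius[[s]] + dist - prim$dish_radius[[s]]
      if (depth > 0) {
        f <- cp$kc * depth^cp$tau
        V <- V + cp$kc * depth^(cp$tau + 1) / (cp$tau + 1)
        addF("femur", prim$condyle_center[[s]], -f * u)
        addF("tibia", prim$dish_center[[s]], f * u)
        if (detail) depths[[paste0("dish_", s)]] <- depth
      }
    }
  }
  ## post (tibia) vs cam (femur)
  ca <- fem_pt(prim$cam_a); cb <- fem_pt(prim$cam_b)
  pa <- tib_pt(prim$post_base); pb <- tib_pt(prim$post_top)
  ss <- segment_segment_distance(ca, cb, pa, pb)
  depth <- prim$cam_radius + prim$post_radius - ss$d
  if (depth > 0 && ss$d > 1e-12) {
    n <- (ss$p1 - ss$p2) / ss$d
    f <- cp$kc * depth^cp$tau
    V <- V + cp$kc * depth^(cp$tau + 1) / (cp$tau + 1)
    xf <- as.numeric(crossprod(Rf, ss$p1 - t_f))   # femur-local contact point
    xt <- as.numeric(crossprod(Rt, ss$p2 - t_t))
    addF("femur", xf, f * n)
    addF("tibia", xt, -f * n)
    if (detail) depths[["post_cam"]] <- depth
  }
  ## patellar button vs trochlear flange
  pc <- pat_pt(c(0, 0, 0))
  ta_ <- fem_pt(prim$trochlea_a); tb_ <- fem_pt(prim$trochlea_b)
  ps <- point_segment_distance(pc, ta_, tb_)
  depth <- prim$trochlea_radius + prim$patella_radius - ps$d
  if (depth > 0 && ps$d > 1e-12) {
    n <- (pc - ps$closest) / ps$d
    f <- cp$kc * depth^cp$tau
    V <- V + cp$kc * depth^(cp$tau + 1) / (cp$tau + 1)
    xf <- as.numeric(crossprod(Rf, ps$closest - t_f))
    addF("patella", c(0, 0, 0), f * n)
    addF("femur", xf, -f * n)
    if (detail) depths[["patellofemoral"]] <- depth
  }

  out <- list(V = V, G = G)
  if (detail) {
    bs <- do.call(rbind, bundle_state)
    rownames(bs) <- names(model$bundles)
    out$ankle_load <- -tib_F[3]        # vertical rig reaction at the ankle
    out$ankle_ap_reaction <- -tib_F[1]
    out$bundles <- bs
    out$contact_depths <- depths
    out$quad_length <- quad_len
    out$poses <- list(femur = rigid_pose(Rf, t_f), tibia = rigid_pose(Rt, t_t),
                      patella = rigid_pose(Rp, t_p))
  }
  out
}

## parameter scaling: rotations ~0.02 rad per unit step, translations ~1 mm
Q_PARSCALE <- c(1, 0.02, 0.02, 0.02, 0.02, 1, 1, 1, 1, 0.02, 0.02, 0.02)

## Minimize total potential at fixed quadriceps tension; warm-started.
solve_equilibrium <- function(sys, q0, maxit = 400, reltol = 1e-14) {
  ## cache: fn and gr share one evaluation
  last <- new.env(parent = emptyenv())
  last$q <- NULL
  ev <- function(q) {
    if (is.null(last$q) || !identical(q, last$q)) {
      last$res <- knee_eval(q, sys)
      last$q <- q
    }
    last$res
  }
  fit <- stats::optim(q0, fn = function(q) ev(q)$V, gr = function(q) ev(q)$G,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = Q_PARSCALE))
  ## one restart if the gradient is not yet tight (BFGS can stall on the
  ## piecewise-smooth contact/slack transitions)
  g <- knee_eval(fit$par, sys)$G
  if (max(abs(g * Q_PARSCALE)) > 1e-3) {
    fit <- stats::optim(fit$par, fn = function(q) ev(q)$V,
                        gr = function(q) ev(q)$G, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol,
                                       parscale = Q_PARSCALE))
    g <- knee_eval(fit$par, sys)$G
  }
  list(q = fit$par, V = fit$value, grad = g,
       residual = max(abs(g * Q_PARSCALE)), counts = fit$counts)
}
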