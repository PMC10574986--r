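#' Compliant contact parameters
#'
#' Parameters of the penetration-depth contact law
#' `F = kc * delta^tau + Cc * delta_dot` used at the tibiofemoral
#' (condyle-dish, post-cam) and patellofemoral interfaces.
#'
#' @param kc contact stiffness, N/mm (default 5000).
#' @param tau contact exponent, dimensionless (default 2.2).
#' @param Cc contact damping, N.s/mm (default 10). The damping term is
#'   inactive in the quasi-static solver (zero overlap rate).
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(kc = 5000, tau = 2.2, Cc = 10) {
  if (kc <= 0) stop("contact_params: kc must be > 0")
  if (tau < 1) stop("contact_params: tau must be >= 1")
  if (Cc < 0) stop("contact_params: Cc must be >= 0")
  structure(list(kc = kc, tau = tau, Cc = Cc), class = "contact_params")
}

#' Contact patch
#'
#' One interpenetrating primitive pair: overlap depth, overlap rate,
#' contact normal (unit vector, pointing from the second body towards the
#' first) and world-frame contact location.
#'
#' @param depth overlap depth `delta`, mm (>= 0).
#' @param rate overlap rate `delta_dot`, mm/s (positive = deepening).
#' @param normal unit 3-vector.
#' @param point world-frame contact location, mm.
#' @param pair character length-2: the two body (or primitive) names.
#' @return An object of class `contact_patch`.
#' @export
contact_patch <- function(depth, rate = 0, normal = c(0, 0, 1),
                          point = c(0, 0, 0), pair = c("a", "b")) {
  if (depth < 0) stop("contact_patch: depth must be >= 0")
  n <- sqrt(sum(normal^2))
  if (abs(n - 1) > 1e-9) stop("contact_patch: normal must be a unit vector")
  structure(list(depth = depth, rate = rate, normal = as.numeric(normal),
                 point = as.numeric(point), pair = pair),
            class = "contact_patch")
}

#' Contact force from a patch
#'
#' Normal compliant contact force: `|F| = kc * depth^tau + Cc * rate`,
#' clamped at zero from below (no adhesion), applied along the patch
#' normal as an equal-and-opposite pair. Purely normal: no friction.
#'
#' @param patch a [contact_patch()].
#' @param params a [contact_params()].
#' @return List with `magnitude` (N), `on_first` and `on_second` (world
#'   force vectors on the two bodies of the pair).
#' @examples
#' p <- contact_patch(depth = 1)
#' contact_force(p, contact_params())$magnitude   # 5000 N
#' @export
contact_force <- function(patch, params = contact_params()) {
  m <- params$kc * patch$depth^params$tau + params$Cc * patch$rate
  m <- max(0, m)
  list(magnitude = m,
       on_first = m * patch$normal,
       on_second = -m * patch$normal)
}

## --- analytic contact queries on the synthetic primitives ---------------

## sphere (radius rs, center cs) seated in a concave spherical dish
## (radius rd >= rs, curvature center cd). Penetration when the
## center-to-center distance exceeds rd - rs, gated to the dish aperture:
## the sphere center must lie within `aperture` of the dish's inward
## (-axis) direction as seen from the curvature center.
sphere_in_dish_depth <- function(cs, cd, rs, rd, down_axis, aperture_cos = 0.35) {
  d <- cs - cd
  dist <- sqrt(sum(d^2))
  if (dist < 1e-12) return(NULL)
  u <- d / dist
  if (sum(u * down_axis) < aperture_cos) return(NULL)
  depth <- rs + dist - rd
  if (depth <= 0) return(NULL)
  list(depth = depth, normal = -u,          # pushes sphere back towards cd
       point = cd + u * (rd - rs / 2))
}

#' Detect contacts in a posed knee model
#'
#' Resolves the analytic primitive pairs of the synthetic knee (medial and
#' lateral condyle vs insert dish, femoral cam vs tibial post, patellar
#' button vs trochlear flange) in the given body poses. Overlap rates are
#' computed from optional body twists; with static bodies all rates are 0.
#'
#' @param model a `knee_model`.
#' @param poses named list of [rigid_pose()]s (`femur`, `tibia`,
#'   `patella`); defaults to the model's stored poses.
#' @param prev_poses optional poses at time `t - dt` for overlap-rate
#'   estimation.
#' @param dt time step, s (used with `prev_poses`).
#' @return List of [contact_patch()]es (empty when nothing touches).
#' @export
detect_contacts <- function(model, poses = model$poses, prev_poses = NULL,
                            dt = NA_real_) {
  patches <- detect_contacts_internal(model, poses)
  if (!is.null(prev_poses) && is.finite(dt) && dt > 0) {
    prev <- detect_contacts_internal(model, prev_poses)
    prev_depth <- stats::setNames(
      vapply(prev, `[[`, numeric(1), "depth"),
      vapply(prev, function(p) paste(p$pair, collapse = "|"), character(1)))
    patches <- lapply(patches, function(p) {
      key <- paste(p$pair, collapse = "|")
      d0 <- if (key %in% names(prev_depth)) prev_depth[[key]] else 0
      p$rate <- (p$depth - d0) / dt
      p
    })
  }
  patches
}

detect_contacts_internal <- function(model, poses) {
  prim <- model$primitives
  Rf <- poses$femur$rotation; Rt <- poses$tibia$rotation
  patches <- list()
  down_t <- as.numeric(Rt %*% c(0, 0, -1))
  for (side in c("medial", "lateral")) {
    cs <- pose_apply(poses$femur, prim$condyle_center[[side]])
    cd <- pose_apply(poses$tibia, prim$dish_center[[side]])
    hit <- sphere_in_dish_depth(cs, cd, prim$condyle_radius[[side]],
                                prim$dish_radius[[side]], down_t)
    if (!is.null(hit))
      patches[[length(patches) + 1L]] <- contact_patch(
        hit$depth, 0, hit$normal, hit$point,
        c(paste0("condyle_", side), paste0("dish_", side)))
  }
  ## post (tibia, vertical capsule) vs cam (femur, transverse capsule)
  post_a <- pose_apply(poses$tibia, prim$post_base)
  post_b <- pose_apply(poses$tibia, prim$post_top)
  cam_a <- pose_apply(poses$femur, prim$cam_a)
  cam_b <- pose_apply(poses$femur, prim$cam_b)
  ss <- segment_segment_distance(cam_a, cam_b, post_a, post_b)
  pc_depth <- prim$cam_radius + prim$post_radius - ss$d
  if (pc_depth > 0 && ss$d > 1e-12) {
    n <- (ss$p1 - ss$p2) / ss$d       # pushes cam away from post
    patches[[length(patches) + 1L]] <- contact_patch(
      pc_depth, 0, n, (ss$p1 + ss$p2) / 2, c("cam", "post"))
  }
  ## patellar button (sphere) vs trochlear flange (cylinder segment)
  pc <- pose_apply(poses$patella, c(0, 0, 0))
  ax_a <- pose_apply(poses$femur, prim$trochlea_a)
  ax_b <- pose_apply(poses$femur, prim$trochlea_b)
  ps <- point_segment_distance(pc, ax_a, ax_b)
  pf_depth <- prim$trochlea_radius + prim$patella_radius - ps$d
  if (pf_depth > 0 && ps$d > 1e-12) {
    n <- (pc - ps$closest) / ps$d     # pushes patella off the flange
    patches[[length(patches) + 1L]] <- contact_patch(
      pf_depth, 0, n, ps$closest + n * prim$trochlea_radius,
      c("patella", "trochlea"))
  }
  patches
}
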