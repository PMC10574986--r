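#' Anatomical frame
#'
#' A body-fixed anatomical frame: origin plus a right-handed orthonormal
#' axis triad, expressed in the host body's local coordinates. The axis
#' convention throughout the package (right knee) is X = anterior,
#' Y = medial, Z = proximal.
#'
#' @param origin length-3 numeric, mm, in body coordinates.
#' @param axes 3x3 orthonormal matrix, columns = (anterior, medial,
#'   proximal) unit vectors in body coordinates.
#' @param side `"right"` (default) or `"left"`; a left knee mirrors the
#'   medial axis, and the sign convention is preserved under mirroring.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), axes = diag(3),
                             side = c("right", "left")) {
  side <- match.arg(side)
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("anatomical_frame: axes not orthonormal")
  if (det(axes) < 0)
    stop("anatomical_frame: axes must be right-handed")
  structure(list(origin = as.numeric(origin), axes = axes, side = side),
            class = "anatomical_frame")
}

frame_world <- function(body_pose, frame) {
  list(R = body_pose$rotation %*% frame$axes,
       o = pose_apply(body_pose, frame$origin))
}

#' Joint kinematics in the Grood-Suntay convention
#'
#' Container for the six tibiofemoral degrees of freedom. Sign convention:
#' positive flexion (FE), valgus (VV), external tibial rotation (IE),
#' anterior (AP), medial (ML) and proximal (IS) translation of the tibia
#' relative to the femur, translations resolved in the tibial anatomical
#' frame.
#'
#' @param FE,VV,IE angles, degrees.
#' @param AP,ML,IS translations, mm.
#' @return An object of class `joint_kinematics` (named numeric vector).
#' @export
joint_kinematics <- function(FE = 0, VV = 0, IE = 0, AP = 0, ML = 0, IS = 0) {
  v <- c(FE = FE, VV = VV, IE = IE, AP = AP, ML = ML, IS = IS)
  if (any(!is.finite(v))) stop("joint_kinematics: all six DOFs must be finite")
  ang <- v[c("FE", "VV", "IE")]
  if (any(ang <= -180 | ang > 180))
    stop("joint_kinematics: angles must lie in (-180, 180]")
  structure(v, class = "joint_kinematics")
}

#' Tibiofemoral kinematics from body poses (Grood-Suntay decomposition)
#'
#' Decomposes the relative pose of the tibia with respect to the femur
#' into the floating-axis joint coordinate system: flexion about the
#' femoral medio-lateral axis, internal-external rotation about the tibial
#' long axis, varus-valgus about the mutually perpendicular floating axis.
#' Translations are the components of the tibial frame origin relative to
#' the femoral frame origin, resolved on the tibial anatomical axes
#' (anterior, medial, proximal positive).
#'
#' @param femur_pose,tibia_pose [rigid_pose()] of each body in the world.
#' @param femur_frame,tibia_frame [anatomical_frame()] of each body.
#' @return A [joint_kinematics()] object (degrees, mm).
#' @examples
#' f <- anatomical_frame()
#' grood_suntay(rigid_pose(), rigid_pose(rot_y(deg2rad(20))), f, f)
#' @export
grood_suntay <- function(femur_pose, tibia_pose, femur_frame, tibia_frame) {
  Fw <- frame_world(femur_pose, femur_frame)
  Tw <- frame_world(tibia_pose, tibia_frame)
  R <- t(Fw$R) %*% Tw$R            # tibial axes in femoral frame
  ## y-x-z floating-axis decomposition: R = Ry(t1) Rx(t2) Rz(t3)
  sb <- -R[2, 3]
  if (abs(sb) > 1 - 1e-9)
    stop("grood_suntay: gimbal singularity (varus-valgus at +-90 deg), floating axis undefined")
  t2 <- asin(sb)
  t1 <- atan2(R[1, 3], R[3, 3])
  t3 <- atan2(R[2, 1], R[2, 2])
  sgn <- if (identical(tibia_frame$side, "left")) -1 else 1
  v <- t(Tw$R) %*% (Tw$o - Fw$o)
  joint_kinematics(FE = rad2deg(t1),
                   VV = sgn * -rad2deg(t2),
                   IE = sgn * -rad2deg(t3),
                   AP = v[1], ML = sgn * v[2], IS = v[3])
}

#' Relative pose from joint kinematics
#'
#' Inverse of [grood_suntay()]: builds the relative rigid pose `P` of the
#' tibia with respect to the femur (in femoral anatomical axes) such that
#' applying `P` to the femur pose reproduces the given kinematics:
#' `tibia_pose = femur_pose o P` (frame-to-frame composition).
#'
#' @param jk a [joint_kinematics()].
#' @param femur_frame,tibia_frame [anatomical_frame()]s (used for side
#'   handling).
#' @return A [rigid_pose()]: rotation = tibial axes in femoral axes,
#'   translation = tibial frame origin relative to the femoral frame
#'   origin, in femoral axes.
#' @export
pose_from_kinematics <- function(jk, femur_frame = anatomical_frame(),
                                 tibia_frame = anatomical_frame()) {
  jk <- as.numeric(jk[c("FE", "VV", "IE", "AP", "ML", "IS")])
  if (abs(abs(jk[2]) - 90) < 1e-7)
    stop("pose_from_kinematics: varus-valgus at +-90 deg is singular")
  sgn <- if (identical(tibia_frame$side, "left")) -1 else 1
  R <- rot_y(deg2rad(jk[1])) %*% rot_x(deg2rad(-sgn * jk[2])) %*%
    rot_z(deg2rad(-sgn * jk[3]))
  v <- c(jk[4], sgn * jk[5], jk[6])
  rigid_pose(R, as.numeric(R %*% v))
}

## Apply the relative pose produced by pose_from_kinematics to a femur
## pose + frames, returning a consistent world tibia pose.
tibia_pose_from_relative <- function(rel, femur_pose, femur_frame, tibia_frame) {
  Fw <- frame_world(femur_pose, femur_frame)
  Rt_world <- Fw$R %*% rel$rotation %*% t(tibia_frame$axes)
  o_t_world <- Fw$o + as.numeric(Fw$R %*% rel$translation)
  t_t <- o_t_world - as.numeric(Rt_world %*% tibia_frame$origin)
  rigid_pose(Rt_world, t_t)
}

#' Per-DOF laxity of a kinematic series
#'
#' Laxity is the absolute difference between the minimal and maximal value
#' of each degree of freedom across the motion.
#'
#' @param trace a `squat_trace` or any data frame with columns among
#'   `FE, VV, IE, AP, ML, IS`.
#' @return Named numeric vector of per-DOF ranges (max - min, >= 0).
#' @examples
#' tr <- data.frame(FE = c(35, 60, 90), VV = c(-2, 0, 3.15))
#' laxity(tr)
#' @export
laxity <- function(trace) {
  trace <- as.data.frame(trace)
  dofs <- intersect(c("FE", "VV", "IE", "AP", "ML", "IS"), names(trace))
  if (nrow(trace) == 0L || length(dofs) == 0L)
    stop("laxity: empty kinematic series")
  vapply(trace[dofs], function(x) {
    if (any(!is.finite(x))) stop("laxity: non-finite values in series")
    max(x) - min(x)
  }, numeric(1))
}

#' Kinematic trace CSV input/output
#'
#' Traces are written with the header `t,FE,VV,IE,AP,ML,IS` plus any
#' additional columns present (loads, per-bundle strains and forces).
#'
#' @param trace data frame to write.
#' @param path file path.
#' @return `read_trace_csv()` returns a data frame; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
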