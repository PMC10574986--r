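#' Elementary rotation matrices
#'
#' Right-handed rotation matrices about the world axes. Angles are in
#' radians here; every user-facing interface in the package takes degrees
#' and converts at the boundary.
#'
#' @param theta rotation angle, radians.
#' @return A 3x3 orthonormal rotation matrix.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rotations
#' @export
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rotations
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Degree/radian conversion
#'
#' @param x angle(s) to convert.
#' @return Converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

## Derivatives of the elementary rotations (needed for analytic
## generalized-force assembly in the equilibrium solver).
drot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(0, 0, 0, 0, -s, c, 0, -c, -s), 3, 3)
}
drot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(-s, 0, -c, 0, 0, 0, c, 0, -s), 3, 3)
}
drot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(-s, c, 0, -c, -s, 0, 0, 0, 0), 3, 3)
}

#' Rigid-body pose
#'
#' A pose is a proper rigid transform: `p_world = rotation %*% p_local +
#' translation`. Rotations are stored as 3x3 orthonormal matrices with
#' determinant +1; translations are in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix, `det == +1`.
#' @param translation numeric length-3 vector, mm.
#' @return An object of class `rigid_pose`.
#' @examples
#' p <- rigid_pose(rot_y(pi / 6), c(0, 0, 10))
#' q <- pose_compose(p, pose_inverse(p))   # identity
#' max(abs(q$translation)) < 1e-12
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_pose: rotation must be 3x3 and translation length 3")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9)
    stop(sprintf("rigid_pose: rotation not orthonormal (max deviation %.3g)", err))
  if (det(rotation) < 0)
    stop("rigid_pose: rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @rdname rigid_pose
#' @param pose,a,b `rigid_pose` objects.
#' @export
pose_inverse <- function(pose) {
  Rt <- t(pose$rotation)
  rigid_pose(Rt, -as.numeric(Rt %*% pose$translation))
}

#' @rdname rigid_pose
#' @export
pose_compose <- function(a, b) {
  rigid_pose(a$rotation %*% b$rotation,
             as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_pose
#' @param points numeric vector (length 3) or n x 3 matrix of local
#'   coordinates, mm.
#' @export
pose_apply <- function(pose, points) {
  if (is.null(dim(points))) {
    as.numeric(pose$rotation %*% points) + pose$translation
  } else {
    sweep(points %*% t(pose$rotation), 2, pose$translation, "+")
  }
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid_pose\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

## unit vector, with informative error on degenerate input
unitize <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(sprintf("degenerate %s: zero length", what))
  v / n
}

## distance from point p to segment [a, b]; returns list(d, closest)
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 < 1e-20) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  q <- a + t * ab
  list(d = sqrt(sum((p - q)^2)), closest = q, t = t)
}

## closest points between segments [a1,b1] and [a2,b2]
segment_segment_distance <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1; d2 <- b2 - a2; r <- a1 - a2
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a < 1e-20 && e < 1e-20) {
    return(list(d = sqrt(sum(r^2)), p1 = a1, p2 = a2))
  }
  if (a < 1e-20) {
    s <- 0; t <- max(0, min(1, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e < 1e-20) {
      t <- 0; s <- max(0, min(1, -c_ / a))
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > 1e-20) max(0, min(1, (b * f - c_ * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- max(0, min(1, -c_ / a)) }
      else if (t > 1) { t <- 1; s <- max(0, min(1, (b - c_) / a)) }
    }
  }
  p1 <- a1 + s * d1; p2 <- a2 + t * d2
  list(d = sqrt(sum((p1 - p2)^2)), p1 = p1, p2 = p2)
}
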