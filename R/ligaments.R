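#' Ligament strain
#'
#' Engineering strain of a bundle of current length `L` and zero-load
#' length `L0`: `(L - L0) / L0`. Negative values (slack bundle) are
#' allowed.
#'
#' @param L current length, mm (>= 0).
#' @param L0 zero-load length, mm (> 0).
#' @return Dimensionless strain.
#' @examples
#' strain(51.5, 50)   # 0.03
#' @export
strain <- function(L, L0) {
  if (any(L0 <= 0)) stop("strain: zero-load length L0 must be > 0")
  if (any(L < 0)) stop("strain: length L must be >= 0")
  (L - L0) / L0
}

#' Zero-load length from reference length and reference strain
#'
#' `L0 = Lr / (eps_r + 1)`: the length at which a bundle that carries
#' strain `eps_r` at its reference length `Lr` becomes load-free.
#'
#' @param Lr reference length, mm.
#' @param eps_r reference strain, dimensionless (> -1).
#' @return Zero-load length, mm.
#' @examples
#' zero_load_length(52, 0.04)   # 50
#' @export
zero_load_length <- function(Lr, eps_r) {
  if (any(eps_r <= -1)) stop("zero_load_length: reference strain must be > -1")
  Lr / (eps_r + 1)
}

#' Blankevoort tensile force law
#'
#' Piecewise nonlinear spring: zero when slack, quadratic toe region up to
#' twice the linear strain limit, then linear:
#' \deqn{f = 0 \; (\epsilon < 0); \quad
#'       f = \tfrac14 k \epsilon^2/\epsilon_l \; (0 \le \epsilon \le 2\epsilon_l); \quad
#'       f = k(\epsilon - \epsilon_l) \; (\epsilon > 2\epsilon_l).}
#' The law is C1-continuous at \eqn{\epsilon = 2\epsilon_l}.
#'
#' @param eps strain, dimensionless.
#' @param k bundle stiffness, N (strain is dimensionless so k carries the
#'   force unit).
#' @param eps_l linear strain limit, default 0.03.
#' @return Tensile force, N (>= 0). Vectorized over `eps`.
#' @examples
#' tensile_force(0.10, k = 400)   # 400 * (0.10 - 0.03) = 28 N
#' @export
tensile_force <- function(eps, k, eps_l = 0.03) {
  if (any(k < 0)) stop("tensile_force: stiffness k must be >= 0")
  if (any(eps_l <= 0)) stop("tensile_force: linear strain limit must be > 0")
  f <- numeric(length(eps))
  toe <- eps >= 0 & eps <= 2 * eps_l
  lin <- eps > 2 * eps_l
  f[toe] <- 0.25 * k * eps[toe]^2 / eps_l
  f[lin] <- k * (eps[lin] - eps_l)
  f
}

## Elastic energy of the Blankevoort law, integrated over bundle length:
## V(eps) = k*L0 * [ eps^3/(12 eps_l) ]                      toe region
##        = k*L0 * [ (2/3) eps_l^2 + ((eps-eps_l)^2 - eps_l^2)/2 ]  linear
blankevoort_energy <- function(eps, k, eps_l, L0) {
  if (eps <= 0) return(0)
  if (eps <= 2 * eps_l) return(k * L0 * eps^3 / (12 * eps_l))
  k * L0 * ((2 / 3) * eps_l^2 + ((eps - eps_l)^2 - eps_l^2) / 2)
}

#' Ligament bundle
#'
#' One straight-line Blankevoort element between two attachment points on
#' two bodies. The reference length `Lr` is defined at the settled
#' full-extension pose (see [equilibrium_settle()]); `L0` is then fixed by
#' [zero_load_length()]. No wrapping, no damping.
#'
#' @param name bundle name (e.g. `"MCL_a"`).
#' @param ligament parent ligament name (e.g. `"MCL"`); perturbations and
#'   activity flags operate per ligament.
#' @param origin_body,insertion_body body names (`"femur"`, `"tibia"`,
#'   `"patella"`).
#' @param origin_pt,insertion_pt length-3 attachment coordinates in the
#'   host body frames, mm.
#' @param k bundle stiffness, N.
#' @param eps_r reference strain.
#' @param eps_l linear strain limit.
#' @param Lr,L0 reference and zero-load lengths, mm (`NA` until settling).
#' @return An object of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, ligament, origin_body, origin_pt,
                            insertion_body, insertion_pt, k, eps_r,
                            eps_l = 0.03, Lr = NA_real_, L0 = NA_real_) {
  if (k < 0) stop("ligament_bundle: k must be >= 0 for bundle ", name)
  if (eps_l <= 0) stop("ligament_bundle: eps_l must be > 0 for bundle ", name)
  if (eps_r <= -1) stop("ligament_bundle: eps_r must be > -1 for bundle ", name)
  if (!is.na(Lr) && is.na(L0)) L0 <- zero_load_length(Lr, eps_r)
  if (!is.na(Lr) && abs(L0 - Lr / (eps_r + 1)) > 1e-12 * max(1, Lr))
    stop("ligament_bundle: L0 inconsistent with Lr/(eps_r + 1) for bundle ", name)
  structure(list(name = name, ligament = ligament,
                 origin_body = origin_body, origin_pt = as.numeric(origin_pt),
                 insertion_body = insertion_body,
                 insertion_pt = as.numeric(insertion_pt),
                 k = k, eps_r = eps_r, eps_l = eps_l, Lr = Lr, L0 = L0),
            class = "ligament_bundle")
}

#' Force pair exerted by a ligament bundle
#'
#' Evaluates the bundle in a posed model: the tensile force (Blankevoort
#' law at the current strain) acts along the straight attachment line,
#' pulling origin and insertion towards each other as an equal-and-
#' opposite (Newton third-law) pair.
#'
#' @param poses named list of [rigid_pose()]s for the bodies referenced by
#'   the bundle.
#' @param bundle a [ligament_bundle()] with `L0` set.
#' @return List with `length`, `eps`, `force` (scalar tension, N),
#'   `on_origin` and `on_insertion` (world force vectors, N).
#' @export
bundle_wrench <- function(poses, bundle) {
  if (is.na(bundle$L0))
    stop("bundle_wrench: bundle ", bundle$name,
         " has no zero-load length; settle the model first")
  p_or <- pose_apply(poses[[bundle$origin_body]], bundle$origin_pt)
  p_in <- pose_apply(poses[[bundle$insertion_body]], bundle$insertion_pt)
  d <- p_in - p_or
  L <- sqrt(sum(d^2))
  if (L < 1e-9)
    stop("bundle_wrench: coincident attachment points for bundle ",
         bundle$name, " (direction undefined)")
  u <- d / L
  eps <- strain(L, bundle$L0)
  f <- tensile_force(eps, bundle$k, bundle$eps_l)
  list(length = L, eps = eps, force = f,
       on_origin = f * u, on_insertion = -f * u)
}

#' Passive quadriceps force
#'
#' Exponential passive tendon-force model `alpha * exp(beta * Quadlength)`
#' where `Quadlength` is the quadriceps excursion (current mean bundle
#' length minus its value at the settled full-extension pose, mm).
#'
#' @param Quadlength quadriceps excursion, mm.
#' @param alpha scale, N (>= 0).
#' @param beta rate, 1/mm.
#' @return Passive force, N.
#' @examples
#' passive_quadriceps_force(0, alpha = 85, beta = 0.05)   # 85 N
#' @export
passive_quadriceps_force <- function(Quadlength, alpha, beta) {
  if (any(alpha < 0)) stop("passive_quadriceps_force: alpha must be >= 0")
  alpha * exp(beta * Quadlength)
}

## Default ligament parameter set (posterior-stabilized TKA, per-bundle
## stiffness shared across a ligament's bundles; configurable).
default_ligament_params <- function() {
  list(
    MCL      = list(k = 400,   eps_r = 0.04,  eps_l = 0.03),
    LCL      = list(k = 650,   eps_r = 0.08,  eps_l = 0.03),
    MPFL     = list(k = 6000,  eps_r = 0.08,  eps_l = 0.03),
    LPFL     = list(k = 3000,  eps_r = 0.06,  eps_l = 0.03),
    patellar = list(k = 25000, eps_r = -0.25, eps_l = 0.03)
  )
}

#' Read and write ligament parameter YAML files
#'
#' The YAML maps ligament name to `{k, eps_r, eps_l}` (N, -, -).
#'
#' @param params named list as returned by the reader.
#' @param path file path.
#' @return `read_ligament_params()` returns a named list;
#'   `write_ligament_params()` returns `path` invisibly.
#' @export
read_ligament_params <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_ligament_params
#' @export
write_ligament_params <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
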