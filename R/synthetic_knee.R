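## Synthetic post-TKA knee generation.
##
## The generator builds a parametric, seeded stand-in for CT-derived
## geometry: analytic primitives (spherical condyles, spherical-dish
## insert facets, capsule post and cam, cylindrical trochlear flange)
## tessellated to watertight multi-shell meshes. Contact resolution uses
## the analytic primitives directly; meshes exist for I/O and inspection.
## World frame (right knee, full extension): X anterior, Y medial,
## Z proximal; ankle at the origin; mm everywhere.

#' Parameters of the synthetic post-TKA knee
#'
#' @param condyle_radii named numeric, mm: radii of the medial and lateral
#'   femoral condyle spheres.
#' @param condyle_spacing centre-to-centre medio-lateral distance between
#'   the condyles, mm.
#' @param insert_dish_radii named numeric, mm: radii of the two insert
#'   dish facets; each must be >= the paired condyle radius (conforming).
#' @param post_cam_dims list: `post_radius`, `post_x`, `post_z_lo`,
#'   `post_z_hi` (tibial post capsule), `cam_radius`, `cam_half_length`,
#'   `cam_elevation` (femoral cam capsule, elevation above the condylar
#'   axis), mm.
#' @param bone_segment_lengths named numeric, mm: femoral shaft length
#'   (proximal resection) and tibial shaft length (distal resection).
#' @param trochlea_radius radius of the femoral trochlear flange cylinder, mm.
#' @param patella_radius radius of the patellar button sphere, mm.
#' @param attachment_offsets optional named list overriding individual
#'   attachment coordinates (names as in the generated model's
#'   `attachments` table).
#' @param attachment_jitter_sd standard deviation, mm, of the seeded
#'   normal jitter applied to ligament/tendon bone attachments (emulates
#'   specimen-to-specimen anatomical variability).
#' @param segment_masses named numeric, kg: femur, tibia, patella.
#' @param mesh_resolution segments per revolution used when tessellating
#'   primitives.
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical model.
#' @return An object of class `synthetic_knee_params`.
#' @export
synthetic_knee_params <- function(condyle_radii = c(medial = 18, lateral = 18),
                                  condyle_spacing = 44,
                                  insert_dish_radii = c(medial = 21, lateral = 21),
                                  post_cam_dims = list(post_radius = 5,
                                                       post_x = -8,
                                                       post_z_lo = -6,
                                                       post_z_hi = 10,
                                                       cam_radius = 8,
                                                       cam_half_length = 16,
                                                       cam_elevation = 20.5),
                                  bone_segment_lengths = c(femur = 320, tibia = 280),
                                  trochlea_radius = 26,
                                  patella_radius = 12,
                                  attachment_offsets = list(),
                                  attachment_jitter_sd = 0.3,
                                  segment_masses = c(femur = 3.0, tibia = 2.5,
                                                     patella = 0.1),
                                  mesh_resolution = 16L,
                                  seed = 1L) {
  p <- list(condyle_radii = condyle_radii, condyle_spacing = condyle_spacing,
            insert_dish_radii = insert_dish_radii, post_cam_dims = post_cam_dims,
            bone_segment_lengths = bone_segment_lengths,
            trochlea_radius = trochlea_radius, patella_radius = patella_radius,
            attachment_offsets = attachment_offsets,
            attachment_jitter_sd = attachment_jitter_sd,
            segment_masses = segment_masses,
            mesh_resolution = as.integer(mesh_resolution),
            seed = as.integer(seed))
  validate_synthetic_knee_params(p)
  structure(p, class = "synthetic_knee_params")
}

validate_synthetic_knee_params <- function(p) {
  err <- function(field, why)
    stop(sprintf("invalid synthetic knee parameter '%s': %s", field, why),
         call. = FALSE)
  pos <- function(field, v) if (any(!is.finite(v)) || any(v <= 0)) err(field, "must be strictly positive")
  pos("condyle_radii", p$condyle_radii)
  pos("condyle_spacing", p$condyle_spacing)
  pos("insert_dish_radii", p$insert_dish_radii)
  pos("bone_segment_lengths", p$bone_segment_lengths)
  pos("trochlea_radius", p$trochlea_radius)
  pos("patella_radius", p$patella_radius)
  pos("segment_masses", p$segment_masses)
  pos("mesh_resolution", p$mesh_resolution)
  d <- p$post_cam_dims
  pos("post_cam_dims$post_radius", d$post_radius)
  pos("post_cam_dims$cam_radius", d$cam_radius)
  pos("post_cam_dims$cam_half_length", d$cam_half_length)
  pos("post_cam_dims$cam_elevation", d$cam_elevation)
  if (d$post_z_hi <= d$post_z_lo)
    err("post_cam_dims$post_z_hi", "post top must lie above post base")
  if (p$attachment_jitter_sd < 0) err("attachment_jitter_sd", "must be >= 0")
  for (s in c("medial", "lateral"))
    if (p$insert_dish_radii[[s]] < p$condyle_radii[[s]])
      err("insert_dish_radii",
          sprintf("%s dish radius must be >= paired condyle radius", s))
  invisible(TRUE)
}

## run code with a private, restored RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## default attachment table: body-local coordinates, mm (right knee).
## Epicondylar / fibular / tibial positions scaled to segment dimensions.
default_attachments <- function(p) {
  w <- p$condyle_spacing / 2 + 11          # epicondylar half-width
  list(
    ## collateral bundles run obliquely (anterior-distal for the anterior
    ## MCL bundle), giving them internal-external rotational leverage
    MCL_a_origin    = list(body = "femur",   pt = c(14, w, 18)),
    MCL_a_insertion = list(body = "tibia",   pt = c(22, 28, -45)),
    MCL_p_origin    = list(body = "femur",   pt = c(-14, w, 14)),
    MCL_p_insertion = list(body = "tibia",   pt = c(-18, 28, -40)),
    LCL_origin      = list(body = "femur",   pt = c(4, -w, 16)),
    LCL_insertion   = list(body = "tibia",   pt = c(-14, -32, -35)),
    MPFL_origin     = list(body = "femur",   pt = c(-2, w, 18)),
    MPFL_insertion  = list(body = "patella", pt = c(0, 11, 2)),
    LPFL_origin     = list(body = "femur",   pt = c(-2, -w, 18)),
    LPFL_insertion  = list(body = "patella", pt = c(0, -11, 2)),
    PL_m_origin     = list(body = "patella", pt = c(4, 7, -10)),
    PL_m_insertion  = list(body = "tibia",   pt = c(35, 8, -40)),
    PL_c_origin     = list(body = "patella", pt = c(4, 0, -11)),
    PL_c_insertion  = list(body = "tibia",   pt = c(35, 0, -42)),
    PL_l_origin     = list(body = "patella", pt = c(4, -7, -10)),
    PL_l_insertion  = list(body = "tibia",   pt = c(35, -8, -40)),
    quad_m_insertion = list(body = "patella", pt = c(2, 7, 10)),
    quad_c_insertion = list(body = "patella", pt = c(2, 0, 11)),
    quad_l_insertion = list(body = "patella", pt = c(2, -7, 10)),
    ham_med_insertion = list(body = "tibia", pt = c(-25, 22, -12)),
    ham_lat_insertion = list(body = "tibia", pt = c(-28, -26, -18))
  )
}

## carriage-local attachment points (hip assembly; carriage origin rides
## the vertical hip axis at height z_h)
carriage_attachments <- function() {
  list(quad_m = c(20, 15, 20), quad_c = c(20, 0, 25), quad_l = c(20, -15, 20),
       ham_med = c(-30, 20, 20), ham_lat = c(-30, -20, 20))
}

#' Generate a synthetic post-TKA knee model
#'
#' Builds the full model: femur + femoral component, tibia + baseplate +
#' insert, patella; 8 passive Blankevoort bundles (MCL anterior/posterior,
#' LCL, MPFL, LPFL, patellar medial/central/lateral), 3 quadriceps bundles
#' and 2 constant-force hamstring actuators; watertight meshes; analytic
#' contact primitives; anatomical frames; and a full-extension pose in
#' which the condyles rest in the insert dishes without interpenetration.
#'
#' @param params a [synthetic_knee_params()].
#' @param ligament_params named list of per-ligament `{k, eps_r, eps_l}`
#'   (defaults: posterior-stabilized set, see the package vignette).
#' @return An object of class `knee_model`.
#' @examples
#' m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
#' length(m$bundles)        # 8 passive bundles
#' @export
generate_synthetic_knee <- function(params = synthetic_knee_params(),
                                    ligament_params = default_ligament_params()) {
  validate_synthetic_knee_params(params)
  p <- params
  Lf <- p$bone_segment_lengths[["femur"]]
  Lt <- p$bone_segment_lengths[["tibia"]]
  half <- p$condyle_spacing / 2
  rd <- p$insert_dish_radii
  rc <- p$condyle_radii
  dish_bottom <- -8
  dish_z <- vapply(c(medial = "medial", lateral = "lateral"),
                   function(s) dish_bottom + rd[[s]], numeric(1))
  cond_z <- vapply(c(medial = "medial", lateral = "lateral"),
                   function(s) dish_z[[s]] - (rd[[s]] - rc[[s]]), numeric(1))
  pivot_z <- mean(cond_z)                 # condylar axis height (femur local)
  pcd <- p$post_cam_dims

  prim <- list(
    condyle_center = list(medial = c(0, half, cond_z[["medial"]]),
                          lateral = c(0, -half, cond_z[["lateral"]])),
    condyle_radius = list(medial = rc[["medial"]], lateral = rc[["lateral"]]),
    dish_center = list(medial = c(0, half, dish_z[["medial"]]),
                       lateral = c(0, -half, dish_z[["lateral"]])),
    dish_radius = list(medial = rd[["medial"]], lateral = rd[["lateral"]]),
    post_base = c(pcd$post_x, 0, pcd$post_z_lo),
    post_top = c(pcd$post_x, 0, pcd$post_z_hi),
    post_radius = pcd$post_radius,
    cam_a = c(0, -pcd$cam_half_length, pivot_z + pcd$cam_elevation),
    cam_b = c(0, pcd$cam_half_length, pivot_z + pcd$cam_elevation),
    cam_radius = pcd$cam_radius,
    trochlea_a = c(0, -30, pivot_z),
    trochlea_b = c(0, 30, pivot_z),
    trochlea_radius = p$trochlea_radius,
    patella_radius = p$patella_radius,
    pivot_z = pivot_z
  )

  ## attachments: defaults + overrides + seeded jitter on bone/patella sites
  att <- default_attachments(p)
  for (nm in names(p$attachment_offsets)) {
    if (!nm %in% names(att))
      stop("invalid synthetic knee parameter 'attachment_offsets': unknown site ", nm)
    att[[nm]]$pt <- as.numeric(p$attachment_offsets[[nm]])
  }
  if (p$attachment_jitter_sd > 0) {
    jit <- with_local_seed(p$seed, {
      matrix(stats::rnorm(3L * length(att), sd = p$attachment_jitter_sd),
             ncol = 3L)
    })
    for (i in seq_along(att)) att[[i]]$pt <- att[[i]]$pt + jit[i, ]
  }

  lp <- ligament_params
  mk <- function(bname, lname, o, i)
    ligament_bundle(bname, lname,
                    att[[o]]$body, att[[o]]$pt, att[[i]]$body, att[[i]]$pt,
                    k = lp[[lname]]$k, eps_r = lp[[lname]]$eps_r,
                    eps_l = lp[[lname]]$eps_l)
  bundles <- list(
    MCL_a = mk("MCL_a", "MCL", "MCL_a_origin", "MCL_a_insertion"),
    MCL_p = mk("MCL_p", "MCL", "MCL_p_origin", "MCL_p_insertion"),
    LCL   = mk("LCL", "LCL", "LCL_origin", "LCL_insertion"),
    MPFL  = mk("MPFL", "MPFL", "MPFL_origin", "MPFL_insertion"),
    LPFL  = mk("LPFL", "LPFL", "LPFL_origin", "LPFL_insertion"),
    PL_m  = mk("PL_m", "patellar", "PL_m_origin", "PL_m_insertion"),
    PL_c  = mk("PL_c", "patellar", "PL_c_origin", "PL_c_insertion"),
    PL_l  = mk("PL_l", "patellar", "PL_l_origin", "PL_l_insertion")
  )

  car <- carriage_attachments()
  actuators <- list(
    quadriceps = list(kind = "quadriceps",
                      bundles = list(
                        list(patella_pt = att$quad_m_insertion$pt, carriage_pt = car$quad_m),
                        list(patella_pt = att$quad_c_insertion$pt, carriage_pt = car$quad_c),
                        list(patella_pt = att$quad_l_insertion$pt, carriage_pt = car$quad_l)),
                      alpha = 85, beta = 0.05, preload = 0),
    hamstrings = list(kind = "hamstring",
                      bundles = list(
                        list(tibia_pt = att$ham_med_insertion$pt, carriage_pt = car$ham_med),
                        list(tibia_pt = att$ham_lat_insertion$pt, carriage_pt = car$ham_lat)),
                      constant_force = 50)
  )

  res <- p$mesh_resolution
  femur_mesh <- mesh_union(
    mesh_cylinder(c(0, 0, 30), c(0, 0, 1), Lf - 30, 16, res),
    mesh_box(c(-25, -half - 12, 5), c(25, half + 12, 40)))
  tibia_mesh <- mesh_union(
    mesh_cylinder(c(0, 0, -Lt), c(0, 0, 1), Lt - 40, 14, res),
    mesh_box(c(-30, -half - 10, -60), c(38, half + 10, -2)))
  patella_mesh <- mesh_sphere(c(0, 0, 0), p$patella_radius, res)
  femoral_component_mesh <- mesh_union(
    mesh_sphere(prim$condyle_center$medial, rc[["medial"]], res),
    mesh_sphere(prim$condyle_center$lateral, rc[["lateral"]], res),
    mesh_cylinder(prim$cam_a, c(0, 1, 0), 2 * pcd$cam_half_length,
                  pcd$cam_radius, res),
    mesh_cylinder(prim$trochlea_a, c(0, 1, 0), 60, p$trochlea_radius, res))
  baseplate_mesh <- mesh_box(c(-30, -half - 14, -13), c(30, half + 14, -9))
  insert_mesh <- insert_dished_mesh(prim, half, dish_bottom)
  post_mesh <- mesh_cylinder(c(pcd$post_x, 0, pcd$post_z_lo), c(0, 0, 1),
                             pcd$post_z_hi - pcd$post_z_lo, pcd$post_radius, res)

  mk_body <- function(name, mesh, sites) {
    structure(list(name = name, mesh = mesh,
                   anatomical_frame = anatomical_frame(),
                   attachment_sites = sites), class = "knee_body")
  }
  sites_for <- function(body)
    lapply(Filter(function(a) a$body == body, att), `[[`, "pt")
  bodies <- list(
    femur = mk_body("femur", femur_mesh, sites_for("femur")),
    tibia = mk_body("tibia", tibia_mesh, sites_for("tibia")),
    patella = mk_body("patella", patella_mesh, sites_for("patella")))

  implant <- list(
    femoral_component = list(mesh = femoral_component_mesh,
                             host = "femur", pose = rigid_pose()),
    tibial_baseplate = list(mesh = baseplate_mesh,
                            host = "tibia", pose = rigid_pose()),
    insert = list(mesh = mesh_union(insert_mesh, post_mesh),
                  host = "tibia", pose = rigid_pose()),
    ie_offset_deg = 0)

  ## full-extension pose: tibia upright on the ankle, femur seated so the
  ## condyles exactly touch the dish bottoms, patella touching the flange
  knee_z <- Lt
  patella_angle <- deg2rad(20)
  r_pf <- p$trochlea_radius + p$patella_radius
  patella_local <- c(r_pf * cos(patella_angle), 0,
                     pivot_z + r_pf * sin(patella_angle))
  poses <- list(
    femur = rigid_pose(diag(3), c(0, 0, knee_z)),
    tibia = rigid_pose(diag(3), c(0, 0, knee_z)),
    patella = rigid_pose(diag(3), c(0, 0, knee_z) + patella_local))

  model <- structure(list(
    params = p, side = "right",
    bodies = bodies, implant = implant, primitives = prim,
    bundles = bundles, actuators = actuators,
    masses = p$segment_masses,
    com_local = list(femur = c(0, 0, Lf / 2), tibia = c(0, 0, -Lt / 2),
                     patella = c(0, 0, 0)),
    hip_local = c(0, 0, Lf), ankle_local = c(0, 0, -Lt),
    carriage = carriage_attachments(),
    frames = list(femur = anatomical_frame(), tibia = anatomical_frame(),
                  patella = anatomical_frame()),
    poses = poses, contact = contact_params(),
    hip_height_extension = NA_real_,
    settled = FALSE, quad_len0 = NA_real_), class = "knee_model")
  model$hip_height_extension <- as.numeric(
    pose_apply(poses$femur, model$hip_local)[3])
  model
}

## dished insert top surface as a closed height-field box
insert_dished_mesh <- function(prim, half, dish_bottom) {
  top <- -2; z0 <- dish_bottom - 1
  xs <- sort(unique(c(seq(-28, 28, by = 4), 0)))
  ys <- sort(unique(c(seq(-half - 14, half + 14, by = 4), -half, 0, half)))
  zfun <- function(x, y) {
    z <- top
    for (s in c("medial", "lateral")) {
      cd <- prim$dish_center[[s]]; r <- prim$dish_radius[[s]]
      r2 <- (x - cd[1])^2 + (y - cd[2])^2
      if (r2 < r^2) z <- min(z, cd[3] - sqrt(r^2 - r2))
    }
    z
  }
  mesh_heightfield(xs, ys, zfun, z0)
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("knee_model (%s knee): %d passive bundles, %d quadriceps bundles, %d hamstrings\n",
              x$side, length(x$bundles),
              length(x$actuators$quadriceps$bundles),
              length(x$actuators$hamstrings$bundles)))
  cat(sprintf("  settled: %s; implant IE offset: %.2f deg\n",
              x$settled, x$implant$ie_offset_deg))
  invisible(x)
}

#' Rotate the tibial implant components about the tibial long axis
#'
#' Applies an internal-external malrotation to the tibial baseplate and
#' polyethylene insert (dish facets and post rotate together) about the
#' tibial anatomical long axis through the baseplate centre. Bones,
#' ligament attachments and the femoral component are unchanged.
#'
#' @param model a `knee_model`.
#' @param angle rotation, degrees (positive = external rotation of the
#'   components on a right tibia); `|angle|` must be <= 15.
#' @return A new `knee_model` with rotated component primitives and poses.
#' @export
apply_implant_ie_rotation <- function(model, angle) {
  if (!is.finite(angle) || abs(angle) > 15)
    stop("apply_implant_ie_rotation: |angle| must be <= 15 degrees")
  if (angle == 0) return(model)
  R <- rot_z(deg2rad(angle))
  rot <- function(v) as.numeric(R %*% v)
  prim <- model$primitives
  prim$dish_center <- lapply(prim$dish_center, rot)
  prim$post_base <- rot(prim$post_base)
  prim$post_top <- rot(prim$post_top)
  model$primitives <- prim
  rp <- rigid_pose(R, c(0, 0, 0))
  model$implant$tibial_baseplate$pose <-
    pose_compose(rp, model$implant$tibial_baseplate$pose)
  model$implant$insert$pose <- pose_compose(rp, model$implant$insert$pose)
  model$implant$ie_offset_deg <- model$implant$ie_offset_deg + angle
  model
}

#' Maximum interpenetration of the insert into the condyles
#'
#' Brute-force signed-distance query of every insert-mesh vertex (posed in
#' the world) against the condyle sphere surfaces; the maximum positive
#' penetration depth, 0 when the surfaces at most touch.
#'
#' @param model a `knee_model`.
#' @param poses body poses (default: the model's stored poses).
#' @return Maximum penetration depth, mm (>= 0).
#' @export
insert_condyle_penetration <- function(model, poses = model$poses) {
  ins <- model$implant$insert
  v_local <- pose_apply(ins$pose, ins$mesh$vertices)
  v <- pose_apply(poses$tibia, v_local)
  worst <- 0
  for (s in c("medial", "lateral")) {
    cc <- pose_apply(poses$femur, model$primitives$condyle_center[[s]])
    r <- model$primitives$condyle_radius[[s]]
    d <- sqrt(rowSums(sweep(v, 2, cc, "-")^2))
    worst <- max(worst, r - min(d))
  }
  max(0, worst)
}

## analytic distance from an attachment site to its host body surface
attachment_surface_distance <- function(model, body, pt) {
  half <- model$params$condyle_spacing / 2
  Lf <- model$params$bone_segment_lengths[["femur"]]
  Lt <- model$params$bone_segment_lengths[["tibia"]]
  d_cyl <- function(p, a, b, r) {
    ps <- point_segment_distance(p, a, b)
    abs(ps$d - r)
  }
  d_box <- function(p, lo, hi) {
    q <- pmin(pmax(p, lo), hi)
    out <- sqrt(sum((p - q)^2))
    if (out > 0) return(out)
    min(p - lo, hi - p)
  }
  switch(body,
    femur = min(d_cyl(pt, c(0, 0, 30), c(0, 0, Lf), 16),
                d_box(pt, c(-25, -half - 12, 5), c(25, half + 12, 40))),
    tibia = min(d_cyl(pt, c(0, 0, -Lt), c(0, 0, -40), 14),
                d_box(pt, c(-30, -half - 10, -60), c(38, half + 10, -2))),
    patella = abs(sqrt(sum(pt^2)) - model$params$patella_radius),
    stop("unknown body: ", body))
}

## --- model serialization -------------------------------------------------

#' Write a knee model to a directory (STL meshes + JSON metadata)
#'
#' @param model a `knee_model`.
#' @param dir output directory (created if needed).
#' @param ascii write ASCII STL instead of binary.
#' @return `dir`, invisibly.
#' @export
write_knee_model <- function(model, dir, ascii = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(model$bodies))
    write_stl(model$bodies[[b]]$mesh, file.path(dir, paste0(b, ".stl")), ascii)
  for (partname in c("femoral_component", "tibial_baseplate", "insert"))
    write_stl(model$implant[[partname]]$mesh,
              file.path(dir, paste0(partname, ".stl")), ascii)
  meta <- list(
    side = model$side,
    params = unclass(model$params),
    primitives = model$primitives,
    bundles = lapply(model$bundles, unclass),
    actuators = model$actuators,
    masses = as.list(model$masses),
    implant_ie_offset_deg = model$implant$ie_offset_deg,
    settled = model$settled, quad_len0 = model$quad_len0,
    poses = lapply(model$poses, function(p)
      list(rotation = as.numeric(p$rotation), translation = p$translation)))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read and write synthetic-knee parameter YAML configs
#'
#' @param params a [synthetic_knee_params()].
#' @param path file path.
#' @return `read_knee_params()` returns a [synthetic_knee_params()].
#' @export
write_knee_params <- function(params, path) {
  u <- unclass(params)
  ## yaml drops names of atomic vectors; store named fields as maps
  for (f in c("condyle_radii", "insert_dish_radii", "bone_segment_lengths",
              "segment_masses"))
    u[[f]] <- as.list(u[[f]])
  yaml::write_yaml(u, path)
  invisible(path)
}

#' @rdname write_knee_params
#' @export
read_knee_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$condyle_radii <- unlist(raw$condyle_radii)
  raw$insert_dish_radii <- unlist(raw$insert_dish_radii)
  raw$bone_segment_lengths <- unlist(raw$bone_segment_lengths)
  raw$segment_masses <- unlist(raw$segment_masses)
  do.call(synthetic_knee_params, raw)
}
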