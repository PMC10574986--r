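fr <- anatomical_frame()

test_that("coincident aligned bodies give all-zero kinematics", {
  jk <- grood_suntay(rigid_pose(), rigid_pose(), fr, fr)
  expect_equal(unclass(jk), c(FE = 0, VV = 0, IE = 0, AP = 0, ML = 0, IS = 0))
})

test_that("elementary motions carry the published sign convention", {
  ## tibia rotating +30 deg about the (medial) y axis relative to the
  ## femur = 30 deg of flexion
  jk <- grood_suntay(rigid_pose(), rigid_pose(rot_y(deg2rad(30))), fr, fr)
  expect_equal(jk[["FE"]], 30, tolerance = 1e-9)
  expect_lt(max(abs(jk[c("VV", "IE", "AP", "ML", "IS")])), 1e-9)
  ## +5 mm displacement of the tibia along its own medial axis
  jk <- grood_suntay(rigid_pose(), rigid_pose(diag(3), c(0, 5, 0)), fr, fr)
  expect_equal(jk[["ML"]], 5, tolerance = 1e-12)
  expect_lt(max(abs(jk[c("FE", "VV", "IE", "AP", "IS")])), 1e-12)
  ## full audit: valgus, external rotation, anterior, proximal positive
  jk <- grood_suntay(rigid_pose(), rigid_pose(rot_x(deg2rad(-4))), fr, fr)
  expect_equal(jk[["VV"]], 4, tolerance = 1e-9)       # valgus = tibia -x roll
  jk <- grood_suntay(rigid_pose(), rigid_pose(rot_z(deg2rad(-6))), fr, fr)
  expect_equal(jk[["IE"]], 6, tolerance = 1e-9)       # external = tibia -z yaw
  jk <- grood_suntay(rigid_pose(), rigid_pose(diag(3), c(7, 0, 0)), fr, fr)
  expect_equal(jk[["AP"]], 7, tolerance = 1e-12)      # anterior
  jk <- grood_suntay(rigid_pose(), rigid_pose(diag(3), c(0, 0, 9)), fr, fr)
  expect_equal(jk[["IS"]], 9, tolerance = 1e-12)      # proximal
})

test_that("kinematics round-trip through pose_from_kinematics to 1e-9", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    jk <- joint_kinematics(FE = runif(1, -120, 120), VV = runif(1, -45, 45),
                           IE = runif(1, -45, 45), AP = runif(1, -20, 20),
                           ML = runif(1, -20, 20), IS = runif(1, -20, 20))
    fp <- rigid_pose(rot_y(runif(1, -1, 1)) %*% rot_x(runif(1, -0.5, 0.5)),
                     runif(3, -50, 50))
    rel <- pose_from_kinematics(jk)
    tp <- kneesim:::tibia_pose_from_relative(rel, fp, fr, fr)
    back <- grood_suntay(fp, tp, fr, fr)
    worst <- max(worst, max(abs(unclass(back) - unclass(jk))))
  }
  expect_lt(worst, 1e-9)
})

test_that("a 35 deg flexion pose reproduces a 35 deg relative rotation angle", {
  rel <- pose_from_kinematics(joint_kinematics(FE = 35))
  ang <- acos((sum(diag(rel$rotation)) - 1) / 2)
  expect_equal(rad2deg(ang), 35, tolerance = 1e-9)
})

test_that("kinematics are invariant to a common rigid transform", {
  fp <- rigid_pose(rot_y(0.4), c(10, -5, 30))
  tp <- rigid_pose(rot_y(0.9) %*% rot_z(-0.1), c(12, -2, 25))
  jk1 <- grood_suntay(fp, tp, fr, fr)
  g <- rigid_pose(rot_z(1.1) %*% rot_x(0.3), c(-40, 8, 100))
  jk2 <- grood_suntay(pose_compose(g, fp), pose_compose(g, tp), fr, fr)
  expect_equal(unclass(jk1), unclass(jk2), tolerance = 1e-9)
})

test_that("the floating axis degenerates at 90 deg varus-valgus", {
  expect_error(grood_suntay(rigid_pose(), rigid_pose(rot_x(deg2rad(-90))), fr, fr),
               "singular")
  expect_error(pose_from_kinematics(joint_kinematics(VV = 90)), "singular")
})

test_that("laxity is the per-DOF range, order-independent", {
  const <- data.frame(FE = rep(40, 7), VV = rep(-1, 7), IE = rep(2, 7),
                      AP = rep(0, 7), ML = rep(0.5, 7), IS = rep(9, 7))
  expect_true(all(laxity(const) == 0))
  tr <- data.frame(VV = c(-2.00, 0.3, 3.15, 1.2), IE = c(0, 8.37, 3, 1))
  lx <- laxity(tr)
  expect_equal(lx[["VV"]], 5.15)
  expect_equal(lx[["IE"]], 8.37)
  shuffled <- tr[c(3, 1, 4, 2), ]
  expect_equal(laxity(shuffled), lx)
  expect_error(laxity(data.frame(FE = numeric(0))), "empty")
})

test_that("kinematic traces survive a CSV round trip", {
  tr <- data.frame(t = c(0, 0.1), FE = c(35, 36), VV = c(0, 0.1),
                   IE = c(-1, -1.1), AP = c(2, 2.2), ML = c(0, 0.05),
                   IS = c(1, 1.01))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  rt <- read_trace_csv(f)
  expect_equal(names(rt), names(tr))
  expect_equal(rt$FE, tr$FE)
})
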