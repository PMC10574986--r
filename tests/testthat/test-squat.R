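test_that("pid_step implements the textbook law with anti-windup", {
  c0 <- pid_controller(kp = 2, ki = 0.5, kd = 0.1, setpoint = 10)
  ## zero error, zero state -> zero output
  out <- pid_step(c0, measured = 10, dt = 0.1)
  expect_equal(out$output, 0)
  ## proportional-only under constant error
  cp <- pid_controller(kp = 3, setpoint = 10)
  expect_equal(pid_step(cp, 6, 0.1)$output, 3 * 4)
  ## integral stays bounded by clamp/ki
  ci <- pid_controller(kp = 0, ki = 10, setpoint = 100, clamp = c(-50, 50))
  for (i in 1:1000) ci <- pid_step(ci, 0, 1)$ctrl
  expect_lte(abs(ci$integral), 50 / 10 + 1e-9)
  expect_error(pid_step(c0, 1, dt = 0), "dt")
})

test_that("a tuned PID drives a first-order plant to its setpoint", {
  ## plant: y' = (u - y) / tau, simulated with forward Euler
  tau <- 0.5; dt <- 0.01
  ctrl <- pid_controller(kp = 2, ki = 8, kd = 0.02, setpoint = 1)
  y <- 0
  for (i in 1:600) {
    st <- pid_step(ctrl, y, dt)
    ctrl <- st$ctrl
    y <- y + dt * (st$output - y) / tau
  }
  expect_lt(abs(y - 1), 0.02)            # within 2 % of the setpoint
})

test_that("settling fixes reference strains and is idempotent", {
  m <- default_model()
  ## strain at the settled pose equals the reference strain (Eq closure)
  for (b in m$bundles) {
    p1 <- pose_apply(m$poses[[b$origin_body]], b$origin_pt)
    p2 <- pose_apply(m$poses[[b$insertion_body]], b$insertion_pt)
    expect_equal(strain(sqrt(sum((p2 - p1)^2)), b$L0), b$eps_r,
                 tolerance = 1e-9)
  }
  m2 <- equilibrium_settle(m)
  expect_equal(vapply(m2$bundles, `[[`, numeric(1), "Lr"),
               vapply(m$bundles, `[[`, numeric(1), "Lr"),
               tolerance = 1e-9)
  ## the femoral unit is in vertical equilibrium and the condyles seated
  patches <- detect_contacts(m, m$poses)
  expect_gt(length(patches), 0L)
  tf <- sum(vapply(patches, function(p)
    contact_force(p, m$contact)$magnitude, numeric(1)))
  expect_gt(tf, 0)
})

test_that("a squat cycle starts at the start flexion and respects the rig", {
  tr <- fast_trace()
  expect_equal(tr$FE[1], 35, tolerance = 0.5)
  expect_equal(nrow(tr), 31L)
  ## flexion profile is cyclic: returns to the start
  expect_equal(tr$FE[31], tr$FE[1], tolerance = 0.5)
  ## rig constraints: hip on the vertical axis, ankle AP/vertical blocked
  m <- default_model()
  q <- kneesim:::q_guess_for_flexion(m, 50)
  poses <- kneesim:::poses_from_q(m, q)
  hip <- pose_apply(poses$femur, m$hip_local)
  expect_equal(hip[1], 0, tolerance = 1e-12)
  expect_equal(hip[2], 0, tolerance = 1e-12)
  ankle <- pose_apply(poses$tibia, m$ankle_local)
  expect_equal(ankle[1], 0, tolerance = 1e-12)   # anterior-posterior eliminated
  expect_equal(ankle[3], 0, tolerance = 1e-12)
})

test_that("zero drive amplitude leaves flexion constant", {
  m <- default_model()
  tr <- run_squat(m, fast_protocol(max_flexion = 35))
  expect_lt(laxity(tr)[["FE"]], 1)
})

test_that("squat traces are deterministic and track the hip profile", {
  tr1 <- fast_trace()
  tr2 <- run_squat(default_model(), fast_protocol())
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  m <- default_model()
  target <- vapply(tr1$FE, function(f) kneesim:::hip_height_for_flexion(m, f),
                   numeric(1))
  achieved <- tr1$hip_disp + m$hip_height_settled
  expect_lt(sqrt(mean((achieved - target)^2)), 1)   # < 1 mm RMS
})

test_that("squat traces round-trip through CSV", {
  tr <- fast_trace()
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  rt <- read_trace_csv(f)
  expect_true(all(c("t", "FE", "VV", "IE", "AP", "ML", "IS",
                    "F_ankle", "F_quad") %in% names(rt)))
  expect_equal(rt$IE, tr$IE, tolerance = 1e-12)
  expect_true(any(grepl("^eps_", names(rt))))
})
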