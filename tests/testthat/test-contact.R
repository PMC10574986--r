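test_that("contact parameter and patch invariants are enforced", {
  p <- contact_params()
  expect_equal(p$kc, 5000)
  expect_equal(p$tau, 2.2)
  expect_equal(p$Cc, 10)
  expect_error(contact_params(kc = 0), "kc")
  expect_error(contact_params(tau = 0.5), "tau")
  expect_error(contact_params(Cc = -1), "Cc")
  expect_error(contact_patch(depth = -0.1), "depth")
  expect_error(contact_patch(depth = 1, normal = c(1, 1, 0)), "unit")
})

test_that("the compliant law reproduces closed-form magnitudes", {
  prm <- contact_params()
  expect_equal(contact_force(contact_patch(1), prm)$magnitude, 5000)
  expect_equal(contact_force(contact_patch(0), prm)$magnitude, 0)
  expect_equal(contact_force(contact_patch(0.5), prm)$magnitude,
               5000 * 0.5^2.2, tolerance = 1e-12)   # ~1088.2 N
  ## damping term, and the no-adhesion clamp on separation
  expect_equal(contact_force(contact_patch(0.5, rate = 2), prm)$magnitude,
               5000 * 0.5^2.2 + 20, tolerance = 1e-12)
  expect_equal(contact_force(contact_patch(0.01, rate = -1e5), prm)$magnitude, 0)
})

test_that("contact force pairs are equal and opposite", {
  p <- contact_patch(0.3, normal = c(0, 0.6, 0.8))
  f <- contact_force(p, contact_params())
  expect_equal(f$on_first + f$on_second, c(0, 0, 0))
  expect_equal(sqrt(sum(f$on_first^2)), f$magnitude)
})

test_that("the elastic term is strictly increasing and conservative", {
  prm <- contact_params(Cc = 0)
  d <- seq(1e-4, 2, length.out = 200)
  f <- vapply(d, function(x) contact_force(contact_patch(x), prm)$magnitude,
              numeric(1))
  expect_true(all(diff(f) > 0))
  expect_lt(f[1], 1e-4 * 5000)           # force -> 0 as depth -> 0+
  ## loading and unloading forces coincide at equal depth (no damping)
  load_path <- vapply(c(0.1, 0.5, 1, 0.5, 0.1), function(x)
    contact_force(contact_patch(x), prm)$magnitude, numeric(1))
  expect_equal(load_path[2], load_path[4])
  expect_equal(load_path[1], load_path[5])
})

test_that("detect_contacts resolves the analytic pairs of the knee", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  ## generated full extension: everything exactly touching, nothing inside
  expect_length(detect_contacts(m), 0L)
  ## push the femur 1 mm down: both dishes engage at depth ~1
  poses <- m$poses
  poses$femur <- rigid_pose(poses$femur$rotation,
                            poses$femur$translation + c(0, 0, -1))
  patches <- detect_contacts(m, poses)
  dish <- Filter(function(p) grepl("condyle", p$pair[1]), patches)
  expect_length(dish, 2L)
  for (p in dish) expect_equal(p$depth, 1, tolerance = 1e-9)
  ## static bodies: zero overlap rate
  rates <- vapply(detect_contacts(m, poses, prev_poses = poses, dt = 0.1),
                  `[[`, numeric(1), "rate")
  expect_true(all(rates == 0))
})

test_that("sphere-in-dish penetration matches the closed form", {
  ## sphere r 20 whose centre sits 19 mm above the bottom of a dish of
  ## radius 20 (concentric axis): centre-to-centre distance 1, depth 1
  hit <- kneesim:::sphere_in_dish_depth(cs = c(0, 0, 19), cd = c(0, 0, 20),
                                        rs = 20, rd = 20,
                                        down_axis = c(0, 0, -1))
  expect_equal(hit$depth, 1, tolerance = 1e-12)
  ## separated: sphere strictly inside the dish clearance
  expect_null(kneesim:::sphere_in_dish_depth(c(0, 0, 19.5), c(0, 0, 20),
                                             18, 20, c(0, 0, -1)))
})
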