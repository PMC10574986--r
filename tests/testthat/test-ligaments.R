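test_that("strain and zero-load length follow their defining relations", {
  expect_equal(strain(50, 50), 0)
  expect_equal(strain(51.5, 50), 0.03)
  expect_equal(strain(45, 50), -0.10)        # slack is negative, allowed
  expect_error(strain(50, 0), "L0")
  expect_equal(zero_load_length(52, 0.04), 50)
  expect_equal(zero_load_length(47.3, 0), 47.3)
  expect_error(zero_load_length(50, -1), "reference strain")
  ## algebraic closure of the two relations over a grid
  for (Lr in c(30, 47.5, 60, 120))
    for (er in c(-0.25, -0.05, 0, 0.04, 0.08, 0.3))
      expect_equal(strain(Lr, zero_load_length(Lr, er)), er, tolerance = 1e-12)
})

test_that("the tensile force law evaluates its three branches", {
  expect_equal(tensile_force(-0.05, k = 1000), 0)
  expect_equal(tensile_force(0.06, k = 400, eps_l = 0.03), 12)   # toe endpoint
  expect_equal(tensile_force(0.10, k = 400, eps_l = 0.03), 28)   # linear branch
  expect_error(tensile_force(0.1, k = -5), "k")
  expect_error(tensile_force(0.1, k = 5, eps_l = 0), "strain limit")
})

test_that("the force law is C0/C1 continuous at twice the linear limit", {
  for (k in c(50, 400, 650, 6000, 25000)) {
    for (el in c(0.01, 0.03, 0.08)) {
      eps <- 2 * el
      below <- tensile_force(eps - 1e-9, k, el)
      above <- tensile_force(eps + 1e-9, k, el)
      expect_equal(below, k * el, tolerance = 1e-6)
      expect_lt(abs(above - below), k * 1e-8)
      ## derivative from both sides equals k
      d_lo <- (tensile_force(eps, k, el) - tensile_force(eps - 1e-7, k, el)) / 1e-7
      d_hi <- (tensile_force(eps + 1e-7, k, el) - tensile_force(eps, k, el)) / 1e-7
      expect_equal(d_lo, k, tolerance = 1e-4)
      expect_equal(d_hi, k, tolerance = 1e-4)
    }
  }
})

test_that("tensile force is monotone in strain and linear in stiffness", {
  eps <- seq(-0.05, 0.2, by = 0.001)
  f <- tensile_force(eps, 400)
  expect_true(all(diff(f) >= 0))
  expect_equal(tensile_force(eps, 800), 2 * tensile_force(eps, 400))
})

test_that("bundle wrenches act along the attachment line as Newton pairs", {
  poses <- list(femur = rigid_pose(), tibia = rigid_pose())
  mk <- function(o, i, Lr, er = 0)
    ligament_bundle("b", "B", "femur", o, "tibia", i, k = 400, eps_r = er,
                    Lr = Lr)
  ## slack: current length 40 < L0 = 50
  w <- bundle_wrench(poses, mk(c(0, 0, 0), c(0, 0, 40), Lr = 50))
  expect_equal(w$force, 0)
  expect_equal(w$on_origin, c(0, 0, 0))
  ## taut along +z, toe endpoint force 12 N: eps 0.06 at L0 = 50 -> L = 53
  w <- bundle_wrench(poses, mk(c(0, 0, 0), c(0, 0, 53), Lr = 50))
  expect_equal(w$force, 12, tolerance = 1e-12)
  expect_equal(w$on_origin, c(0, 0, 12))       # origin pulled towards insertion
  expect_equal(w$on_insertion, c(0, 0, -12))
  ## action-reaction over seeded random configurations
  set.seed(99)
  for (i in 1:100) {
    b <- mk(runif(3, -30, 30), runif(3, -30, 30), Lr = runif(1, 20, 60),
            er = runif(1, -0.1, 0.1))
    w <- bundle_wrench(poses, b)
    expect_equal(w$on_origin + w$on_insertion, c(0, 0, 0))
  }
  expect_error(bundle_wrench(poses, mk(c(1, 2, 3), c(1, 2, 3), Lr = 10)),
               "coincident")
})

test_that("passive quadriceps force is exponential in the excursion", {
  expect_equal(passive_quadriceps_force(0, alpha = 85, beta = 0.05), 85)
  expect_equal(passive_quadriceps_force(123, alpha = 0, beta = 0.05), 0)
  x <- seq(-50, 50, by = 1)
  f <- passive_quadriceps_force(x, alpha = 32.5, beta = 0.05)
  expect_true(all(diff(f) > 0))
  expect_error(passive_quadriceps_force(0, alpha = -1, beta = 0.05), "alpha")
})
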