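test_that("strain differences summarize bundle-averaged strain gaps", {
  tr <- fast_trace()
  expect_equal(strain_difference(tr, tr, "MCL"), 0)
  ## constructed uniform offset on both MCL bundles
  off <- tr
  off$eps_MCL_a <- off$eps_MCL_a + 0.0027
  off$eps_MCL_p <- off$eps_MCL_p + 0.0027
  expect_equal(strain_difference(tr, off, "MCL"), 0.0027, tolerance = 1e-12)
  ## order-statistics property: max summary dominates the mean summary
  set.seed(5)
  for (i in 1:10) {
    jit <- tr
    jit$eps_MCL_a <- jit$eps_MCL_a + rnorm(nrow(tr), sd = 1e-3)
    expect_gte(strain_difference(tr, jit, "MCL", "max"),
               strain_difference(tr, jit, "MCL", "mean"))
  }
  expect_error(strain_difference(tr, tr, "ALL"), "absent")
})

test_that("kinematic differences are per-DOF means and SDs of opt - pert", {
  tr <- fast_trace()
  d0 <- kinematic_difference(tr, tr)
  expect_true(all(d0$mean == 0) && all(d0$sd == 0))
  expect_false("FE" %in% d0$dof)             # flexion is the drive DOF
  pert <- tr
  pert$IE <- pert$IE - 1.0
  d1 <- kinematic_difference(tr, pert)
  expect_equal(d1$mean[d1$dof == "IE"], 1.0)
  expect_equal(d1$sd[d1$dof == "IE"], 0)
  ## 5-sample toy trace against direct arithmetic
  toy_a <- data.frame(FE = 1:5, VV = c(1, 2, 3, 2, 1), IE = rep(0, 5),
                      AP = 1:5, ML = rep(2, 5), IS = 5:1)
  toy_b <- data.frame(FE = 1:5, VV = rep(0, 5), IE = c(1, 0, -1, 0, 1),
                      AP = rep(3, 5), ML = rep(2, 5), IS = rep(3, 5))
  d <- kinematic_difference(toy_a, toy_b)
  expect_equal(d$mean[d$dof == "VV"], mean(c(1, 2, 3, 2, 1)))
  expect_equal(d$sd[d$dof == "IE"], stats::sd(-c(1, 0, -1, 0, 1)))
  expect_equal(d$mean[d$dof == "AP"], mean(1:5 - 3))
})

test_that("an always-slack LCL yields the sentinel and a bit-identical trace", {
  m <- slack_lcl_model()
  pr <- fast_protocol()
  tr0 <- run_squat(m, pr)
  expect_false(ligament_active(tr0, "LCL"))
  expect_true(all(tr0$eps_LCL < 0))
  ## stiffness perturbation of a slack ligament changes nothing at all
  tr2 <- run_squat(scale_ligament_k(m, "LCL", 3), pr)
  expect_identical(as.data.frame(tr0), as.data.frame(tr2))
  res <- stiffness_for_strain_error(m, "LCL", strain_error_target("LCL"),
                                    pr, nominal_trace = tr0)
  expect_identical(res$sentinel, "/")
  expect_false(res$active)
})

test_that("sensitivity reports round-trip through JSON", {
  skip_if_not_installed("jsonlite")
  tr <- fast_trace()
  pert <- tr; pert$IE <- pert$IE + 0.3
  rep <- structure(list(
    windows = list(MCL = list(k_low = 300, k_high = 2400, k_nominal = 400,
                              active = TRUE,
                              bound_hit = c(decrease = TRUE, increase = FALSE),
                              achieved = c(decrease = 0.001, increase = 0.0027)),
                   LCL = list(k_low = "/", k_high = "/", active = FALSE)),
    scenarios = list(a = list(arm = "stiffness", ligament = "MCL", k = 2400)),
    differences = list(a = kinematic_difference(tr, pert)),
    curves = list(a = data.frame(FE = tr$FE, dVV = tr$VV - pert$VV,
                                 dIE = tr$IE - pert$IE)),
    us_vs_imp = list()), class = "sensitivity_report")
  f <- withr::local_tempfile(fileext = ".json")
  write_sensitivity_report(rep, f)
  rt <- read_sensitivity_report(f)
  expect_equal(rt$windows$MCL$k_high, 2400)
  expect_equal(rt$windows$LCL$k_low, "/")
  expect_equal(rt$differences$a$mean, rep$differences$a$mean, tolerance = 1e-12)
  expect_equal(rt$curves$a$dIE, rep$curves$a$dIE, tolerance = 1e-12)
})
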