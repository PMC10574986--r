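# The pipeline driver is exercised at reduced problem size: coarse cycle,
# single squat pass, one-parameter calibration, no line-search depth.

tiny_cfg <- function(out_dir, study = NULL, calibration = NULL) {
  run_config(
    seed = 7L, out_dir = out_dir,
    protocol = squat_protocol(cycle_samples = 11L, cycles = 1L, duration = 2),
    calibration = calibration,
    study = study, log_level = "quiet")
}

test_that("the pipeline emits a manifest consistent with the filesystem", {
  d <- withr::local_tempdir()
  man <- run_full_protocol(tiny_cfg(
    d,
    calibration = list(perturb = list(MCL = 1.5),
                       spec = calibration_spec(list(
                         list(ligament = "MCL", what = "k",
                              lower = 200, upper = 900)),
                         max_cycles = 1L, line_evals = 4L)),
    study = list(targets = list(), implant_angles = c(3.2),
                 directions = "increase")))
  expect_equal(man$stages$generate, "completed")
  expect_equal(man$stages$squat, "completed")
  expect_equal(man$stages$calibrate, "completed")
  expect_equal(man$stages$sensitivity, "completed")
  for (f in man$files) expect_true(file.exists(file.path(d, f)))
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_equal(man$seed, 7L)
  expect_match(man$config_hash, "^[0-9a-f]{8}$")
})

test_that("omitting stages marks them skipped and stops the chain there", {
  d <- withr::local_tempdir()
  man <- run_full_protocol(tiny_cfg(d))
  expect_equal(man$stages$calibrate, "skipped")
  expect_equal(man$stages$sensitivity, "skipped")
  expect_false(file.exists(file.path(d, "sensitivity.json")))
  expect_true(file.exists(file.path(d, "reference_trace.csv")))
})

test_that("identical configurations reproduce byte-identical artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_full_protocol(tiny_cfg(d1))
  run_full_protocol(tiny_cfg(d2))
  for (f in c("reference_trace.csv", "model/model.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})
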