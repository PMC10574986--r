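test_that("generation is bit-identical under a fixed seed", {
  a <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  b <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  expect_identical(a$bodies$femur$mesh$vertices, b$bodies$femur$mesh$vertices)
  expect_identical(lapply(a$bundles, `[[`, "origin_pt"),
                   lapply(b$bundles, `[[`, "origin_pt"))
  c_ <- generate_synthetic_knee(synthetic_knee_params(seed = 8))
  expect_false(identical(a$bundles$MCL_a$origin_pt, c_$bundles$MCL_a$origin_pt))
})

test_that("the default model carries the full bundle complement", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  expect_length(m$bundles, 8L)                       # 2 MCL + 1 LCL + MPFL + LPFL + 3 patellar
  ligs <- vapply(m$bundles, `[[`, character(1), "ligament")
  expect_equal(sum(ligs == "MCL"), 2L)
  expect_equal(sum(ligs == "LCL"), 1L)
  expect_equal(sum(ligs == "patellar"), 3L)
  expect_length(m$actuators$quadriceps$bundles, 3L)
  expect_length(m$actuators$hamstrings$bundles, 2L)
})

test_that("generated full-extension pose has zero insert-condyle interpenetration", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  expect_lte(insert_condyle_penetration(m), 1e-9)
})

test_that("invalid parameters fail naming the offending field", {
  expect_error(synthetic_knee_params(condyle_spacing = -1), "condyle_spacing")
  expect_error(synthetic_knee_params(insert_dish_radii = c(medial = 10, lateral = 21)),
               "insert_dish_radii")
  expect_error(synthetic_knee_params(bone_segment_lengths = c(femur = 0, tibia = 280)),
               "bone_segment_lengths")
})

test_that("all body and implant meshes are watertight", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  for (b in m$bodies) expect_true(mesh_is_watertight(b$mesh))
  for (p in c("femoral_component", "tibial_baseplate", "insert"))
    expect_true(mesh_is_watertight(m$implant[[p]]$mesh))
})

test_that("attachment sites lie within 5 mm of their host surface", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  for (b in m$bundles) {
    expect_lte(kneesim:::attachment_surface_distance(m, b$origin_body, b$origin_pt), 5)
    expect_lte(kneesim:::attachment_surface_distance(m, b$insertion_body, b$insertion_pt), 5)
  }
})

test_that("implant IE rotation is a group action about the tibial long axis", {
  m <- generate_synthetic_knee(synthetic_knee_params(seed = 7))
  expect_identical(apply_implant_ie_rotation(m, 0), m)     # identity
  back <- apply_implant_ie_rotation(apply_implant_ie_rotation(m, 3.2), -3.2)
  expect_lt(max(abs(unlist(back$primitives$dish_center) -
                    unlist(m$primitives$dish_center))), 1e-9)
  expect_lt(max(abs(back$implant$insert$pose$rotation - diag(3))), 1e-9)
  ## composition adds
  two <- apply_implant_ie_rotation(apply_implant_ie_rotation(m, 1.5), 1.7)
  one <- apply_implant_ie_rotation(m, 3.2)
  expect_lt(max(abs(unlist(two$primitives$post_base) -
                    unlist(one$primitives$post_base))), 1e-9)
  ## distance to the long axis preserved; femur untouched
  r0 <- sqrt(sum(m$primitives$dish_center$medial[1:2]^2))
  r1 <- sqrt(sum(one$primitives$dish_center$medial[1:2]^2))
  expect_equal(r1, r0, tolerance = 1e-12)
  expect_identical(one$bodies$femur$mesh, m$bodies$femur$mesh)
  expect_identical(one$bundles, m$bundles)
  expect_error(apply_implant_ie_rotation(m, 20), "15")
})

test_that("parameter YAML and model directory round trips work", {
  p <- synthetic_knee_params(seed = 11, condyle_spacing = 46)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_knee_params(p, f)
  p2 <- read_knee_params(f)
  expect_equal(p2$condyle_spacing, 46)
  expect_equal(p2$seed, 11L)
  m <- generate_synthetic_knee(p)
  d <- withr::local_tempdir()
  write_knee_model(m, d)
  expect_true(file.exists(file.path(d, "model.json")))
  expect_true(file.exists(file.path(d, "femur.stl")))
  rt <- read_stl(file.path(d, "insert.stl"))
  expect_equal(nrow(rt$faces), nrow(m$implant$insert$mesh$faces))
})
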