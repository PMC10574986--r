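test_that("STL write/read round trip preserves triangles and vertices", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, f)
  rt <- read_stl(f)
  expect_equal(nrow(rt$faces), 12L)
  expect_equal(kneesim:::mesh_canonical_soup(rt),
               kneesim:::mesh_canonical_soup(cube))
})

test_that("ASCII and binary STL encode the same triangle soup", {
  m <- mesh_sphere(c(1, -2, 3), 7.5, 10)
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, fb, ascii = FALSE)
  write_stl(m, fa, ascii = TRUE)
  expect_equal(kneesim:::mesh_canonical_soup(read_stl(fb)),
               kneesim:::mesh_canonical_soup(read_stl(fa)))
})

test_that("malformed STL files raise format errors with byte offsets", {
  f <- withr::local_tempfile(fileext = ".stl")
  file.create(f)
  expect_error(read_stl(f), "byte 0.*empty")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 zap", "    endloop", "  endfacet",
               "endsolid x"), f)
  expect_error(read_stl(f), "format error at byte")
  ## truncated binary: header claims more triangles than the file holds
  con <- file(f, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4L, endian = "little")
  writeBin(raw(10), con)
  close(con)
  expect_error(read_stl(f), "format error")
})

test_that("tessellated primitives are watertight with outward normals", {
  vol <- function(m) {
    v <- m$vertices; f <- m$faces
    s <- 0
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
      s <- s + sum(a * kneesim:::pracma_cross(b, c_)) / 6
    }
    s
  }
  box <- mesh_box(c(-1, -2, -3), c(2, 1, 0))
  expect_true(mesh_is_watertight(box))
  expect_equal(vol(box), 27)
  cyl <- mesh_cylinder(c(0, 0, 0), c(0, 0, 1), 4, 2, 64)
  expect_true(mesh_is_watertight(cyl))
  expect_equal(vol(cyl), pi * 4 * 4, tolerance = 0.01)
  sph <- mesh_sphere(c(5, 5, 5), 3, 48)
  expect_true(mesh_is_watertight(sph))
  expect_equal(vol(sph), 4 / 3 * pi * 27, tolerance = 0.01)
  hf <- kneesim:::mesh_heightfield(0:4, 0:3, function(x, y) 2, 0)
  expect_true(mesh_is_watertight(hf))
  expect_equal(vol(hf), 4 * 3 * 2)
})
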