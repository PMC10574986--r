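#' Triangle meshes
#'
#' Meshes are stored as a list with `vertices` (n x 3 numeric, mm) and
#' `faces` (m x 3 integer, 1-based, counter-clockwise when viewed from
#' outside). A mesh may contain several closed shells (e.g. a bone shaft
#' plus a condylar block); watertightness is checked per edge: every edge
#' must be shared by exactly two faces with opposite winding.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix, 1-based.
#' @return An object of class `knee_mesh`.
#' @export
knee_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("knee_mesh: vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("knee_mesh: face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "knee_mesh")
}

#' @export
print.knee_mesh <- function(x, ...) {
  cat(sprintf("knee_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a mesh is watertight with consistent winding
#'
#' @param mesh a [knee_mesh()].
#' @return `TRUE` if every directed edge is matched by exactly one
#'   opposite directed edge (closed, orientable, consistently wound).
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  fwd <- paste(from, to)
  rev <- paste(to, from)
  if (anyDuplicated(fwd) > 0L) return(FALSE)
  all(fwd %in% rev)
}

## --- tessellated primitives (closed shells) ------------------------------

#' Tessellated primitive shells
#'
#' Closed, consistently wound triangle meshes of elementary solids:
#' UV sphere, capped cylinder, axis-aligned box.
#'
#' @param center,radius sphere centre (mm) and radius.
#' @param a cylinder base-cap centre.
#' @param axis cylinder axis direction (normalized internally).
#' @param length,n_seg cylinder length and segments per revolution.
#' @param lo,hi opposite box corners.
#' @return A [knee_mesh()].
#' @name mesh_primitives
NULL

#' @rdname mesh_primitives
#' @export
mesh_sphere <- function(center, radius, n_seg = 16L) {
  n_seg <- max(6L, as.integer(n_seg))
  n_ring <- max(3L, n_seg %/% 2L)
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ph <- seq(0, pi, length.out = n_ring + 1L)
  ## poles + interior rings
  verts <- rbind(c(0, 0, radius))
  for (i in seq_len(n_ring - 1L)) {
    p <- ph[i + 1L]
    verts <- rbind(verts, cbind(radius * sin(p) * cos(th),
                                radius * sin(p) * sin(th),
                                radius * cos(p)))
  }
  verts <- rbind(verts, c(0, 0, -radius))
  idx <- function(ring, k) 1L + (ring - 1L) * n_seg + ((k - 1L) %% n_seg) + 1L
  faces <- NULL
  for (k in seq_len(n_seg))            # top cap
    faces <- rbind(faces, c(1L, idx(1L, k), idx(1L, k + 1L)))
  if (n_ring > 2L) for (r in seq_len(n_ring - 2L)) for (k in seq_len(n_seg)) {
    a <- idx(r, k); b <- idx(r, k + 1L); c_ <- idx(r + 1L, k); d <- idx(r + 1L, k + 1L)
    faces <- rbind(faces, c(a, c_, d), c(a, d, b))
  }
  bot <- nrow(verts)
  for (k in seq_len(n_seg))            # bottom cap
    faces <- rbind(faces, c(bot, idx(n_ring - 1L, k + 1L), idx(n_ring - 1L, k)))
  knee_mesh(sweep(verts, 2, center, "+"), faces)
}

#' @rdname mesh_primitives
#' @export
mesh_cylinder <- function(a, axis, length, radius, n_seg = 16L) {
  n_seg <- max(6L, as.integer(n_seg))
  u <- unitize(axis, "cylinder axis")
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitize(pracma_cross(ref, u)); e2 <- pracma_cross(u, e1)
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring <- t(vapply(th, function(t) radius * (cos(t) * e1 + sin(t) * e2),
                   numeric(3)))
  b <- a + length * u
  verts <- rbind(sweep(ring, 2, a, "+"), sweep(ring, 2, b, "+"), a, b)
  ia <- seq_len(n_seg); ib <- n_seg + ia
  ca <- 2L * n_seg + 1L; cb <- 2L * n_seg + 2L
  nx <- function(k) ((k %% n_seg) + 1L)
  faces <- NULL
  for (k in seq_len(n_seg)) {
    faces <- rbind(faces,
                   c(ia[k], ia[nx(k)], ib[nx(k)]),
                   c(ia[k], ib[nx(k)], ib[k]),
                   c(ca, ia[nx(k)], ia[k]),       # bottom cap (normal -u)
                   c(cb, ib[k], ib[nx(k)]))       # top cap (normal +u)
  }
  knee_mesh(verts, faces)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname mesh_primitives
#' @export
mesh_box <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]),
                             y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  ## corner order from expand.grid: x fastest
  q <- rbind(
    c(1, 2, 4, 3),  # z = lo (viewed from below must wind CW in xy)
    c(5, 7, 8, 6),  # z = hi
    c(1, 5, 6, 2),  # y = lo
    c(3, 4, 8, 7),  # y = hi
    c(1, 3, 7, 5),  # x = lo
    c(2, 6, 8, 4))  # x = hi
  faces <- NULL
  for (i in seq_len(nrow(q)))
    faces <- rbind(faces, q[i, c(1, 3, 2)], q[i, c(1, 4, 3)])
  knee_mesh(v, faces)
}

## merge several meshes into one multi-shell mesh
mesh_union <- function(...) {
  parts <- list(...)
  verts <- NULL; faces <- NULL; off <- 0L
  for (m in parts) {
    verts <- rbind(verts, m$vertices)
    faces <- rbind(faces, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  knee_mesh(verts, faces)
}

## closed height-field box: top surface z = zfun(x, y) sampled on the given
## grid lines, flat bottom at z0, vertical skirt. Used for the tibial
## insert (dished top surface).
mesh_heightfield <- function(xs, ys, zfun, z0) {
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(x = xs, y = ys)
  zt <- mapply(zfun, g$x, g$y)
  top <- cbind(g$x, g$y, zt)
  bot <- cbind(g$x, g$y, z0)
  verts <- rbind(top, bot)
  id <- function(i, j) (j - 1L) * nx + i          # top sheet
  idb <- function(i, j) nx * ny + id(i, j)        # bottom sheet
  faces <- NULL
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i, j + 1L); d <- id(i + 1L, j + 1L)
    faces <- rbind(faces, c(a, b, d), c(a, d, c_))            # top, +z out
    a2 <- idb(i, j); b2 <- idb(i + 1L, j); c2 <- idb(i, j + 1L); d2 <- idb(i + 1L, j + 1L)
    faces <- rbind(faces, c(a2, d2, b2), c(a2, c2, d2))       # bottom, -z out
  }
  for (i in seq_len(nx - 1L)) {                               # y = min / max walls
    faces <- rbind(faces,
                   c(id(i, 1L), idb(i, 1L), idb(i + 1L, 1L)),
                   c(id(i, 1L), idb(i + 1L, 1L), id(i + 1L, 1L)),
                   c(id(i, ny), idb(i + 1L, ny), idb(i, ny)),
                   c(id(i, ny), id(i + 1L, ny), idb(i + 1L, ny)))
  }
  for (j in seq_len(ny - 1L)) {                               # x = min / max walls
    faces <- rbind(faces,
                   c(id(1L, j), idb(1L, j + 1L), idb(1L, j)),
                   c(id(1L, j), id(1L, j + 1L), idb(1L, j + 1L)),
                   c(id(nx, j), idb(nx, j), idb(nx, j + 1L)),
                   c(id(nx, j), idb(nx, j + 1L), id(nx, j + 1L)))
  }
  knee_mesh(verts, faces)
}

## --- STL input/output ----------------------------------------------------

#' Read and write STL files
#'
#' `write_stl()` writes a mesh as either binary (default) or ASCII STL;
#' `read_stl()` auto-detects the encoding. STL stores a triangle soup in
#' single precision, so a write/read round trip preserves vertex
#' coordinates to single-float precision and the triangle count exactly.
#'
#' @param path file path.
#' @param mesh a [knee_mesh()].
#' @param ascii write ASCII STL instead of binary.
#' @return `read_stl()` returns a [knee_mesh()] with one vertex per
#'   triangle corner (soup); `write_stl()` returns `path` invisibly.
#' @examples
#' m <- mesh_box(c(0, 0, 0), c(1, 1, 1))
#' f <- tempfile(fileext = ".stl")
#' write_stl(m, f)
#' read_stl(f)
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("read_stl: no such file: ", path)
  sz <- file.size(path)
  if (sz == 0) stop("read_stl: format error at byte 0: empty file")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 80L))
  is_ascii <- sz >= 6 && identical(rawToChar(head[1:5]), "solid") &&
    !is_binary_stl_size(path)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

is_binary_stl_size <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  !is.na(n) && n >= 0 && sz == 84 + 50 * as.numeric(n)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) stop(sprintf("read_stl: format error at byte %d: truncated binary header", sz))
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (sz != 84 + 50 * as.numeric(n))
    stop(sprintf("read_stl: format error at byte 80: triangle count %d inconsistent with file size %d", n, sz))
  if (n == 0L) return(knee_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  raw <- readBin(con, "raw", n = 50L * n)
  m <- matrix(raw, nrow = 50L)
  tri_raw <- as.raw(m[1:48, , drop = FALSE])
  vals <- readBin(as.raw(tri_raw), "double", n = 12L * n, size = 4L,
                  endian = "little")
  vm <- matrix(vals, ncol = 12L, byrow = TRUE)   # nx ny nz v1 v2 v3
  verts <- matrix(t(vm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  knee_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  byte_off <- cumsum(c(0L, nchar(lines, type = "bytes") + 1L))
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L)
    stop("read_stl: format error at byte 0: no vertices in ASCII STL")
  if (length(vl) %% 3L != 0L)
    stop(sprintf("read_stl: format error at byte %d: vertex count not a multiple of 3",
                 byte_off[vl[length(vl)]]))
  coords <- matrix(NA_real_, length(vl), 3L)
  for (i in seq_along(vl)) {
    tok <- strsplit(trimws(lines[vl[i]]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (length(tok) < 4L || anyNA(v))
      stop(sprintf("read_stl: format error at byte %d: malformed vertex line",
                   byte_off[vl[i]]))
    coords[i, ] <- v
  }
  n <- length(vl) %/% 3L
  knee_mesh(coords, matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE))
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "knee_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    e1 <- v[f[i, 2], ] - v[f[i, 1], ]
    e2 <- v[f[i, 3], ] - v[f[i, 1], ]
    nm <- pracma_cross(e1, e2)
    L <- sqrt(sum(nm^2))
    normals[i, ] <- if (L > 1e-14) nm / L else c(0, 0, 1)
  }
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid kneesim", con)
    for (i in seq_len(n)) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e", normals[i, 1],
                         normals[i, 2], normals[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %.9e %.9e %.9e",
                           v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid kneesim", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    hdr <- charToRaw(formatC("kneesim binary STL", width = -80))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(normals[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
               con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

## canonical triangle-soup representation: per-triangle sorted-by-vertex
## rows, then lexicographically sorted; used to compare encodings
mesh_canonical_soup <- function(mesh, digits = 5) {
  v <- mesh$vertices; f <- mesh$faces
  tri <- t(apply(f, 1, function(idx) {
    pts <- round(v[idx, , drop = FALSE], digits)
    ord <- do.call(order, as.data.frame(pts))
    as.numeric(t(pts[ord, ]))
  }))
  tri[do.call(order, as.data.frame(tri)), , drop = FALSE]
}
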