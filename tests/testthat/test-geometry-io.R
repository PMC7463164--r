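test_that("hand-written PLY round-trips and preserves vertex order", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 1",
               "3 0 1 2", "3 0 2 3"), f)
  m <- read_mesh(f, frame = "MNI")
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 2)
  expect_equal(m$vertices[4, ], c(0, 1, 1))
  f2 <- tempfile(fileext = ".ply")
  write_mesh(m, f2)
  m2 <- read_mesh(f2, frame = "MNI")
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-9)
})

test_that("mesh round-trips on a generated head within 1e-6 mm (PLY and OBJ)", {
  scalp <- make_head(subdiv = 2)$scalp
  for (ext in c(".ply", ".obj")) {
    f <- tempfile(fileext = ext)
    write_mesh(scalp, f)
    m <- read_mesh(f, frame = "MNI")
    expect_lt(max(abs(m$vertices - scalp$vertices)), 1e-6)
    expect_identical(m$faces, scalp$faces)
  }
})

test_that("binary little-endian PLY is readable", {
  f <- tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeBin(as.numeric(c(0, 0, 0, 2, 0, 0, 0, 2, 0)), con, size = 4,
           endian = "little")
  writeBin(as.raw(3), con)
  writeBin(c(0L, 1L, 2L), con, size = 4, endian = "little")
  close(con)
  m <- read_mesh(f, frame = "photo")
  expect_equal(m$vertices[2, 1], 2)
  expect_equal(m$faces, matrix(1:3, 1))
})

test_that("malformed meshes are rejected with informative errors", {
  # quad face
  f <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), f)
  expect_error(read_mesh(f), "only triangles", class = "opto_format_error")
  # out-of-range index
  f2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), f2)
  expect_error(read_mesh(f2), "out-of-range", class = "opto_format_error")
  # zero-area face
  expect_error(
    surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                 rbind(c(1, 2, 3)), "MNI"),
    "zero area", class = "opto_format_error")
  expect_error(read_mesh(tempfile(fileext = ".ply")), "not found",
               class = "opto_format_error")
})

test_that("landmark reader enforces the five-fiducial vocabulary", {
  f <- write_tmp_csv(c("name,x,y,z", "Nasion,0,95,-10", "INION,0,-115,-20",
                       "cz,0,-10,100", "lpa,-80,-15,-40", "rpa,80,-15,-40"))
  lm <- read_landmarks(f)
  expect_s3_class(lm, "landmark_set")
  expect_identical(lm$id, c("nasion", "inion", "cz", "lpa", "rpa"))

  f2 <- write_tmp_csv(c("name,x,y,z", "nasion,0,95,-10", "cz,0,-10,100",
                        "lpa,-80,-15,-40", "rpa,80,-15,-40"))
  expect_error(read_landmarks(f2), "inion", class = "opto_validation_error")

  f3 <- write_tmp_csv(c("name,x,y,z", "nasion,0,95,0", "inion,0,-115,0",
                        "cz,0,-10,0", "lpa,-80,-15,0", "rpa,80,-15,0"))
  expect_error(read_landmarks(f3), "coplanar", class = "opto_validation_error")

  f4 <- write_tmp_csv(c("name,x,y,z", "nasion,0,95,-10", "nasion,0,94,-10",
                        "inion,0,-115,-20", "cz,0,-10,100", "lpa,-80,-15,-40",
                        "rpa,80,-15,-40"))
  expect_error(read_landmarks(f4), "duplicate", class = "opto_validation_error")

  f5 <- write_tmp_csv(c("name,x,y,z", "nasion,0,NOPE,-10", "inion,0,-115,-20",
                        "cz,0,-10,100", "lpa,-80,-15,-40", "rpa,80,-15,-40"))
  expect_error(read_landmarks(f5), "non-numeric", class = "opto_format_error")
})

test_that("optode reader handles the 6+12 cap, empty bodies, duplicates", {
  rows <- c("id,role,x,y,z",
            sprintf("S%d,source,%d,0,0", 1:6, 1:6 * 30),
            sprintf("D%d,detector,%d,28,0", 1:12, 1:12 * 15))
  opt <- read_optodes(write_tmp_csv(rows))
  expect_equal(nrow(opt), 18)
  expect_equal(sum(opt$role == "source"), 6)
  expect_equal(sum(opt$role == "detector"), 12)
  expect_identical(opt$id[1], "S1")  # order preserved

  empty <- read_optodes(write_tmp_csv("id,role,x,y,z"))
  expect_equal(nrow(empty), 0)

  dup <- write_tmp_csv(c("id,role,x,y,z", "S1,source,0,0,0", "S1,source,1,0,0"))
  expect_error(read_optodes(dup), "duplicate", class = "opto_validation_error")

  bad <- write_tmp_csv(c("id,role,x,y,z", "S1,emitter,0,0,0"))
  expect_error(read_optodes(bad), "role", class = "opto_validation_error")
})

test_that("all tabular types round-trip through their writers within 1e-6", {
  lm <- template_landmarks()
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f, frame = "MNI")
  expect_equal(as.data.frame(lm2), as.data.frame(lm), tolerance = 1e-9)

  opt <- make_cap(make_head(subdiv = 2))
  f2 <- tempfile(fileext = ".csv")
  write_optodes(opt, f2)
  opt2 <- read_optodes(f2, frame = "MNI")
  expect_equal(opt2$x, opt$x, tolerance = 1e-6)
  expect_identical(opt2$role, opt$role)

  pts <- point_table(letters[1:3], c(0.1, -2, 3), 1, c(-9, 0, 2), "photo")
  f3 <- tempfile(fileext = ".csv")
  write_points(pts, f3)
  expect_equal(as.data.frame(read_points(f3, "photo")), as.data.frame(pts),
               tolerance = 1e-9)
})

test_that("frame safety: photo/MNI objects refuse to mix", {
  mesh <- square_mesh(frame = "MNI")
  pts <- point_table("p", 0, 0, 1, frame = "photo")
  expect_error(project_to_surface(pts, mesh), "frame mismatch",
               class = "opto_validation_error")
  a <- point_table("p", 0, 0, 0, "photo")
  b <- point_table("p", 0, 0, 0, "MNI")
  expect_error(displacement(a, b), "frame mismatch",
               class = "opto_validation_error")
  expect_error(point_table("p", 1, 2, 3, frame = "scanner"),
               class = "opto_validation_error")
})
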