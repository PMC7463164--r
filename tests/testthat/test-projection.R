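test_that("closest-point projection: exact cases on a simple mesh", {
  mesh <- square_mesh()
  # point coincident with a vertex maps to itself
  at_vertex <- project_to_surface(point_table("v", -1, -1, 0, "MNI"), mesh)
  expect_equal(as.numeric(at_vertex[1, c("x", "y", "z")]), c(-1, -1, 0))
  # foot of perpendicular above the plane
  above <- project_to_surface(point_table("p", 0, 0, 10, "MNI"), mesh)
  expect_equal(as.numeric(above[1, c("x", "y", "z")]), c(0, 0, 0))
  # edge clamping outside the square
  out <- project_to_surface(point_table("q", 5, 0, 3, "MNI"), mesh)
  expect_equal(as.numeric(out[1, c("x", "y", "z")]), c(1, 0, 0))
})

test_that("closest-point projection matches the independent oracle", {
  mesh <- make_head(subdiv = 1)$scalp  # 80 faces is plenty at unit-test scale
  set.seed(31)
  pts <- point_table(as.character(1:40), runif(40, -120, 120),
                     runif(40, -140, 140), runif(40, -120, 120), "MNI")
  proj <- project_to_surface(pts, mesh)
  for (i in seq_len(nrow(pts))) {
    expect_equal(as.numeric(proj[i, c("x", "y", "z")]),
                 oracle_closest_point(as.numeric(pts[i, c("x", "y", "z")]), mesh),
                 tolerance = 1e-9)
  }
})

test_that("projection is idempotent and never beaten by a mesh vertex", {
  mesh <- make_head(subdiv = 1)$scalp
  set.seed(77)
  pts <- point_table(as.character(1:25), runif(25, -150, 150),
                     runif(25, -150, 150), runif(25, -150, 150), "MNI")
  proj <- project_to_surface(pts, mesh)
  proj2 <- project_to_surface(proj, mesh)
  expect_lt(max(abs(pt_mat(proj2) - pt_mat(proj))), 1e-9)
  P <- pt_mat(pts); Q <- pt_mat(proj)
  for (i in seq_len(nrow(P))) {
    dproj <- sqrt(sum((P[i, ] - Q[i, ])^2))
    dvert <- min(sqrt(rowSums(sweep(mesh$vertices, 2, P[i, ])^2)))
    expect_lte(dproj, dvert + 1e-12)
  }
})

test_that("ray-to-centroid lands on the surface; misses are recorded", {
  mesh <- make_head(subdiv = 2)$scalp
  axes <- c(80, 98, 80)
  pts <- point_table(c("a", "b"), c(200, 0), c(0, -250), c(0, 40), "MNI")
  proj <- project_to_surface(pts, mesh, method = "ray-to-centroid")
  expect_equal(nrow(proj), 2)
  # on the ellipsoid surface within facet tolerance
  lvl <- rowSums(sweep(pt_mat(proj)^2, 2, axes^2, "/"))
  expect_true(all(abs(lvl - 1) < 0.05))
  # two small triangles on opposite sides of their joint centroid (origin):
  # a point radially behind triangle 1 hits it; a point on the z axis
  # misses both
  mesh2 <- surface_mesh(rbind(c(8, -1, 5), c(10, 1, 5), c(10, -1, 5),
                              c(-10, -1, -5), c(-8, 1, -5), c(-10, 1, -5)),
                        rbind(c(1, 2, 3), c(4, 5, 6)), "MNI")
  res <- project_to_surface(point_table(c("hit", "miss"),
                                        c(18.66, 0), c(-0.66, 0), c(10, 10),
                                        "MNI"),
                            mesh2, method = "ray-to-centroid")
  failed <- attr(res, "failed")
  expect_equal(failed$id, "miss")
  expect_equal(res$id, "hit")
})

test_that("pair_channels applies the separation band and orders channels", {
  one <- optode_set(c("S1", "D1"), c("source", "detector"),
                    c(0, 28), 0, 0, "MNI")
  ch <- pair_channels(one)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$separation_mm, 28)
  far <- optode_set(c("S1", "D1", "D2"), c("source", "detector", "detector"),
                    c(0, 50, -50), 0, 0, "MNI")
  expect_equal(nrow(pair_channels(far, 28, 0.2)), 0)
  # lexicographic channel numbering
  grid <- optode_set(c("S2", "S1", "D1"), c("source", "source", "detector"),
                     c(28, -28, 0), 0, 0, "MNI")
  ch2 <- pair_channels(grid)
  expect_identical(ch2$source, c("S1", "S2"))
  expect_identical(ch2$channel, 1:2)
})

test_that("enlarging the tolerance never removes channels", {
  cap <- make_cap(make_head(subdiv = 2))
  tols <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  counts <- vapply(tols, function(t_) nrow(pair_channels(cap, 28, t_)), 0L)
  expect_true(all(diff(counts) >= 0))
  keys <- lapply(tols, function(t_) {
    ch <- pair_channels(cap, 28, t_); paste(ch$source, ch$detector)
  })
  for (i in seq_len(length(tols) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
})

test_that("pairing override computes separations for the given pairs", {
  cap <- make_cap(make_head(subdiv = 2))
  ovr <- data.frame(channel = c(10, 20), source = c("S01", "S02"),
                    detector = c("D01", "D02"))
  ch <- pair_channels(cap, pairing = ovr)
  expect_identical(ch$channel, c(10, 20))
  m <- pt_mat(cap)
  expect_equal(ch$separation_mm[1], sqrt(sum((m["S01", ] - m["D01", ])^2)))
  expect_error(pair_channels(cap, pairing = data.frame(
    channel = 1, source = "S99", detector = "D01")), "unknown optode",
    class = "opto_validation_error")
})

test_that("channel midpoints: scalp mean, degenerate pair, sphere cortex", {
  opt <- optode_set(c("S1", "D1"), c("source", "detector"),
                    c(0, 2), 0, 0, "MNI")
  ch <- data.frame(channel = 1, source = "S1", detector = "D1")
  mid <- channel_midpoints(ch, opt, "scalp")
  expect_equal(as.numeric(mid[1, c("x", "y", "z")]), c(1, 0, 0))
  # coincident endpoints give the point itself
  co <- point_table(c("S1", "D1"), 5, -3, 2, "MNI")
  expect_equal(as.numeric(channel_midpoints(ch, co, "scalp")[1, c("x", "y", "z")]),
               c(5, -3, 2))
  # endpoints on a radius-80 sphere, cortical space: midpoint re-projected
  # back to the sphere (within mesh facet sag)
  sphere <- make_head(semi_axes = c(80, 80, 80), subdiv = 3)$scalp
  ang <- pi / 16
  ends <- point_table(c("S1", "D1"),
                      80 * cos(c(-ang, ang)), 80 * sin(c(-ang, ang)), 0, "MNI")
  mid2 <- channel_midpoints(ch, ends, "cortical", cortex = sphere)
  r <- sqrt(sum(as.numeric(mid2[1, c("x", "y", "z")])^2))
  expect_lt(abs(r - 80), 0.5)
  # and exactly on the mesh
  re <- project_to_surface(mid2, sphere)
  expect_lt(max(abs(pt_mat(re) - pt_mat(mid2))), 1e-9)
  # both midpoint orders agree for a symmetric pair
  mid3 <- channel_midpoints(ch, ends, "cortical", cortex = sphere,
                            order = "projected-endpoints")
  expect_lt(max(abs(pt_mat(mid3) - pt_mat(mid2))), 1.0)
  expect_error(channel_midpoints(ch, co, "cortical"), "cortex",
               class = "opto_validation_error")
  expect_error(
    channel_midpoints(data.frame(channel = 1, source = "S9", detector = "D1"),
                      co, "scalp"),
    "lack optode", class = "opto_validation_error")
})
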