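test_that("sphere sampling: containment, n = 1, determinism", {
  s <- sample_sphere_uniform(c(5, -3, 2), r = 7, n = 500, seed = 4)
  m <- pt_mat(s)
  expect_true(all((m[, 1] - 5)^2 + (m[, 2] + 3)^2 + (m[, 3] - 2)^2 <= 49 + 1e-12))
  one <- sample_sphere_uniform(c(0, 0, 0), r = 10, n = 1, seed = 9)
  expect_equal(nrow(one), 1)
  expect_lte(sqrt(sum(pt_mat(one)^2)), 10)
  again <- sample_sphere_uniform(c(5, -3, 2), r = 7, n = 500, seed = 4)
  expect_identical(pt_mat(again), m)
  expect_error(sample_sphere_uniform(c(0, 0, 0), r = -1),
               class = "opto_validation_error")
  expect_error(sample_sphere_uniform(c(0, 0, 0), n = 0),
               class = "opto_validation_error")
})

test_that("mean sampled radius approaches 3r/4", {
  s <- sample_sphere_uniform(c(0, 0, 0), r = 10, n = 20000, seed = 11)
  mean_r <- mean(sqrt(rowSums(pt_mat(s)^2)))
  se <- 10 * sqrt(3 / 80) / sqrt(20000)  # sd(radius) = r*sqrt(3/80)
  expect_lt(abs(mean_r - 7.5), 3 * se)
})

test_that("label lookup: voxel centers, outside points, boundary stability", {
  vol <- array(0L, c(4, 4, 4))
  vol[2, 3, 2] <- 7L
  aff <- rbind(cbind(diag(3) * 2, c(-3, -3, -3)), c(0, 0, 0, 1))
  atlas <- parcellation_atlas(vol, aff, c("7" = "somewhere"))
  # voxel (1,2,1) 0-based -> world (-1, 1, -1)
  expect_equal(label_points(point_table("p", -1, 1, -1, "MNI"), atlas), 7L)
  expect_equal(label_points(point_table("p", 500, 0, 0, "MNI"), atlas), 0L)
  # boundary point: equidistant between voxels, fixed tie rule, stable
  bnd <- point_table("p", 0, 1, -1, "MNI")  # x = 0 between centers -1 and 1
  lab <- replicate(10, label_points(bnd, atlas))
  expect_true(all(lab == lab[1]))
  expect_error(label_points(point_table("p", 0, 0, 0, "photo"), atlas),
               "MNI", class = "opto_validation_error")
})

test_that("atlas invariants are enforced", {
  vol <- array(1L, c(2, 2, 2))
  aff <- diag(4)
  expect_error(parcellation_atlas(vol, aff, c("2" = "wrong id")),
               "without a region name", class = "opto_validation_error")
  expect_error(parcellation_atlas(vol, matrix(0, 4, 4), c("1" = "ok")),
               "invertible", class = "opto_validation_error")
  expect_silent(parcellation_atlas(vol, aff, c("1" = "ok")))
})

test_that("NIfTI atlas round-trips through .nii and .nii.gz", {
  atlas <- make_atlas("voronoi", grid = c(12, 10, 8), spacing = 5,
                      n_regions = 4, seed = 3)
  for (ext in c(".nii", ".nii.gz")) {
    nii <- tempfile(fileext = ext)
    lab <- tempfile(fileext = ".json")
    write_atlas(atlas, nii, lab)
    back <- read_atlas(nii, lab)
    expect_identical(back$labels, atlas$labels)
    expect_equal(unname(back$affine), unname(atlas$affine), tolerance = 1e-6)
    expect_identical(back$names, atlas$names)
  }
})

test_that("region_table: pure, boundary and background geometries", {
  half <- make_atlas("half-spaces")
  # ball wholly inside one label
  pure <- region_table(point_table("c", -30, 0, 0, "MNI"), half,
                       r = 10, n = 2000, seed = 5)
  expect_equal(pure$fraction[pure$region == "left half-space"], 1)
  expect_true(pure$detected[1])
  # ball on the boundary: ~50/50 within 3 binomial SE at n = 10000
  bnd <- region_table(point_table("c", 0, 10, -5, "MNI"), half,
                      r = 10, n = 10000, seed = 6)
  fr <- bnd$fraction[bnd$region == "left half-space"]
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 10000))
  # fractions sum to 1 including background
  expect_equal(sum(bnd$fraction), 1, tolerance = 1e-9)
  # ball wholly in background
  bg <- region_table(point_table("c", 500, 500, 500, "MNI"), half,
                     r = 10, n = 500, seed = 7)
  expect_equal(bg$fraction[bg$region == "<background>"], 1)
  expect_equal(nrow(detected_regions(bg)), 0)
})

test_that("region_table is deterministic per seed and ordered by fraction", {
  atlas <- make_atlas("nested-shells", shell_radii = c(20, 40, 60))
  ch <- point_table(c("ch1", "ch2"), c(15, 0), c(0, 0), c(0, 35), "MNI")
  a <- region_table(ch, atlas, r = 10, n = 4000, seed = 42)
  b <- region_table(ch, atlas, r = 10, n = 4000, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (id in unique(a$channel)) {
    fr <- a$fraction[a$channel == id & a$region != "<background>"]
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("estimated fractions converge to the analytic shell volumes", {
  # ball of radius 10 centred at radius 15: intersects shells [0,20) and [20,40)
  # spherical-cap lens volume of ball r about c cut by sphere R:
  vol_inside <- function(R, r, c_) {
    # intersection volume of ball(r, centre c_) with ball(R, origin), c_ > |R - r|
    if (c_ + r <= R) return(4 / 3 * pi * r^3)
    if (c_ >= R + r) return(0)
    (pi / (12 * c_)) * (R + r - c_)^2 *
      (c_^2 + 2 * c_ * (R + r) - 3 * (R - r)^2)
  }
  r <- 10; c_ <- 15; R <- 20
  frac1 <- vol_inside(R, r, c_) / (4 / 3 * pi * r^3)
  atlas <- make_atlas("nested-shells", grid = c(64, 64, 64), spacing = 2,
                      shell_radii = c(20, 40, 60))
  errs <- vapply(c(1000, 16000), function(n) {
    tab <- region_table(point_table("c", c_, 0, 0, "MNI"), atlas,
                        r = r, n = n, seed = 13)
    abs(tab$fraction[tab$region == "shell 1"] - frac1)
  }, 0)
  se <- sqrt(frac1 * (1 - frac1) / 16000)
  expect_lt(errs[2], 4 * se + 0.01)  # small bias allowance for voxelization
  expect_lt(errs[2], errs[1] + 0.02) # error shrinks with n
})

test_that("normalization over labeled samples only", {
  half <- make_atlas("half-spaces", grid = c(16, 16, 16), spacing = 4)
  # ball partly outside the 64-mm volume: some samples are background
  edge <- point_table("c", 0, 0, 30, "MNI")
  all_n <- region_table(edge, half, r = 10, n = 4000, seed = 8)
  lab_n <- region_table(edge, half, r = 10, n = 4000, seed = 8,
                        normalize = "labeled")
  labeled <- all_n$region != "<background>"
  expect_equal(sum(lab_n$fraction[lab_n$region != "<background>"]), 1,
               tolerance = 1e-9)
  expect_gt(sum(lab_n$fraction), 1)  # background reported against all samples
})
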