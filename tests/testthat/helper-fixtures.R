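# Shared fixtures: all tiny geometry is built in code, no binary files.

pt_mat <- function(p) {
  m <- as.matrix(as.data.frame(p)[, c("x", "y", "z")])
  rownames(m) <- p$id
  m
}

# canonical MNI-ish template fiducials (mm)
template_landmarks <- function(frame = "MNI") {
  landmark_set(point_table(
    c("nasion", "inion", "cz", "lpa", "rpa"),
    x = c(0, 0, 0, -80, 80),
    y = c(95, -115, -10, -15, -15),
    z = c(-10, -20, 100, -40, -40), frame = frame))
}

# random well-conditioned affine: scale in [0.7, 1.4], rotation, shear < 0.2
random_affine <- function(seed, source_frame = "photo", target_frame = "MNI") {
  set.seed(seed)
  repeat {
    A <- diag(runif(1, 0.7, 1.4), 3) %*% random_rotation() +
      matrix(runif(9, -0.2, 0.2), 3, 3)
    if (abs(det(A)) > 1e-3 && kappa(A) < 100) break
  }
  affine_transform(A, runif(3, -50, 50), 0, source_frame, target_frame)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
        c(2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b)),
        c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2))
}

# two-triangle square in the z = 0 plane, spanning [-1, 1]^2
square_mesh <- function(frame = "MNI", scale = 1) {
  surface_mesh(scale * rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)), frame)
}

# independent closest-point oracle: per triangle, candidates are the
# unconstrained plane foot (if inside), the three clamped edge projections,
# and the three vertices; global min over triangles.  Deliberately a
# different formulation from the implementation's region-logic walk.
oracle_closest_point <- function(p, mesh) {
  best <- NULL; bestd <- Inf
  v <- mesh$vertices; f <- mesh$faces
  seg <- function(a, b) {
    t_ <- sum((p - a) * (b - a)) / sum((b - a)^2)
    a + min(max(t_, 0), 1) * (b - a)
  }
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c_ <- v[f[k, 3], ]
    cand <- list(seg(a, b), seg(b, c_), seg(c_, a), a, b, c_)
    # interior foot via barycentric solve
    M <- cbind(b - a, c_ - a)
    st <- solve(crossprod(M), crossprod(M, p - a))
    if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
      cand <- c(cand, list(a + M %*% st))
    }
    for (q in cand) {
      d <- sum((p - q)^2)
      if (d < bestd) { bestd <- d; best <- as.numeric(q) }
    }
  }
  best
}

# Monte-Carlo oracle for equal-sphere overlap: uniform samples in sphere A,
# hit rate inside sphere B at separation d
mc_overlap <- function(d, R, n, seed) {
  s <- sample_sphere_uniform(c(0, 0, 0), r = R, n = n, seed = seed)
  m <- as.matrix(as.data.frame(s)[, c("x", "y", "z")])
  mean((m[, 1] - d)^2 + m[, 2]^2 + m[, 3]^2 <= R^2)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
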