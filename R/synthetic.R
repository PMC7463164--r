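#' Synthetic head: nested ellipsoid scalp and cortex with fiducials
#'
#' Generates a download-free stand-in for a participant head: the scalp is a
#' triangulated ellipsoid (subdivided icosahedron), the cortex the same mesh
#' shrunk toward the origin, and the five fiducials sit at the ellipsoid
#' poles (nasion anterior, inion posterior, Cz apex, lpa/rpa lateral).  The
#' default semi-axes (80, 98, 80) mm give an equatorial circumference of
#' about 56 cm, matching an adult head-band measurement, and a
#' nasion-to-inion arc over the vertex of about half that circumference.
#'
#' @param semi_axes length-3 positive numeric, ellipsoid semi-axes (x, y, z)
#'   in mm
#' @param shrink cortex scale factor in (0,1), default 0.8
#' @param subdiv icosphere subdivision level (default 3: 642 vertices,
#'   1280 faces)
#' @param frame frame tag, default `"MNI"`
#' @return list with elements `scalp`, `cortex` ([surface_mesh()]s),
#'   `landmarks` ([landmark_set()]), `semi_axes`, `shrink`; class
#'   `synthetic_head`
#' @export
make_head <- function(semi_axes = c(80, 98, 80), shrink = 0.8, subdiv = 3,
                      frame = "MNI") {
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    opto_validation_error("semi_axes must be 3 positive numbers")
  }
  if (shrink <= 0 || shrink >= 1) {
    opto_validation_error("cortex shrink factor must be in (0,1)")
  }
  ico <- icosphere(subdiv)
  scalp_v <- sweep(ico$vertices, 2, semi_axes, "*")
  scalp <- surface_mesh(scalp_v, ico$faces, frame)
  cortex <- surface_mesh(scalp_v * shrink, ico$faces, frame)
  a <- semi_axes[1]; b <- semi_axes[2]; c_ <- semi_axes[3]
  lm <- landmark_set(point_table(
    c("nasion", "inion", "cz", "lpa", "rpa"),
    x = c(0, 0, 0, -a, a),
    y = c(b, -b, 0, 0, 0),
    z = c(0, 0, c_, 0, 0), frame = frame))
  structure(list(scalp = scalp, cortex = cortex, landmarks = lm,
                 semi_axes = semi_axes, shrink = shrink),
            class = "synthetic_head")
}

# unit icosphere by repeated 4-way subdivision of an icosahedron
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  list(vertices = v, faces = f)
}

# Planar cap lattice: 3-row hexagonal patch, spacing `sep`, row height
# sep*sqrt(3)/2. For the default 6-source/12-detector cap the role pattern
# is frozen so that exactly 23 source-detector pairs sit at distance `sep`
# (the next-nearest pair is at 1.73*sep, far outside any sane tolerance).
cap_lattice <- function(n_sources = 6, n_detectors = 12, sep = 28) {
  if (n_sources < 1 || n_detectors < 1) {
    opto_validation_error("optode counts must be positive")
  }
  n <- n_sources + n_detectors
  h <- sep * sqrt(3) / 2
  if (n == 18L) {
    nc <- 6L
    u0 <- seq(0, by = sep, length.out = nc)
    u1 <- u0 + sep / 2
    uv <- rbind(cbind(u0, 0), cbind(u1, h), cbind(u0, 2 * h))
    role <- rep("detector", 18L)
    # sources: row0 cols 3,4; row1 cols 1,5; row2 cols 3,4  -> 23 channels
    role[c(3L, 4L, 6L + 1L, 6L + 5L, 12L + 3L, 12L + 4L)] <- "source"
  } else {
    nc <- ceiling(n / 3)
    if (nc > 12L) {
      opto_stop("infeasible packing: too many optodes for the lateral patch",
                "opto_validation_error")
    }
    u0 <- seq(0, by = sep, length.out = nc)
    uv <- rbind(cbind(u0, 0), cbind(u0 + sep / 2, h), cbind(u0, 2 * h))
    uv <- uv[seq_len(n), , drop = FALSE]
    role <- rep("detector", n)
    role[round(seq(1, n, length.out = n_sources))] <- "source"
  }
  nsrc <- cumsum(role == "source")
  ndet <- cumsum(role == "detector")
  id <- ifelse(role == "source", sprintf("S%02d", nsrc), sprintf("D%02d", ndet))
  list(uv = uv, role = role, id = id, sep = sep)
}

#' Synthetic optode cap on the scalp
#'
#' Wraps a planar hexagonal optode lattice (see Details) onto the
#' left-lateral scalp patch of a synthetic head and snaps every optode onto
#' the scalp mesh.  With the defaults (6 sources, 12 detectors, 28 mm
#' spacing) the layout yields exactly 23 source-detector channels under
#' [pair_channels()] at the default tolerance.
#'
#' The wrap maps the lattice's u axis to azimuth along a constant-latitude
#' ring of the ellipsoid (arc length exact on the middle row) and its v axis
#' to latitude offsets measured by meridian arc length, centred over the
#' left side of the head; metric distortion over the roughly 15 x 5 cm
#' patch stays within a few percent, far inside the pairing tolerance.
#'
#' @param head a [make_head()] result
#' @param n_sources,n_detectors optode counts (defaults 6 and 12)
#' @param sep lattice spacing in mm (default 28); this is the nominal
#'   source-detector separation
#' @param z_center latitude (mm, z of the middle lattice row) of the patch
#' @return an [optode_set()] on the scalp mesh, in the head's frame
#' @export
make_cap <- function(head, n_sources = 6, n_detectors = 12, sep = 28,
                     z_center = 25) {
  lat <- cap_lattice(n_sources, n_detectors, sep)
  axes <- head$semi_axes
  a <- axes[1]; b <- axes[2]; c_ <- axes[3]
  if (abs(z_center) >= c_) {
    opto_validation_error("z_center must lie inside the head's z extent")
  }
  vs <- sort(unique(lat$uv[, 2]))
  v_mid <- (min(vs) + max(vs)) / 2
  # meridian (y = 0): (x, z) = (-a sin(phi), c cos(phi)); arc-length table
  phi_grid <- seq(1e-3, pi - 1e-3, length.out = 4000)
  dphi <- diff(phi_grid[1:2])
  spd <- sqrt((a * cos(phi_grid))^2 + (c_ * sin(phi_grid))^2)
  s_grid <- cumsum(spd) * dphi
  phi_c <- acos(z_center / c_)
  s_c <- stats::approx(phi_grid, s_grid, phi_c)$y
  phi_of_v <- function(v) {
    stats::approx(s_grid, phi_grid, s_c + (v - v_mid))$y
  }
  us <- sort(unique(round(lat$uv[, 1], 9)))
  u_mid <- (min(us) + max(us)) / 2
  # centre-row ring: ellipse (A cos t, B sin t); arc-length mapping for u
  k_c <- sin(phi_c)
  t_grid <- seq(0, 2 * pi, length.out = 8000)
  dt <- diff(t_grid[1:2])
  spd_t <- sqrt((a * k_c * sin(t_grid))^2 + (b * k_c * cos(t_grid))^2)
  st_grid <- cumsum(spd_t) * dt
  st_left <- stats::approx(t_grid, st_grid, pi)$y
  t_of_u <- function(u) {
    # u > centre runs anterior (toward +y), i.e. decreasing t from pi
    stats::approx(st_grid, t_grid, st_left - (u - u_mid))$y
  }
  phi <- phi_of_v(lat$uv[, 2])
  if (anyNA(phi)) {
    opto_validation_error("infeasible packing: cap rows run off the head")
  }
  t_ <- t_of_u(lat$uv[, 1])
  if (anyNA(t_)) {
    opto_validation_error("infeasible packing: cap columns wrap past the head")
  }
  k <- sin(phi)
  pts <- cbind(a * k * cos(t_), b * k * sin(t_), c_ * cos(phi))
  raw <- point_table(lat$id, pts[, 1], pts[, 2], pts[, 3],
                     frame_of(head$scalp))
  snapped <- project_to_surface(raw, head$scalp, "closest-point")
  m <- pt_coords(snapped)
  optode_set(lat$id, lat$role, m[, 1], m[, 2], m[, 3], frame_of(head$scalp))
}

#' Session simulation specification
#'
#' Parameters of the multi-participant, three-session experiment the
#' simulator emulates: a pre-MRI photo session, an MRI session whose cap is
#' displaced by the supine shift, and a post-MRI photo session in which the
#' shift has partially recovered.
#'
#' @param n_participants number of participants (default 20, the scale of a
#'   typical validation cohort)
#' @param jitter_sd per-axis cap placement jitter across participants in mm
#'   (applied in the scalp tangent plane; default 3)
#' @param shift length-3 supine shift vector in mm added during the MRI
#'   session (default `c(0, 5, 5)`: forward and upward)
#' @param post_shift_fraction fraction of the shift persisting in the
#'   post-MRI photo session (default 0.5: the cap partly settles back)
#' @param noise_sd per-axis measurement/digitization noise in mm
#'   (default 1)
#' @param true_affine the ground-truth photo-to-MNI [affine_transform()];
#'   default is a mild similarity (scale 1.35 with a small rotation and
#'   offset) standing in for the arbitrary photogrammetric frame
#' @param seed integer seed driving all randomness
#' @return a `session_spec` list
#' @export
session_spec <- function(n_participants = 20, jitter_sd = 3,
                         shift = c(0, 5, 5), post_shift_fraction = 0.5,
                         noise_sd = 1, true_affine = NULL, seed = 1) {
  if (n_participants < 1) opto_validation_error("need at least 1 participant")
  if (jitter_sd < 0 || noise_sd < 0) {
    opto_validation_error("standard deviations must be >= 0")
  }
  if (is.null(true_affine)) {
    ang <- 0.15
    Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
    true_affine <- affine_transform(1.35 * Rz, c(12, -7, 30), 0,
                                    source_frame = "photo",
                                    target_frame = "MNI")
  }
  structure(list(n_participants = as.integer(n_participants),
                 jitter_sd = jitter_sd, shift = as.numeric(shift),
                 post_shift_fraction = post_shift_fraction,
                 noise_sd = noise_sd, true_affine = true_affine,
                 seed = as.integer(seed)),
            class = "session_spec")
}

# tangent-plane jitter on an ellipsoidal scalp: draw isotropic 3-D noise,
# remove the component along the local surface normal, add, re-snap to mesh
jitter_on_scalp <- function(m, sd, head) {
  if (sd == 0) return(m)
  axes <- head$semi_axes
  nrml <- sweep(m, 2, axes^2, "/")
  nrml <- nrml / row_norms(nrml)
  eps <- matrix(stats::rnorm(length(m), sd = sd), ncol = 3)
  eps <- eps - nrml * rowSums(eps * nrml)
  m + eps
}

snap_to_mesh <- function(m, ids, mesh) {
  p <- point_table(ids, m[, 1], m[, 2], m[, 3], frame_of(mesh))
  pt_coords(project_to_surface(p, mesh, "closest-point"))
}

#' Simulate multi-participant registration sessions
#'
#' For each participant the true cap placement is the nominal cap plus
#' tangent-plane jitter, re-snapped to the scalp.  The MRI session adds the
#' supine shift vector before re-snapping; the post-MRI photo session adds
#' `post_shift_fraction` of it.  Photo-session observations are the true
#' MNI positions (optodes and fiducials) carried into the photo frame by
#' the inverse of the ground-truth affine, plus measurement noise; the MRI
#' session observes MNI positions directly, plus noise.
#'
#' @param head a [make_head()] result
#' @param cap an [optode_set()] from [make_cap()] (head's frame)
#' @param spec a [session_spec()]
#' @return a `session_simulation` list:
#'   `observations$por_pre` / `$por_post`: per participant a list with
#'   photo-frame `optodes` and `landmarks`; `observations$mri`: per
#'   participant an MNI [point_table()]; `truth`: per session a
#'   [group_positions()] of true MNI optode positions;
#'   `template_landmarks`: the MNI fiducials; `spec`.
#' @export
simulate_sessions <- function(head, cap, spec = session_spec()) {
  set.seed(spec$seed)
  aff <- spec$true_affine
  inv <- invert_affine(aff)
  scalp <- head$scalp
  ids <- cap$id
  base <- pt_coords(cap)
  lm_mni <- head$landmarks
  lm_photo_true <- apply_affine(inv, lm_mni)
  participants <- sprintf("P%02d", seq_len(spec$n_participants))
  obs_pre <- obs_post <- vector("list", spec$n_participants)
  obs_mri <- truth_pre <- truth_mri <- truth_post <-
    vector("list", spec$n_participants)
  noise <- function(m) m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                                  ncol = 3)
  for (i in seq_len(spec$n_participants)) {
    placed <- snap_to_mesh(jitter_on_scalp(base, spec$jitter_sd, head),
                           ids, scalp)
    mri_true <- snap_to_mesh(sweep(placed, 2, spec$shift, "+"), ids, scalp)
    post_true <- snap_to_mesh(
      sweep(placed, 2, spec$post_shift_fraction * spec$shift, "+"), ids, scalp)
    truth_pre[[i]] <- pt_from_coords(ids, placed, "MNI")
    truth_mri[[i]] <- pt_from_coords(ids, mri_true, "MNI")
    truth_post[[i]] <- pt_from_coords(ids, post_true, "MNI")
    to_photo <- function(m) {
      noise(pt_coords(apply_affine(inv, pt_from_coords(ids, m, "MNI"))))
    }
    obs_pre[[i]] <- list(
      optodes = {
        m <- to_photo(placed)
        optode_set(ids, cap$role, m[, 1], m[, 2], m[, 3], "photo")
      },
      landmarks = landmark_set(pt_from_coords(
        lm_photo_true$id, noise(pt_coords(lm_photo_true)), "photo")))
    obs_post[[i]] <- list(
      optodes = {
        m <- to_photo(post_true)
        optode_set(ids, cap$role, m[, 1], m[, 2], m[, 3], "photo")
      },
      landmarks = landmark_set(pt_from_coords(
        lm_photo_true$id, noise(pt_coords(lm_photo_true)), "photo")))
    obs_mri[[i]] <- pt_from_coords(ids, noise(mri_true), "MNI")
  }
  names(obs_pre) <- names(obs_post) <- names(obs_mri) <- participants
  names(truth_pre) <- names(truth_mri) <- names(truth_post) <- participants
  structure(list(
    observations = list(por_pre = obs_pre, por_post = obs_post, mri = obs_mri),
    truth = list(por_pre = group_positions(truth_pre),
                 mri = group_positions(truth_mri),
                 por_post = group_positions(truth_post)),
    template_landmarks = lm_mni,
    spec = spec), class = "session_simulation")
}

#' Register simulated photo sessions into MNI space
#'
#' Runs the registration stage on a [simulate_sessions()] result: per
#' participant, fits the five-landmark affine from the photo-frame fiducials
#' to the template fiducials and applies it to the photo-frame optodes.
#' MRI observations are already in MNI space and pass through.
#'
#' @param sim a `session_simulation`
#' @return list of [group_positions()] (MNI) named por_pre, mri, por_post
#' @export
register_simulation <- function(sim) {
  reg_one <- function(obs) {
    tr <- fit_affine(obs$landmarks, sim$template_landmarks)
    optode_points(apply_affine(tr, obs$optodes))
  }
  list(
    por_pre = group_positions(lapply(sim$observations$por_pre, reg_one)),
    mri = group_positions(sim$observations$mri),
    por_post = group_positions(lapply(sim$observations$por_post, reg_one)))
}

#' Synthetic parcellation atlases with known geometry
#'
#' Builds label volumes whose region geometry is analytically known, so
#' Monte-Carlo region estimates can be checked against closed-form volumes:
#'
#' * `"half-spaces"`: two labels split by the plane x = 0.
#' * `"nested-shells"`: concentric spherical shells about the origin with
#'   boundaries `shell_radii`.
#' * `"voronoi"`: nearest-seed labels for `n_regions` random seed points
#'   (deterministic per `seed`).
#'
#' @param geometry one of the three geometries above
#' @param grid length-3 integer grid shape (default 32^3)
#' @param spacing voxel size in mm (default 4); the volume is centred on
#'   the origin
#' @param labels optional character vector of region names
#' @param shell_radii outer radii (mm) of the nested shells
#' @param n_regions number of Voronoi regions
#' @param seed seed for the Voronoi geometry
#' @return a [parcellation_atlas()]
#' @export
make_atlas <- function(geometry = c("half-spaces", "nested-shells", "voronoi"),
                       grid = c(32, 32, 32), spacing = 4, labels = NULL,
                       shell_radii = c(20, 40, 60), n_regions = 5, seed = 1) {
  geometry <- match.arg(geometry)
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 2L)) {
    opto_validation_error("grid must be 3 integers >= 2")
  }
  origin <- -(grid - 1) / 2 * spacing
  affine <- rbind(cbind(diag(rep(spacing, 3)), origin), c(0, 0, 0, 1))
  ix <- seq(0, grid[1] - 1); iy <- seq(0, grid[2] - 1); iz <- seq(0, grid[3] - 1)
  wx <- origin[1] + spacing * ix
  wy <- origin[2] + spacing * iy
  wz <- origin[3] + spacing * iz
  if (geometry == "half-spaces") {
    vol <- array(0L, grid)
    vol[wx < 0, , ] <- 1L
    vol[wx >= 0, , ] <- 2L
    if (is.null(labels)) labels <- c("left half-space", "right half-space")
  } else if (geometry == "nested-shells") {
    r2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
    vol <- array(0L, grid)
    bounds <- c(0, shell_radii)
    for (k in seq_along(shell_radii)) {
      vol[r2 >= bounds[k]^2 & r2 < bounds[k + 1]^2] <- k
    }
    if (is.null(labels)) labels <- sprintf("shell %d", seq_along(shell_radii))
  } else {
    set.seed(as.integer(seed))
    ext <- (grid - 1) * spacing / 2
    seeds <- cbind(stats::runif(n_regions, -ext[1], ext[1]),
                   stats::runif(n_regions, -ext[2], ext[2]),
                   stats::runif(n_regions, -ext[3], ext[3]))
    pts <- as.matrix(expand.grid(x = wx, y = wy, z = wz))
    d2 <- sapply(seq_len(n_regions), function(k) {
      rowSums(sweep(pts, 2, seeds[k, ])^2)
    })
    vol <- array(max.col(-d2, ties.method = "first"), grid)
    if (is.null(labels)) labels <- sprintf("cell %d", seq_len(n_regions))
  }
  nm <- stats::setNames(labels, as.character(seq_along(labels)))
  parcellation_atlas(vol, affine, nm)
}
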