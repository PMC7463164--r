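#' Project points onto a triangulated surface
#'
#' Pulls scalp-level positions onto a surface mesh (typically the cortical
#' surface of the MNI template, or the scalp itself when snapping synthetic
#' optodes).  Two methods:
#'
#' * `"closest-point"` (default): the Euclidean nearest point over all
#'   triangles, ties broken by the lowest face index.
#' * `"ray-to-centroid"`: the intersection of the segment from the point to
#'   the mesh centroid with the nearest intersected triangle.  Points whose
#'   segment misses every triangle are dropped from the output and recorded
#'   in the `failed` attribute (one record per point); the run continues.
#'
#' @param points a [point_table()]; must share the mesh's frame
#' @param mesh a [surface_mesh()]
#' @param method `"closest-point"` or `"ray-to-centroid"`
#' @return a [point_table()] of on-surface positions, with attributes
#'   `method` and (possibly empty) `failed` (data.frame id, reason)
#' @export
project_to_surface <- function(points, mesh,
                               method = c("closest-point", "ray-to-centroid")) {
  method <- match.arg(method)
  check_same_frame(points, mesh, "points and mesh")
  if (!nrow(mesh$faces)) opto_validation_error("mesh has no faces")
  p <- pt_coords(points)
  if (method == "closest-point") {
    proj <- t(vapply(seq_len(nrow(p)), function(i) {
      closest_point_on_mesh(p[i, ], mesh)$point
    }, numeric(3)))
    failed <- data.frame(id = character(), reason = character())
  } else {
    g <- mesh_centroid(mesh)
    res <- lapply(seq_len(nrow(p)), function(i) ray_hit(p[i, ], g, mesh))
    ok <- vapply(res, function(r) !is.null(r), TRUE)
    proj <- do.call(rbind, lapply(res[ok], identity))
    if (is.null(proj)) proj <- matrix(numeric(), 0, 3)
    failed <- data.frame(
      id = points$id[!ok],
      reason = rep("segment to mesh centroid intersects no triangle",
                   sum(!ok)))
    points <- points[ok, , drop = FALSE]
  }
  out <- point_table(points$id, proj[, 1], proj[, 2], proj[, 3],
                     frame_of(points))
  attr(out, "method") <- method
  attr(out, "failed") <- failed
  out
}

# closest point on a triangle mesh; returns list(point, face, dist2)
# vectorized over faces (Ericson's region-based point-triangle test)
closest_point_on_mesh <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-c_, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  n <- nrow(f)
  s <- numeric(n); t_ <- numeric(n)  # barycentric (s along ab, t along ac)
  done <- logical(n)

  reg <- d1 <= 0 & d2 <= 0                       # vertex a
  s[reg] <- 0; t_[reg] <- 0; done <- done | reg
  reg <- !done & d3 >= 0 & d4 <= d3              # vertex b
  s[reg] <- 1; t_[reg] <- 0; done <- done | reg
  reg <- !done & d6 >= 0 & d5 <= d6              # vertex c
  s[reg] <- 0; t_[reg] <- 1; done <- done | reg
  vc <- d1 * d4 - d3 * d2
  reg <- !done & vc <= 0 & d1 >= 0 & d3 <= 0     # edge ab
  w <- d1 / (d1 - d3)
  s[reg] <- w[reg]; t_[reg] <- 0; done <- done | reg
  vb <- d5 * d2 - d1 * d6
  reg <- !done & vb <= 0 & d2 >= 0 & d6 <= 0     # edge ac
  w <- d2 / (d2 - d6)
  s[reg] <- 0; t_[reg] <- w[reg]; done <- done | reg
  va <- d3 * d6 - d5 * d4
  reg <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge bc
  w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  s[reg] <- 1 - w[reg]; t_[reg] <- w[reg]; done <- done | reg
  reg <- !done                                   # interior
  denom <- va + vb + vc
  s[reg] <- (vb / denom)[reg]; t_[reg] <- (vc / denom)[reg]

  q <- a + ab * s + ac * t_
  d2q <- rowSums(sweep(q, 2, p)^2)
  i <- which.min(d2q)  # lowest face index wins ties
  list(point = q[i, ], face = i, dist2 = d2q[i])
}

# Moeller-Trumbore over all faces for segment p -> g; nearest hit or NULL
ray_hit <- function(p, g, mesh, eps = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  d <- g - p
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tv <- sweep(-a, 2, p, "+")
  u <- rowSums(tv * pv) / det
  qv <- cross3(tv, e1)
  vbar <- (qv %*% d) / det
  t_ <- rowSums(e2 * qv) / det
  hit <- abs(det) > eps & u >= -1e-9 & vbar >= -1e-9 & (u + vbar) <= 1 + 1e-9 &
    t_ >= -1e-9 & t_ <= 1 + 1e-9
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.min(t_[hit])]
  p + t_[i] * d
}

#' Pair sources and detectors into data channels
#'
#' An fNIRS data channel is a source-detector pair at (approximately) the
#' nominal separation of the cap: every pair whose Euclidean separation lies
#' within `nominal_sep * (1 +/- tol)` becomes a channel.  Channel numbers are
#' assigned in lexicographic (source id, detector id) order, so numbering is
#' deterministic; a measured cap's own numbering can be imposed with
#' `pairing` (a data.frame channel,source,detector).
#'
#' @param optodes an [optode_set()]
#' @param nominal_sep nominal source-detector separation in mm (default 28)
#' @param tol relative tolerance in (0,1), default 0.2
#' @param pairing optional override data.frame with columns
#'   channel, source, detector; separations are then computed for exactly
#'   those pairs
#' @return a `channel_table`: data.frame channel, source, detector,
#'   separation_mm, with the optodes' frame attribute
#' @export
pair_channels <- function(optodes, nominal_sep = 28, tol = 0.2,
                          pairing = NULL) {
  if (nominal_sep <= 0) opto_validation_error("nominal_sep must be > 0")
  if (tol <= 0 || tol >= 1) opto_validation_error("tol must be in (0,1)")
  m <- pt_coords(optodes)
  if (!is.null(pairing)) {
    need <- c("channel", "source", "detector")
    if (!all(need %in% names(pairing))) {
      opto_validation_error("pairing override needs columns channel,source,detector")
    }
    miss <- setdiff(c(pairing$source, pairing$detector), optodes$id)
    if (length(miss)) {
      opto_validation_error(sprintf("pairing references unknown optode id(s): %s",
                                    paste(unique(miss), collapse = ", ")))
    }
    sep <- row_norms(m[pairing$source, , drop = FALSE] -
                       m[pairing$detector, , drop = FALSE])
    tab <- data.frame(channel = pairing$channel, source = pairing$source,
                      detector = pairing$detector, separation_mm = sep)
  } else {
    src <- optodes$id[optodes$role == "source"]
    det <- optodes$id[optodes$role == "detector"]
    pairs <- expand.grid(detector = det, source = src,
                         stringsAsFactors = FALSE)[, c("source", "detector")]
    if (nrow(pairs)) {
      pairs <- pairs[order(pairs$source, pairs$detector), , drop = FALSE]
      sep <- row_norms(m[pairs$source, , drop = FALSE] -
                         m[pairs$detector, , drop = FALSE])
      keep <- sep >= nominal_sep * (1 - tol) & sep <= nominal_sep * (1 + tol)
      pairs <- pairs[keep, , drop = FALSE]
      sep <- sep[keep]
    } else {
      sep <- numeric()
    }
    tab <- data.frame(channel = seq_len(nrow(pairs)),
                      source = pairs$source, detector = pairs$detector,
                      separation_mm = sep)
  }
  rownames(tab) <- NULL
  structure(tab, frame = frame_of(optodes),
            nominal_sep = nominal_sep, tol = tol,
            class = c("channel_table", "data.frame"))
}

#' Channel midpoints on the scalp or cortex
#'
#' A channel's location is the midpoint between its source and detector.  In
#' `"scalp"` space that is the plain arithmetic mean of the two optode
#' positions.  In `"cortical"` space the midpoint must lie on the cortical
#' surface; two orders of operation are offered:
#'
#' * `"scalp-midpoint"` (default): average the scalp endpoints, then project
#'   the mean onto the cortex.
#' * `"projected-endpoints"`: project each endpoint onto the cortex first,
#'   average, then re-project the mean onto the surface.
#'
#' @param channels a [pair_channels()] table
#' @param positions a [point_table()] (or optode set) containing every
#'   source and detector id
#' @param space `"scalp"` or `"cortical"`
#' @param cortex a [surface_mesh()], required for cortical space
#' @param method projection method passed to [project_to_surface()]
#' @param order midpoint rule for cortical space, see above
#' @return a [point_table()] keyed by channel id
#' @export
channel_midpoints <- function(channels, positions,
                              space = c("scalp", "cortical"), cortex = NULL,
                              method = "closest-point",
                              order = c("scalp-midpoint", "projected-endpoints")) {
  space <- match.arg(space)
  order <- match.arg(order)
  miss <- setdiff(c(channels$source, channels$detector), positions$id)
  if (length(miss)) {
    opto_validation_error(sprintf("positions lack optode id(s): %s",
                                  paste(unique(miss), collapse = ", ")))
  }
  m <- pt_coords(positions)
  frame <- frame_of(positions)
  if (space == "cortical" && order == "projected-endpoints") {
    proj <- project_to_surface(
      point_table(positions$id, m[, 1], m[, 2], m[, 3], frame),
      cortex, method)
    m <- pt_coords(proj)
  }
  mid <- (m[channels$source, , drop = FALSE] +
            m[channels$detector, , drop = FALSE]) / 2
  out <- point_table(as.character(channels$channel),
                     mid[, 1], mid[, 2], mid[, 3], frame)
  if (space == "cortical") {
    if (is.null(cortex)) {
      opto_validation_error("cortical space requires a cortex mesh")
    }
    out <- project_to_surface(out, cortex, method)
  }
  out
}
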