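#' Affine transforms between coordinate frames
#'
#' A 12-parameter affine map `p -> A p + b` carrying photo-frame coordinates
#' into MNI space (or back).  `A` is the unitless 3 x 3 linear part, `b` the
#' translation in mm, and `fit_rms` the root-mean-square landmark residual of
#' the fit that produced it (0 for exact constructions).
#'
#' @param A 3 x 3 invertible matrix
#' @param b length-3 translation (mm)
#' @param fit_rms non-negative RMS residual in mm
#' @param source_frame,target_frame frame tags
#' @return an `affine_transform`
#' @export
affine_transform <- function(A, b, fit_rms = 0,
                             source_frame = "photo", target_frame = "MNI") {
  A <- matrix(as.numeric(A), 3, 3)
  b <- as.numeric(b)
  if (length(b) != 3L || any(!is.finite(A)) || any(!is.finite(b))) {
    opto_validation_error("affine needs a finite 3x3 matrix and 3-vector")
  }
  d <- det(A)
  if (abs(d) <= 1e-9) {
    opto_validation_error(sprintf("affine linear part is singular (|det| = %g)",
                                  abs(d)))
  }
  if (fit_rms < 0) opto_validation_error("fit_rms must be >= 0")
  check_frame_tag(source_frame); check_frame_tag(target_frame)
  structure(list(A = A, b = b, fit_rms = as.numeric(fit_rms),
                 determinant = d,
                 source_frame = source_frame, target_frame = target_frame),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("affine_transform: '%s' -> '%s', det = %.6g, fit_rms = %.6g mm\n",
              x$source_frame, x$target_frame, x$determinant, x$fit_rms))
  invisible(x)
}

#' Fit the landmark-based affine transfer
#'
#' Least-squares estimate of the 12-parameter affine mapping the five source
#' fiducials (nasion, inion, Cz, preauricular points) onto the matching
#' target fiducials: 15 equations, 12 unknowns, ordinary least squares with
#' equal landmark weights.  The global scale ambiguity of photogrammetric
#' reconstruction is absorbed by the linear part.
#'
#' A negative determinant (mirrored reconstruction) and an RMS residual above
#' 10 mm (about half an optode separation, suggesting mis-picked landmarks)
#' each raise a warning but not an error.
#'
#' @param source a [landmark_set()] in the frame to map from
#' @param target a [landmark_set()] in the frame to map to (e.g. template
#'   fiducials in MNI space)
#' @return an [affine_transform()] with `fit_rms` in mm
#' @examples
#' tmpl <- landmark_set(point_table(
#'   c("nasion", "inion", "cz", "lpa", "rpa"),
#'   x = c(0, 0, 0, -80, 80), y = c(95, -115, -10, -15, -15),
#'   z = c(-10, -20, 100, -40, -40), frame = "MNI"))
#' fit_affine(tmpl, tmpl)  # identity, fit_rms 0
#' @export
fit_affine <- function(source, target) {
  source <- landmark_set(source); target <- landmark_set(target)
  S <- pt_coords(source)  # canonical row order guaranteed by landmark_set
  T_ <- pt_coords(target)
  X <- cbind(S, 1)
  B <- qr.solve(X, T_)           # 4 x 3
  A <- t(B[1:3, , drop = FALSE])
  b <- as.numeric(B[4, ])
  resid <- X %*% B - T_
  fit_rms <- sqrt(sum(resid^2) / nrow(S))
  out <- affine_transform(A, b, fit_rms,
                          source_frame = frame_of(source),
                          target_frame = frame_of(target))
  if (out$determinant < 0) {
    warning("fitted affine has negative determinant: source landmarks appear mirrored",
            call. = FALSE)
  }
  if (fit_rms > 10) {
    warning(sprintf(
      "landmark fit_rms = %.1f mm exceeds 10 mm; check landmark picking",
      fit_rms), call. = FALSE)
  }
  out
}

#' Apply an affine transform to a point table
#'
#' @param transform an [affine_transform()]
#' @param points a [point_table()] (or optode/landmark set) in the
#'   transform's source frame
#' @return points mapped to the target frame, order and ids preserved;
#'   optode roles are kept
#' @export
apply_affine <- function(transform, points) {
  if (!identical(frame_of(points), transform$source_frame)) {
    opto_validation_error(sprintf(
      "frame mismatch: points are in '%s' but transform maps from '%s'",
      frame_of(points), transform$source_frame))
  }
  m <- pt_coords(points)
  out <- sweep(m %*% t(transform$A), 2, transform$b, "+")
  if (inherits(points, "optode_set")) {
    optode_set(points$id, points$role, out[, 1], out[, 2], out[, 3],
               transform$target_frame)
  } else {
    pt_from_coords(points$id, out, transform$target_frame)
  }
}

#' Invert an affine transform
#'
#' @param transform an [affine_transform()]
#' @return the inverse transform (frames swapped; `fit_rms` carried over as
#'   a fit-quality annotation)
#' @export
invert_affine <- function(transform) {
  Ainv <- solve(transform$A)
  affine_transform(Ainv, -Ainv %*% transform$b, transform$fit_rms,
                   source_frame = transform$target_frame,
                   target_frame = transform$source_frame)
}

#' Serialize / deserialize an affine transform as JSON
#'
#' The 3 x 3 matrix is stored row-major, translation as a 3-vector, plus
#' `fit_rms`, determinant and frame tags.
#'
#' @param transform an [affine_transform()]
#' @param path file path
#' @return `read_affine`: an [affine_transform()]
#' @export
write_affine <- function(transform, path) {
  obj <- list(matrix = as.numeric(t(transform$A)),
              translation = transform$b,
              fit_rms = transform$fit_rms,
              determinant = transform$determinant,
              source_frame = transform$source_frame,
              target_frame = transform$target_frame)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) opto_format_error(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(obj$matrix, 3, 3, byrow = TRUE), obj$translation,
                   obj$fit_rms, obj$source_frame, obj$target_frame)
}
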