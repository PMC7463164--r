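LANDMARK_NAMES <- c("nasion", "inion", "cz", "lpa", "rpa")

#' Fiducial landmark sets
#'
#' The five cranial reference points anchoring the affine transfer into MNI
#' space: nasion, inion, Cz (vertex), and the left/right preauricular points
#' (`lpa`, `rpa`).  The set must be complete, without duplicates, and
#' non-coplanar -- a coplanar set leaves the out-of-plane behaviour of a
#' 12-parameter affine unconstrained.
#'
#' @param points a [point_table()] whose ids are the five landmark names
#'   (case-insensitive)
#' @return a `landmark_set` (a `point_table` subclass, rows in canonical
#'   order nasion, inion, cz, lpa, rpa)
#' @export
landmark_set <- function(points) {
  ids <- tolower(points$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    opto_validation_error(sprintf("duplicate landmark name(s): %s",
                                  paste(dup, collapse = ", ")))
  }
  missing <- setdiff(LANDMARK_NAMES, ids)
  if (length(missing)) {
    opto_validation_error(sprintf("missing landmark(s): %s",
                                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(ids, LANDMARK_NAMES)
  if (length(extra)) {
    opto_validation_error(sprintf("unknown landmark name(s): %s",
                                  paste(extra, collapse = ", ")))
  }
  points <- points[match(LANDMARK_NAMES, ids), , drop = FALSE]
  points$id <- LANDMARK_NAMES
  m <- as.matrix(points[, c("x", "y", "z")])
  if (coords_rank(m) < 3L) {
    opto_validation_error(
      "landmarks are coplanar (rank of centered coordinates < 3); the affine fit would be degenerate")
  }
  structure(points, class = c("landmark_set", "point_table", "data.frame"),
            frame = frame_of(points))
}

# rank of centered coordinates; tolerance relative to spread
coords_rank <- function(m, tol = 1e-7) {
  centered <- sweep(m, 2, colMeans(m))
  s <- svd(centered)$d
  if (s[1] == 0) return(0L)
  sum(s > tol * s[1])
}

#' Read / write fiducial landmarks
#'
#' CSV schema `name,x,y,z`; the name column must contain exactly
#' nasion, inion, cz, lpa, rpa (case-insensitive).
#'
#' @param path file path
#' @param frame frame tag to attach on read; default `"photo"` since picked
#'   landmarks usually live on the reconstruction
#' @return `read_landmarks`: a [landmark_set()]
#' @export
read_landmarks <- function(path, frame = "photo") {
  df <- read_csv_checked(path, c("name", "x", "y", "z"))
  landmark_set(point_table(df$name, as_num(df$x, path), as_num(df$y, path),
                           as_num(df$z, path), frame))
}

#' @param landmarks a [landmark_set()]
#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = landmarks$id, x = landmarks$x, y = landmarks$y,
                   z = landmarks$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
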