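OPTODE_ROLES <- c("source", "detector")

#' Optode sets
#'
#' An optode set records the scalp positions of the light emitters
#' (`source`) and detectors of an fNIRS probe.  A typical unilateral cap in
#' this workflow holds 6 sources and 12 detectors forming 23 channels.
#'
#' @param id character optode labels, unique
#' @param role `"source"` or `"detector"`, one per optode
#' @param x,y,z coordinates in millimetres
#' @param frame `"photo"` or `"MNI"`
#' @return an `optode_set` (a `point_table` subclass with a `role` column)
#' @export
optode_set <- function(id, role, x, y, z, frame) {
  pts <- point_table(id, x, y, z, frame)
  role <- tolower(as.character(role))
  if (length(role) != nrow(pts)) {
    opto_validation_error("role must have one entry per optode")
  }
  bad <- setdiff(unique(role), OPTODE_ROLES)
  if (length(bad)) {
    opto_validation_error(sprintf(
      "invalid optode role(s): %s (must be source or detector)",
      paste(bad, collapse = ", ")))
  }
  pts$role <- role
  pts <- pts[, c("id", "role", "x", "y", "z")]
  structure(pts, class = c("optode_set", "point_table", "data.frame"),
            frame = frame)
}

#' @export
print.optode_set <- function(x, ...) {
  cat(sprintf("optode_set: %d source(s), %d detector(s), frame '%s'\n",
              sum(x$role == "source"), sum(x$role == "detector"), frame_of(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write optode coordinates
#'
#' CSV schema `id,role,x,y,z` with role in source/detector.  An empty body
#' is valid (downstream operations decide whether that is acceptable).
#'
#' @param path file path
#' @param frame frame tag to attach on read; default `"photo"`
#' @return `read_optodes`: an [optode_set()], file order preserved
#' @export
read_optodes <- function(path, frame = "photo") {
  df <- read_csv_checked(path, c("id", "role", "x", "y", "z"))
  if (!nrow(df)) {
    return(optode_set(character(), character(), numeric(), numeric(),
                      numeric(), frame))
  }
  optode_set(df$id, df$role, as_num(df$x, path), as_num(df$y, path),
             as_num(df$z, path), frame)
}

#' @param optodes an [optode_set()]
#' @rdname read_optodes
#' @export
write_optodes <- function(optodes, path) {
  utils::write.csv(as.data.frame(optodes)[, c("id", "role", "x", "y", "z")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# point_table view of an optode set (drops role)
optode_points <- function(optodes) {
  point_table(optodes$id, optodes$x, optodes$y, optodes$z, frame_of(optodes))
}
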