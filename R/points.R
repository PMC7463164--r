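#' Point tables
#'
#' The basic spatial container: a data frame with columns `id`, `x`, `y`, `z`
#' (millimetres) and a frame attribute (`"photo"` or `"MNI"`).  Axis
#' convention follows MNI/RAS usage: x negative toward the left hemisphere,
#' y positive anterior, z positive dorsal.
#'
#' @param id character vector of point identifiers (unique)
#' @param x,y,z numeric coordinates in millimetres
#' @param frame `"photo"` or `"MNI"`
#' @return a `point_table`: data.frame with a `frame` attribute
#' @examples
#' pts <- point_table(c("a", "b"), x = c(0, 1), y = 0, z = 0, frame = "MNI")
#' frame_of(pts)
#' @export
point_table <- function(id, x, y, z, frame) {
  check_frame_tag(frame)
  id <- as.character(id)
  n <- length(id)
  x <- check_numeric_finite(rep_len(x, n), "x")
  y <- check_numeric_finite(rep_len(y, n), "y")
  z <- check_numeric_finite(rep_len(z, n), "z")
  if (anyDuplicated(id)) {
    opto_validation_error(sprintf(
      "duplicate point id(s): %s",
      paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  df <- data.frame(id = id, x = x, y = y, z = z, stringsAsFactors = FALSE)
  structure(df, frame = frame, class = c("point_table", "data.frame"))
}

#' @export
print.point_table <- function(x, ...) {
  cat(sprintf("point_table: %d point(s), frame '%s'\n", nrow(x), frame_of(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# n x 3 coordinate matrix, rownames = ids
pt_coords <- function(p) {
  m <- as.matrix(p[, c("x", "y", "z")])
  rownames(m) <- p$id
  m
}

# rebuild a point_table from an id vector and n x 3 matrix
pt_from_coords <- function(id, m, frame) {
  point_table(id, m[, 1], m[, 2], m[, 3], frame)
}

#' Read / write generic point tables
#'
#' CSV schema `id,x,y,z`, comma-separated, header required, "." decimal.
#' Files carry no frame or unit information; coordinates are always read as
#' millimetres and tagged with the frame the caller declares.
#'
#' @param path file path
#' @param frame frame tag to attach on read
#' @return `read_points`: a [point_table()]; `write_points`: `path`, invisibly
#' @export
read_points <- function(path, frame) {
  df <- read_csv_checked(path, c("id", "x", "y", "z"))
  point_table(df$id, as_num(df$x, path), as_num(df$y, path),
              as_num(df$z, path), frame)
}

#' @param points a [point_table()]
#' @rdname read_points
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("id", "x", "y", "z")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    opto_format_error(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    opto_format_error(sprintf("%s: missing column(s): %s", path,
                              paste(missing, collapse = ", ")))
  }
  df
}

as_num <- function(x, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- x[is.na(out)][1]
    opto_format_error(sprintf("%s: non-numeric coordinate value '%s'",
                              path, bad))
  }
  out
}
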