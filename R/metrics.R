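#' Between-method displacement per optode or channel
#'
#' For each shared id, the per-axis absolute coordinate differences
#' `dx, dy, dz` and the Euclidean distance `d` between two position
#' estimates of the same probe (e.g. photogrammetric vs MRI registration).
#' Raw precision is retained; use [round_displacement()] for report-style
#' rounding (distances to 1 decimal).
#'
#' @param a,b [point_table()]s covering the same id set, same frame
#' @return data.frame id, dx, dy, dz, d (mm), in the order of `a`
#' @examples
#' a <- point_table("opt1", -61, 34, -7, frame = "MNI")
#' b <- point_table("opt1", -59, 39, -5, frame = "MNI")
#' displacement(a, b)  # d = sqrt(4 + 25 + 4) = 5.74
#' @export
displacement <- function(a, b) {
  check_same_frame(a, b, "position tables")
  if (!setequal(a$id, b$id)) {
    opto_validation_error(sprintf(
      "id mismatch between position tables (only in first: %s; only in second: %s)",
      paste(setdiff(a$id, b$id), collapse = ",") ,
      paste(setdiff(b$id, a$id), collapse = ",")))
  }
  ma <- pt_coords(a)
  mb <- pt_coords(b)[a$id, , drop = FALSE]
  dif <- abs(ma - mb)
  data.frame(id = a$id, dx = dif[, 1], dy = dif[, 2], dz = dif[, 3],
             d = row_norms(dif), row.names = NULL)
}

#' @param records a displacement data.frame
#' @param coord_digits,dist_digits rounding for the axis and distance columns
#' @rdname displacement
#' @export
round_displacement <- function(records, coord_digits = 0, dist_digits = 1) {
  records$dx <- round(records$dx, coord_digits)
  records$dy <- round(records$dy, coord_digits)
  records$dz <- round(records$dz, coord_digits)
  records$d <- round(records$d, dist_digits)
  records
}

#' Group positions across participants
#'
#' A `group_positions` object holds one [point_table()] per participant,
#' all covering the same id set in the same frame -- the input for
#' between-participant dispersion statistics.
#'
#' @param tables named list of [point_table()]s (names = participant ids)
#' @return a `group_positions` object
#' @export
group_positions <- function(tables) {
  if (!length(tables)) opto_validation_error("no participant tables supplied")
  ids <- tables[[1]]$id
  frame <- frame_of(tables[[1]])
  for (t_ in tables) {
    if (!setequal(t_$id, ids)) {
      opto_validation_error("participants do not cover the same id set")
    }
    if (!identical(frame_of(t_), frame)) {
      opto_validation_error("participant tables are in different frames")
    }
  }
  structure(list(tables = tables, ids = ids),
            frame = frame, class = "group_positions")
}

#' Composite standard deviation of positions across participants
#'
#' For each id, the sample standard deviation of each coordinate across
#' participants, combined as `Csd = sqrt(sdx^2 + sdy^2 + sdz^2)` -- a scalar
#' measure of between-participant placement dispersion.  Uses the n-1
#' denominator.  `Csd^2` equals the trace of the per-id coordinate
#' covariance, so Csd is invariant under rigid rotation of all participants.
#'
#' @param group a [group_positions()] with at least 2 participants
#' @return data.frame id, sdx, sdy, sdz, csd (mm)
#' @export
composite_sd <- function(group) {
  if (!inherits(group, "group_positions")) group <- group_positions(group)
  n <- length(group$tables)
  if (n < 2L) {
    opto_validation_error("composite_sd needs at least 2 participants")
  }
  ids <- group$ids
  arr <- vapply(group$tables,
                function(t_) pt_coords(t_)[ids, , drop = FALSE],
                matrix(0, length(ids), 3))  # id x 3 x participant
  sds <- apply(arr, c(1, 2), stats::sd)
  data.frame(id = ids, sdx = sds[, 1], sdy = sds[, 2], sdz = sds[, 3],
             csd = sqrt(rowSums(sds^2)), row.names = NULL)
}

#' Mean per-axis displacement
#'
#' Arithmetic mean of the per-axis absolute differences over all records --
#' the summary used to diagnose directional cap shift (e.g. the forward and
#' upward displacement caused by lying supine in an MRI scanner).
#'
#' @param records a [displacement()] data.frame
#' @return named numeric: mean dx, dy, dz (mm)
#' @export
axis_displacement_summary <- function(records) {
  if (!nrow(records)) opto_validation_error("no displacement records")
  c(dx = mean(records$dx), dy = mean(records$dy), dz = mean(records$dz))
}

#' Channel measurement overlap between two registrations
#'
#' Each channel's sampling volume is modelled as a sphere of radius `R`
#' (default 20 mm) about the channel position.  The overlap between two
#' registrations of the same channel is the lens (intersection) volume of
#' the two equal spheres divided by the volume of one sphere, so identical
#' positions give 1 and separations of `2R` or more give 0.  Closed form for
#' separation `d <= 2R`:
#' `fraction = (4R + d) (2R - d)^2 / (16 R^3)`.
#'
#' @param center_a,center_b [point_table()]s of channel centers (same ids,
#'   same frame), or single positions
#' @param R sphere radius in mm (default 20)
#' @return data.frame id, separation_mm, overlap
#' @export
channel_overlap <- function(center_a, center_b, R = 20) {
  if (R <= 0) opto_validation_error("sphere radius R must be > 0")
  dis <- displacement(center_a, center_b)
  data.frame(id = dis$id, separation_mm = dis$d,
             overlap = sphere_overlap_fraction(dis$d, R), row.names = NULL)
}

#' @param d separation(s) in mm
#' @rdname channel_overlap
#' @export
sphere_overlap_fraction <- function(d, R = 20) {
  if (R <= 0) opto_validation_error("sphere radius R must be > 0")
  ifelse(d >= 2 * R, 0, (4 * R + d) * (2 * R - d)^2 / (16 * R^3))
}
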