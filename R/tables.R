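#' Bundled reference coordinate tables
#'
#' Group-averaged optode and frontal-channel MNI coordinates from a
#' published comparison of photogrammetric (POR) and MRI-based fNIRS
#' registration on a 18-optode / 23-channel left-hemisphere cap, for adult
#' and child cohorts.  These printed tables serve as worked-example
#' fixtures: feeding the POR and MRI coordinate columns through
#' [displacement()] reproduces the printed per-axis differences exactly and
#' the printed Euclidean distances to rounding precision.
#'
#' @param group `"adult"`, `"child"`, or `"both"`
#' @return `reference_optode_table`: data.frame group, optode,
#'   por_x..por_z, mri_x..mri_z, dx, dy, dz, d;
#'   `reference_channel_table`: data.frame group, channel, method, x, y, z,
#'   regions (semicolon-joined), dx, dy, dz
#' @export
reference_optode_table <- function(group = c("both", "adult", "child")) {
  group <- match.arg(group)
  path <- system.file("extdata", "group_mean_optodes.csv",
                      package = "optodereg", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (group != "both") df <- df[df$group == group, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname reference_optode_table
#' @export
reference_channel_table <- function(group = c("both", "adult", "child")) {
  group <- match.arg(group)
  path <- system.file("extdata", "frontal_channels.csv",
                      package = "optodereg", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (group != "both") df <- df[df$group == group, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# POR / MRI halves of the optode table as point_tables (MNI frame)
reference_point_tables <- function(group) {
  df <- reference_optode_table(group)
  list(por = point_table(df$optode, df$por_x, df$por_y, df$por_z, "MNI"),
       mri = point_table(df$optode, df$mri_x, df$mri_y, df$mri_z, "MNI"))
}
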