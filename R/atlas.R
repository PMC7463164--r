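#' Parcellation atlases
#'
#' An integer label volume with a voxel-to-world affine (mm, MNI frame) and
#' a label-id-to-region-name map.  Label 0 is reserved for background
#' (non-brain); every nonzero label occurring in the grid must be named.
#' This generic interface stands in for any anatomical database volume
#' (e.g. an AAL-style gyrus atlas).
#'
#' @param labels 3-D integer array of region labels
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices -> mm)
#' @param names named character vector mapping label ids (as names) to
#'   region names, e.g. `c("1" = "Inferior frontal gyrus")`
#' @return a `parcellation_atlas`
#' @export
parcellation_atlas <- function(labels, affine, names) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) {
    opto_validation_error("atlas labels must be a 3-D array")
  }
  storage.mode(labels) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine[1:3, 1:3])) <= 1e-12) {
    opto_validation_error("voxel-to-world affine must be 4x4 and invertible")
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (any(present < 0L)) opto_validation_error("negative labels are not allowed")
  unnamed <- setdiff(as.character(present), base::names(names))
  if (length(unnamed)) {
    opto_validation_error(sprintf("label(s) without a region name: %s",
                                  paste(unnamed, collapse = ", ")))
  }
  structure(list(labels = labels, affine = affine,
                 names = vapply(names, as.character, "")),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("parcellation_atlas: %s grid, %d named region(s)\n",
              paste(dim(x$labels), collapse = " x "), length(x$names)))
  invisible(x)
}

#' Read / write a parcellation atlas
#'
#' The volume is a NIfTI-1 integer label file (`.nii` or `.nii.gz`, sform
#' preferred for orientation) and the label map a JSON object
#' `{"7": "Inferior frontal gyrus", ...}`.
#'
#' @param nii_path path to the label volume
#' @param labels_path path to the JSON label map
#' @return `read_atlas`: a [parcellation_atlas()]
#' @export
read_atlas <- function(nii_path, labels_path) {
  vol <- read_nifti_vol(nii_path)
  if (!file.exists(labels_path)) {
    opto_format_error(sprintf("file not found: %s", labels_path))
  }
  nm <- unlist(jsonlite::read_json(labels_path))
  data <- vol$data
  if (any(abs(data - round(data)) > 1e-6)) {
    opto_format_error(sprintf("%s: label volume is not integer-valued", nii_path))
  }
  parcellation_atlas(round(data), vol$affine, nm)
}

#' @param atlas a [parcellation_atlas()]
#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, nii_path, labels_path) {
  write_nifti_vol(atlas$labels, atlas$affine, nii_path)
  jsonlite::write_json(as.list(atlas$names), labels_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(nii_path)
}

#' Look up atlas labels at world coordinates
#'
#' Each point is mapped through the inverse voxel-to-world affine and
#' assigned the label of the nearest voxel (labels are categorical, so no
#' interpolation).  Points on a voxel boundary are resolved by rounding the
#' fractional index half away from the grid center, a fixed deterministic
#' tie rule.  Points outside the grid get the background label 0.
#'
#' @param points a [point_table()] in MNI frame
#' @param atlas a [parcellation_atlas()]
#' @return integer vector of labels, one per point
#' @export
label_points <- function(points, atlas) {
  if (!identical(frame_of(points), "MNI")) {
    opto_validation_error("atlas lookup requires MNI-frame points")
  }
  m <- pt_coords(points)
  label_coords(m, atlas)
}

# world mm matrix -> labels (internal, frame already checked)
label_coords <- function(m, atlas) {
  inv <- solve(atlas$affine)
  vox <- sweep(m %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")  # 0-based cont. index
  dims <- dim(atlas$labels)
  ctr <- (dims - 1) / 2
  out <- integer(nrow(vox))
  idx <- matrix(0L, nrow(vox), 3)
  for (j in 1:3) {
    lo <- floor(vox[, j])
    frac <- vox[, j] - lo
    up <- frac > 0.5 | (frac == 0.5 & vox[, j] >= ctr[j])  # ties: away from center
    idx[, j] <- as.integer(lo + up)
  }
  inside <- idx[, 1] >= 0L & idx[, 1] < dims[1] &
    idx[, 2] >= 0L & idx[, 2] < dims[2] &
    idx[, 3] >= 0L & idx[, 3] < dims[3]
  if (any(inside)) {
    lin <- idx[inside, 1] + dims[1] * (idx[inside, 2] + dims[2] * idx[inside, 3])
    out[inside] <- atlas$labels[lin + 1L]
  }
  out
}
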