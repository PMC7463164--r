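#' @keywords internal
"_PACKAGE"

VALID_FRAMES <- c("photo", "MNI")

opto_stop <- function(msg, class = "opto_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "opto_error")))
}

opto_validation_error <- function(msg) opto_stop(msg, "opto_validation_error")
opto_format_error <- function(msg) opto_stop(msg, "opto_format_error")

check_frame_tag <- function(frame) {
  if (!is.character(frame) || length(frame) != 1L || !frame %in% VALID_FRAMES) {
    opto_validation_error(sprintf(
      "frame must be one of %s", paste(sQuote(VALID_FRAMES), collapse = ", ")))
  }
  frame
}

#' Coordinate frame of an object
#'
#' All spatial objects carry a frame tag, either `"photo"` (the arbitrary
#' frame of a photogrammetric reconstruction, in mm up to the global scale
#' ambiguity of structure-from-motion) or `"MNI"` (millimetres in MNI152
#' template space, x increasing to the right).  Operations refuse to mix
#' frames.
#'
#' @param x an object with a frame attribute
#' @return the frame tag, a single string
#' @export
frame_of <- function(x) {
  f <- attr(x, "frame", exact = TRUE)
  if (is.null(f)) opto_validation_error("object carries no frame tag")
  f
}

check_same_frame <- function(a, b, what = "objects") {
  fa <- frame_of(a); fb <- frame_of(b)
  if (!identical(fa, fb)) {
    opto_validation_error(sprintf(
      "frame mismatch: %s are in frames '%s' and '%s'", what, fa, fb))
  }
  fa
}

check_numeric_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    opto_validation_error(sprintf("%s must be finite numbers", name))
  }
  as.numeric(x)
}

# Euclidean norms of matrix rows
row_norms <- function(m) sqrt(rowSums(m * m))
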