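#' Uniform sampling inside a sphere
#'
#' Draws `n` points uniformly from the closed ball of radius `r` about a
#' channel position: isotropic directions from normalized Gaussian triples,
#' radii by the inverse-CDF rule `r * u^(1/3)` (no rejection, so the draw
#' count per seed is fixed and runs are reproducible).  The mean sampled
#' radius of a uniform ball is `3r/4`.
#'
#' @param center a single-row [point_table()], or a length-3 numeric (mm)
#' @param r ball radius in mm (default 10)
#' @param n number of samples (default 10000)
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (callers that loop over channels seed once outside)
#' @param frame frame tag when `center` is a bare numeric
#' @return a [point_table()] with ids `"1"..."n"`
#' @export
sample_sphere_uniform <- function(center, r = 10, n = 10000, seed = NULL,
                                  frame = "MNI") {
  if (r <= 0) opto_validation_error("sphere radius r must be > 0")
  if (n < 1) opto_validation_error("sample count n must be >= 1")
  if (inherits(center, "point_table")) {
    if (nrow(center) != 1L) {
      opto_validation_error("center must be a single point")
    }
    frame <- frame_of(center)
    center <- as.numeric(center[1, c("x", "y", "z")])
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- row_norms(dir)
  nrm[nrm == 0] <- 1
  dir <- dir / nrm
  rad <- r * stats::runif(n)^(1 / 3)
  pts <- sweep(dir * rad, 2, center, "+")
  point_table(as.character(seq_len(n)), pts[, 1], pts[, 2], pts[, 3], frame)
}

#' Monte-Carlo region estimation per channel
#'
#' Estimates which anatomical regions each data channel samples: draws `n`
#' points uniformly in a ball of radius `r` (default 10 mm, n = 10000)
#' around each channel position, looks every point up in the parcellation
#' atlas, and tabulates region fractions.  Regions at or above
#' `min_fraction` of the samples are marked `detected`.  Background
#' (label 0, non-brain) samples are reported as region `"<background>"`;
#' with `normalize = "all"` (default) they stay in the denominator, with
#' `"labeled"` fractions are renormalized over brain-labeled samples only.
#'
#' @param channels a [point_table()] of channel positions (MNI frame)
#' @param atlas a [parcellation_atlas()]
#' @param r sampling ball radius in mm
#' @param n samples per channel
#' @param seed integer seed for the whole table (one RNG stream, channels
#'   sampled in row order, so the table is reproducible per seed)
#' @param min_fraction detection threshold on the reported fraction
#' @param normalize `"all"` or `"labeled"`
#' @return a `region_table`: data.frame channel, region, fraction, detected,
#'   regions per channel sorted by descending fraction (background last);
#'   parameters recorded in attributes
#' @export
region_table <- function(channels, atlas, r = 10, n = 10000, seed = 1,
                         min_fraction = 0.05,
                         normalize = c("all", "labeled")) {
  normalize <- match.arg(normalize)
  if (min_fraction < 0 || min_fraction > 1) {
    opto_validation_error("min_fraction must be in [0,1]")
  }
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(channels)), function(i) {
    samp <- sample_sphere_uniform(channels[i, , drop = FALSE], r = r, n = n,
                                  seed = NULL)
    lab <- label_points(samp, atlas)
    counts <- table(lab)
    is_bg <- base::names(counts) == "0"
    denom <- if (normalize == "labeled") {
      max(sum(counts[!is_bg]), 1L)
    } else {
      n
    }
    # background is always reported relative to all samples
    frac <- ifelse(is_bg, as.numeric(counts) / n, as.numeric(counts) / denom)
    region <- ifelse(base::names(counts) == "0", "<background>",
                     atlas$names[base::names(counts)])
    df <- data.frame(channel = channels$id[i], region = region,
                     fraction = frac,
                     detected = region != "<background>" & frac >= min_fraction,
                     row.names = NULL)
    bg <- df$region == "<background>"
    rbind(df[!bg, , drop = FALSE][order(-df$fraction[!bg]), , drop = FALSE],
          df[bg, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, r = r, n = n, seed = seed, min_fraction = min_fraction,
            normalize = normalize, class = c("region_table", "data.frame"))
}

#' Detected regions per channel
#'
#' @param regions a [region_table()]
#' @return the subset of rows with `detected == TRUE`
#' @export
detected_regions <- function(regions) {
  regions[regions$detected, , drop = FALSE]
}
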