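#' Segment the cell region of a frame
#'
#' Gaussian-smooths the image, applies a global threshold (Otsu by default),
#' keeps the largest connected above-threshold component and fills its
#' holes. The returned centroid is the intensity-weighted centre of mass of
#' the raw image over the mask — the reference point for dispersion
#' analysis.
#'
#' @param stack A [frame_stack()].
#' @param channel Channel index or name.
#' @param frame Frame index.
#' @param smooth_sigma Gaussian pre-smoothing sigma in px.
#' @param method `"otsu"` or `"quantile"`.
#' @param quantile Threshold quantile when `method = "quantile"`.
#' @return An object of class `cell_region`: `mask` (logical Y x X),
#'   `intensity_centroid_px` `(y, x)`, `area_px`, `threshold`,
#'   `pixel_size_nm`.
#' @export
segment_cell <- function(stack, channel = 1, frame = 1,
                         smooth_sigma = 2, method = c("otsu", "quantile"),
                         quantile = 0.5) {
  method <- match.arg(method)
  img <- frame_matrix(stack, channel, frame)
  rng <- range(img)
  if (diff(rng) == 0) {
    stop("no cell found: image has no contrast", call. = FALSE)
  }
  sm <- as.matrix(EBImage::gblur(img, sigma = smooth_sigma))
  # clip the bright tail (vesicle spots) so the cell-body/background
  # contrast, not a few bright pixels, drives the threshold
  sm <- pmin(sm, stats::quantile(sm, 0.995, names = FALSE))
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L),
    quantile = stats::quantile(norm, quantile, names = FALSE)
  )
  above <- norm > thr
  if (!any(above)) stop("no cell found: empty threshold mask", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(above * 1))
  tab <- tabulate(as.integer(as.matrix(lab)))
  biggest <- which.max(tab)
  mask <- as.matrix(lab) == biggest
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0

  w <- img * mask
  tot <- sum(w)
  yy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  xx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  centroid <- c(sum(yy * w), sum(xx * w)) / tot

  structure(
    list(
      mask = mask,
      intensity_centroid_px = centroid,
      area_px = sum(mask),
      threshold = as.numeric(thr),
      method = method,
      pixel_size_nm = stack$pixel_size_nm
    ),
    class = "cell_region"
  )
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf(
    "<cell_region> area %d px, centroid (%.2f, %.2f) px, %s threshold %.4g\n",
    x$area_px, x$intensity_centroid_px[1], x$intensity_centroid_px[2],
    x$method, x$threshold
  ))
  invisible(x)
}

#' Build a cell region from a known mask
#'
#' Convenience constructor for analyses on pre-defined masks (e.g. the
#' ground-truth disk of a synthetic cell, or a mask from other software).
#'
#' @param mask Logical Y x X matrix.
#' @param image Optional intensity image for the centroid; a uniform image
#'   (geometric centroid) is assumed when absent.
#' @param pixel_size_nm Pixel size in nm.
#' @return A `cell_region`.
#' @export
cell_region_from_mask <- function(mask, image = NULL, pixel_size_nm = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (is.null(image)) image <- matrix(1, nrow(mask), ncol(mask))
  w <- image * mask
  yy <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  xx <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  structure(
    list(
      mask = mask,
      intensity_centroid_px = c(sum(yy * w), sum(xx * w)) / sum(w),
      area_px = sum(mask),
      threshold = NA_real_,
      method = "manual",
      pixel_size_nm = pixel_size_nm
    ),
    class = "cell_region"
  )
}
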