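#' Spot-detection and linking parameters
#'
#' @param expected_spot_sigma_px Expected PSF sigma of a diffraction-limited
#'   spot, px.
#' @param detection_threshold Threshold on the band-pass response in robust
#'   noise units: a candidate must exceed `median + k * MAD` of the
#'   difference-of-Gaussians image, `k` being this value. Because the
#'   threshold is relative to the image's own robust noise, detection counts
#'   are invariant under global intensity scaling.
#' @param min_separation_px Minimum distance between detections; closer
#'   candidates are suppressed in favour of the stronger response, so two
#'   unresolvable spots yield one detection at their intensity-weighted
#'   position.
#' @param max_link_displacement_px Hard gate for frame-to-frame linking.
#' @param window_radius_px Radius of the square window used for sub-pixel
#'   centre-of-mass refinement and intensity measures; defaults to
#'   `ceiling(2 * expected_spot_sigma_px)`.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(expected_spot_sigma_px = 1.3,
                             detection_threshold = 10,
                             min_separation_px = 3,
                             max_link_displacement_px = 5,
                             window_radius_px = NULL) {
  if (is.null(window_radius_px)) {
    window_radius_px <- ceiling(2 * expected_spot_sigma_px)
  }
  stopifnot(
    "expected_spot_sigma_px must be positive" = expected_spot_sigma_px > 0,
    "detection_threshold must be positive" = detection_threshold > 0,
    "min_separation_px must be positive" = min_separation_px > 0,
    "max_link_displacement_px must be positive" = max_link_displacement_px > 0,
    "window_radius_px must be positive" = window_radius_px > 0
  )
  structure(
    list(
      expected_spot_sigma_px = expected_spot_sigma_px,
      detection_threshold = detection_threshold,
      min_separation_px = min_separation_px,
      max_link_displacement_px = max_link_displacement_px,
      window_radius_px = as.integer(window_radius_px)
    ),
    class = "detection_params"
  )
}

# Difference-of-Gaussians band-pass at sigma / 1.6 sigma.
dog_response <- function(img, sigma) {
  as.matrix(EBImage::gblur(img, sigma = sigma)) -
    as.matrix(EBImage::gblur(img, sigma = 1.6 * sigma))
}

# Logical matrix: strict local maxima over the 8-neighbourhood.
local_maxima <- function(resp) {
  ny <- nrow(resp); nx <- ncol(resp)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- resp
  out <- matrix(TRUE, ny, nx)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
      out <- out & (resp > nb)
    }
  }
  out
}

#' Detect diffraction-limited vesicle spots in one frame
#'
#' Band-passes the frame with a difference of Gaussians at the expected spot
#' scale, picks strict local maxima above a robust threshold
#' (`median + k * MAD` of the response), suppresses candidates closer than
#' `min_separation_px` to a stronger one, and refines each kept candidate to
#' a sub-pixel centroid by background-subtracted centre of mass in a local
#' window. Fully deterministic.
#'
#' @param stack A [frame_stack()].
#' @param channel Channel index or name.
#' @param frame Frame index.
#' @param params A [detection_params()].
#' @return A tibble with one row per detection, sorted by descending peak
#'   intensity: `frame`, `channel`, `y_px`, `x_px`, `y_nm`, `x_nm`,
#'   `peak_intensity`, `integrated_intensity`.
#' @export
detect_vesicles <- function(stack, channel = 1, frame = 1,
                            params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  img <- frame_matrix(stack, channel, frame)
  ch_name <- stack$channel_names[resolve_channel(stack, channel)]
  empty <- tibble::tibble(
    frame = integer(0), channel = character(0),
    y_px = numeric(0), x_px = numeric(0),
    y_nm = numeric(0), x_nm = numeric(0),
    peak_intensity = numeric(0), integrated_intensity = numeric(0)
  )
  if (diff(range(img)) == 0) return(empty)

  resp <- dog_response(img, params$expected_spot_sigma_px)
  thr <- stats::median(resp) + params$detection_threshold * stats::mad(resp)
  cand <- which(local_maxima(resp) & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  # strongest-first suppression of candidates within min_separation_px
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
    keep[i] <- min(d2) >= params$min_separation_px^2
  }
  cand <- cand[keep, , drop = FALSE]

  r <- params$window_radius_px
  out <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    ys <- max(1L, cy - r):min(nrow(img), cy + r)
    xs <- max(1L, cx - r):min(ncol(img), cx + r)
    win <- img[ys, xs, drop = FALSE]
    # local background: median of the window border
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- stats::median(border)
    w <- pmax(win - bg, 0)
    tot <- sum(w)
    if (tot <= 0) {
      cyx <- c(cy, cx)
    } else {
      cyx <- c(sum(outer(ys, rep(1, length(xs))) * w),
               sum(outer(rep(1, length(ys)), xs) * w)) / tot
    }
    tibble::tibble(
      frame = as.integer(frame), channel = ch_name,
      y_px = cyx[1], x_px = cyx[2],
      y_nm = cyx[1] * stack$pixel_size_nm,
      x_nm = cyx[2] * stack$pixel_size_nm,
      peak_intensity = max(win),
      integrated_intensity = tot
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$peak_intensity))
}

#' Vesicle counts per frame
#'
#' Runs [detect_vesicles()] on every frame of a channel and reports one
#' count per frame with the physical time axis
#' (`(frame - 1) * frame_interval_s`).
#'
#' @inheritParams detect_vesicles
#' @return A tibble `(frame, time_s, count)`.
#' @export
count_vesicles_over_time <- function(stack, channel = 1,
                                     params = detection_params()) {
  purrr::map_dfr(seq_len(n_frames(stack)), function(t) {
    det <- detect_vesicles(stack, channel, t, params)
    tibble::tibble(
      frame = t,
      time_s = (t - 1) * stack$frame_interval_s,
      count = nrow(det)
    )
  })
}
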