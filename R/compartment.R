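#' Threshold a marker channel into a compartment mask
#'
#' Builds the binary endosomal-compartment mask from the marker channel
#' (e.g. a Rab GTPase or flotillin). The threshold method and value are
#' always recorded because downstream means depend on them. Otsu-derived
#' masks are invariant under positive scaling of the marker intensities.
#'
#' @param stack A [frame_stack()].
#' @param marker_channel Channel index or name.
#' @param frame Frame index.
#' @param method `"otsu"` (default), `"fixed"` or `"quantile"`.
#' @param value Threshold value (`"fixed"`, in intensity counts) or
#'   quantile (`"quantile"`).
#' @return An object of class `compartment_mask`: `mask` (logical Y x X),
#'   `threshold_value`, `method`, `marker_channel`, `frame`, `area_px`,
#'   `empty` (flag: no above-threshold pixels).
#' @export
threshold_compartment <- function(stack, marker_channel = 1, frame = 1,
                                  method = c("otsu", "fixed", "quantile"),
                                  value = NULL) {
  method <- match.arg(method)
  img <- frame_matrix(stack, marker_channel, frame)
  ch_name <- stack$channel_names[resolve_channel(stack, marker_channel)]
  rng <- range(img)
  thr <- switch(method,
    otsu = {
      if (diff(rng) == 0) {
        rng[2]  # flat image: nothing can exceed the threshold
      } else {
        norm <- (img - rng[1]) / diff(rng)
        t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                             levels = 256L)
        rng[1] + t01 * diff(rng)
      }
    },
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs `value`", call. = FALSE)
      value
    },
    quantile = {
      if (is.null(value)) value <- 0.95
      stats::quantile(img, value, names = FALSE)
    }
  )
  mask <- img > thr
  structure(
    list(
      mask = mask,
      threshold_value = as.numeric(thr),
      method = method,
      marker_channel = ch_name,
      frame = as.integer(frame),
      area_px = sum(mask),
      empty = !any(mask)
    ),
    class = "compartment_mask"
  )
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat(sprintf(
    "<compartment_mask> channel '%s' frame %d: %d px (%s threshold %.4g)%s\n",
    x$marker_channel, x$frame, x$area_px, x$method, x$threshold_value,
    if (x$empty) " [EMPTY]" else ""
  ))
  invisible(x)
}

#' Mean cargo intensity inside a compartment mask
#'
#' Restricts the cargo channel to the compartment mask and averages, after
#' setting sub-background cargo pixels to zero. The background is the
#' median cargo intensity outside the cell mask when one is supplied,
#' otherwise the median outside the compartment mask; subtraction is
#' clamped at zero. Out-of-mask pixels are excluded from the mean, not
#' counted as zeros — counting them would dilute the mean by mask area.
#' An empty mask yields `NA`, never zero.
#'
#' @param stack A [frame_stack()].
#' @param cargo_channel Channel index or name of the cargo (e.g.
#'   fluorescent transferrin).
#' @param mask A `compartment_mask` from [threshold_compartment()].
#' @param cell Optional `cell_region` used for the background estimate.
#' @param background `"auto"` (median outside cell/compartment, default),
#'   `"none"`, or a fixed numeric value.
#' @return Mean in-compartment cargo intensity (scalar; `NA` for an empty
#'   mask).
#' @export
mean_cargo_in_compartment <- function(stack, cargo_channel, mask,
                                      cell = NULL, background = "auto") {
  stopifnot(inherits(mask, "compartment_mask"))
  if (mask$empty) return(NA_real_)
  img <- frame_matrix(stack, cargo_channel, mask$frame)
  bg <- if (identical(background, "auto")) {
    outside <- if (!is.null(cell)) !cell$mask else !mask$mask
    if (any(outside)) stats::median(img[outside]) else 0
  } else if (identical(background, "none")) {
    0
  } else {
    as.numeric(background)
  }
  vals <- pmax(img[mask$mask] - bg, 0)
  mean(vals)
}

#' Cargo-in-compartment time course
#'
#' Per frame: threshold the marker channel into a compartment mask, then
#' average the background-zeroed cargo channel inside it. Frames whose mask
#' comes out empty carry `NA`.
#'
#' @inheritParams threshold_compartment
#' @param cargo_channel Cargo channel index or name.
#' @param per_movie Threshold once on the first frame and reuse that mask
#'   for all frames (`TRUE`), or threshold each frame independently
#'   (default `FALSE`).
#' @param cell Optional `cell_region` for the background estimate.
#' @return A tibble `(frame, time_s, mask_area_px, threshold, masked_mean)`.
#' @export
compartment_timecourse <- function(stack, marker_channel, cargo_channel,
                                   method = c("otsu", "fixed", "quantile"),
                                   value = NULL, per_movie = FALSE,
                                   cell = NULL) {
  method <- match.arg(method)
  fixed_mask <- if (per_movie) {
    threshold_compartment(stack, marker_channel, 1L, method, value)
  }
  purrr::map_dfr(seq_len(n_frames(stack)), function(t) {
    m <- if (per_movie) {
      fm <- fixed_mask
      fm$frame <- as.integer(t)
      fm
    } else {
      threshold_compartment(stack, marker_channel, t, method, value)
    }
    tibble::tibble(
      frame = t,
      time_s = (t - 1) * stack$frame_interval_s,
      mask_area_px = m$area_px,
      threshold = m$threshold_value,
      masked_mean = mean_cargo_in_compartment(stack, cargo_channel, m,
                                              cell = cell)
    )
  })
}

#' Pool per-cell compartment series into a grouped time series
#'
#' Stacks per-cell time courses from two experimental groups into the long
#' format consumed by [time_of_divergence()]: every cell contributes one
#' observation per timepoint, pooled within its group. Missing values
#' (frames with empty masks) are dropped listwise at their timepoint.
#'
#' @param series_list Named list of tibbles from [compartment_timecourse()]
#'   (names are cell ids).
#' @param groups Character vector, one group label per list element.
#' @return A tibble `(timepoint_index, time, group, cell_id, value)`.
#' @export
pool_compartment_series <- function(series_list, groups) {
  stopifnot(length(series_list) == length(groups))
  if (is.null(names(series_list))) {
    names(series_list) <- paste0("cell", seq_along(series_list))
  }
  purrr::map2_dfr(series_list, groups, function(s, g) {
    tibble::tibble(
      timepoint_index = s$frame,
      time = s$time_s,
      group = g,
      value = s$masked_mean
    )
  }, .id = "cell_id") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("timepoint_index", "time", "group", "cell_id", "value")
}
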