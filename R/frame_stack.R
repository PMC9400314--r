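#' Multi-channel time-lapse image stack
#'
#' `frame_stack()` wraps a 4-d intensity array together with the physical
#' calibration needed downstream: the pixel size in nanometres and the frame
#' interval in seconds. The array is stored `Y x X x C x T` (row = y,
#' column = x), the natural layout for R matrices; a pixel's centre sits at
#' its integer coordinate and all physical distances are obtained by
#' multiplying pixel coordinates by `pixel_size_nm`.
#'
#' @param data A numeric array. Accepted shapes: `Y x X` (one channel, one
#'   frame), `Y x X x C` (one frame) or `Y x X x C x T`. Intensities must be
#'   non-negative and finite.
#' @param pixel_size_nm Positive scalar, physical pixel size in nm.
#' @param frame_interval_s Positive scalar, time between frames in seconds.
#' @param channel_names Character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `frame_stack` with elements `data` (always
#'   4-d), `pixel_size_nm`, `frame_interval_s`, `channel_names`.
#' @examples
#' img <- matrix(rpois(64 * 64, 5), 64, 64)
#' fs <- frame_stack(img, pixel_size_nm = 160, frame_interval_s = 1)
#' dim(fs$data)
#' @export
frame_stack <- function(data, pixel_size_nm, frame_interval_s = 1,
                        channel_names = NULL) {
  if (!is.numeric(data)) stop("`data` must be a numeric array", call. = FALSE)
  d <- dim(data)
  if (is.null(d) || length(d) < 2 || length(d) > 4) {
    stop("`data` must have 2 to 4 dimensions (Y x X [x C [x T]])", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (length(d) == 2) dim(data) <- c(d, 1L, 1L)
  if (length(d) == 3) dim(data) <- c(d, 1L)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  stopifnot(
    "pixel_size_nm must be a positive scalar" =
      is.numeric(pixel_size_nm) && length(pixel_size_nm) == 1 && pixel_size_nm > 0,
    "frame_interval_s must be a positive scalar" =
      is.numeric(frame_interval_s) && length(frame_interval_s) == 1 && frame_interval_s > 0
  )
  n_ch <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch) {
    stop("`channel_names` length must match the number of channels", call. = FALSE)
  }
  structure(
    list(
      data = data,
      pixel_size_nm = as.numeric(pixel_size_nm),
      frame_interval_s = as.numeric(frame_interval_s),
      channel_names = as.character(channel_names)
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_stack> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ", "), d[4]
  ))
  cat(sprintf(
    "  pixel size %.4g nm, frame interval %.4g s\n",
    x$pixel_size_nm, x$frame_interval_s
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[4]
n_channels <- function(stack) dim(stack$data)[3]

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) {
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(stack$channel_names, collapse = ", ")), call. = FALSE)
    }
    return(idx)
  }
  channel <- as.integer(channel)
  if (channel < 1 || channel > n_channels(stack)) {
    stop(sprintf("channel index %d out of range 1..%d", channel,
                 n_channels(stack)), call. = FALSE)
  }
  channel
}

#' Extract one frame of one channel as a matrix
#'
#' @param stack A [frame_stack()].
#' @param channel Channel index or name.
#' @param frame Frame index (1-based).
#' @return A `Y x X` numeric matrix.
#' @export
frame_matrix <- function(stack, channel = 1, frame = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  ch <- resolve_channel(stack, channel)
  frame <- as.integer(frame)
  if (frame < 1 || frame > n_frames(stack)) {
    stop(sprintf("frame %d out of range 1..%d", frame, n_frames(stack)),
         call. = FALSE)
  }
  stack$data[, , ch, frame]
}

#' Write a frame stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are interleaved channel-fastest (page = (t-1)*C + c). Intensities
#' are divided by a stored scale factor so the 32-bit float TIFF stays in
#' \[0, 1\]; the scale, pixel size, frame interval and channel names go to a
#' `<path>.yaml` sidecar so [read_stack()] restores the object.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  scale <- max(stack$data, 1)
  pages <- list()
  for (t in seq_len(n_frames(stack))) {
    for (c in seq_len(n_channels(stack))) {
      pages[[length(pages) + 1L]] <- stack$data[, , c, t] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    pixel_size_nm = stack$pixel_size_nm,
    frame_interval_s = stack$frame_interval_s,
    channel_names = as.list(stack$channel_names),
    n_channels = n_channels(stack),
    n_frames = n_frames(stack),
    intensity_scale = scale
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.yaml` sidecar must sit next to it).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    stop("sidecar '", meta_path, "' not found", call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- meta$n_channels
  nt <- meta$n_frames
  if (length(pages) != nc * nt) {
    stop("page count does not match sidecar metadata", call. = FALSE)
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], nc, nt))
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      arr[, , c, t] <- pages[[(t - 1L) * nc + c]] * meta$intensity_scale
    }
  }
  frame_stack(arr,
              pixel_size_nm = meta$pixel_size_nm,
              frame_interval_s = meta$frame_interval_s,
              channel_names = unlist(meta$channel_names))
}
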