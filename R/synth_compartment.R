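#' Generate a synthetic marker-compartment movie with cargo signal
#'
#' Emulates a two-channel movie in which a marker channel (e.g. a Rab
#' GTPase) shows a few bright, thresholdable endosomal compartments —
#' rendered as soft-edged disks so any threshold between background and
#' plateau recovers the same area — and a cargo channel whose in-compartment
#' intensity follows a configurable per-frame amplitude (e.g. a linear ramp
#' as cargo accumulates).
#'
#' @param image_size_px `(Y, X)` image size.
#' @param n_blobs Number of compartment blobs.
#' @param blob_radius_px Blob radius in px.
#' @param marker_level Marker plateau amplitude above background (counts).
#' @param cargo_levels Numeric vector, one in-compartment cargo amplitude
#'   per frame; its length sets the frame count.
#' @param background_level Mean background counts per pixel (both channels).
#' @param read_noise_sd Read-noise SD in counts.
#' @param pixel_size_nm Pixel size in nm.
#' @param seed Integer seed.
#' @return A list with `stack` (channels `"marker"`, `"cargo"`) and `truth`
#'   (blob centre tibble, the true binary `mask`, its `area_px`, and the
#'   `cargo_levels` used).
#' @export
generate_compartment_series <- function(image_size_px = c(96L, 96L),
                                        n_blobs = 3L,
                                        blob_radius_px = 6,
                                        marker_level = 400,
                                        cargo_levels = seq(50, 400, length.out = 10),
                                        background_level = 50,
                                        read_noise_sd = 3,
                                        pixel_size_nm = 160,
                                        seed = 1L) {
  stopifnot(n_blobs >= 1, blob_radius_px > 0, marker_level > 0)
  n_frames <- length(cargo_levels)
  withr::with_seed(seed, {
    sz <- as.integer(image_size_px)
    margin <- blob_radius_px + 6
    # rejection-sample blob centres so blobs never touch
    centres <- matrix(numeric(0), ncol = 2)
    for (b in seq_len(n_blobs)) {
      for (try in 1:2000) {
        pos <- c(stats::runif(1, margin, sz[1] - margin),
                 stats::runif(1, margin, sz[2] - margin))
        if (nrow(centres) == 0 ||
            min(sqrt((centres[, 1] - pos[1])^2 +
                     (centres[, 2] - pos[2])^2)) > 2.5 * blob_radius_px + 4) {
          centres <- rbind(centres, pos)
          break
        }
      }
      if (nrow(centres) < b) {
        stop("could not place blobs without overlap", call. = FALSE)
      }
    }
    yy <- matrix(seq_len(sz[1]), sz[1], sz[2])
    xx <- matrix(seq_len(sz[2]), sz[1], sz[2], byrow = TRUE)
    profile <- matrix(0, sz[1], sz[2])
    for (b in seq_len(n_blobs)) {
      rr <- sqrt((yy - centres[b, 1])^2 + (xx - centres[b, 2])^2)
      profile <- profile + 1 / (1 + exp((rr - blob_radius_px) / 0.5))
    }
    profile[profile > 1] <- 1
    true_mask <- profile > 0.5

    clean <- array(0, dim = c(sz[1], sz[2], 2L, n_frames))
    for (t in seq_len(n_frames)) {
      clean[, , 1, t] <- background_level + marker_level * profile
      clean[, , 2, t] <- background_level + cargo_levels[t] * profile
    }
    noisy <- array(0, dim = dim(clean))
    for (t in seq_len(n_frames)) {
      for (ch in 1:2) {
        noisy[, , ch, t] <- apply_noise(clean[, , ch, t], read_noise_sd)
      }
    }
    stack <- frame_stack(noisy, pixel_size_nm = pixel_size_nm,
                         channel_names = c("marker", "cargo"))
    truth <- list(
      blobs = tibble::tibble(blob_id = seq_len(n_blobs),
                             y_px = centres[, 1], x_px = centres[, 2],
                             radius_px = blob_radius_px),
      mask = true_mask,
      area_px = sum(true_mask),
      cargo_levels = cargo_levels,
      background_level = background_level
    )
    list(stack = stack, truth = truth)
  })
}
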