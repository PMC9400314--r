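#' Configuration for the synthetic cell-image generator
#'
#' Collects every parameter of the simulated acquisition: geometry of the
#' roughly disk-shaped cell, number of diffraction-limited vesicle spots per
#' channel, the imposed cross-channel co-positioning, the radial spot
#' distribution, the PSF width and the noise model (Poisson shot noise plus
#' additive Gaussian read noise, the behaviour of the sCMOS/PMT detectors
#' such data comes from).
#'
#' Spot radii about the cell centre are drawn from a scaled Beta
#' distribution with mean `dispersion_scale` (as a fraction of the usable
#' cell radius), so the generator's dispersion knob maps monotonically onto
#' the dispersion statistic measured downstream.
#'
#' The number of co-positioned channel-2 spots is `round(coloc_fraction *
#' n_vesicles_per_channel[2])` — imposed exactly, not sampled. Each paired
#' spot is placed within `coloc_offset_nm` of a distinct channel-1 spot
#' (exactly on top of it when the offset is 0); the remaining channel-2
#' spots are rejection-sampled to lie farther than `exclusion_nm` from every
#' channel-1 spot, so the true colocalization fraction is exact.
#'
#' @param image_size_px Integer `(Y, X)` image size, default `c(128, 128)`.
#' @param pixel_size_nm Pixel size in nm; the default 160 nm puts the
#'   320 nm colocalization cutoff at two pixels, typical confocal sampling.
#' @param cell_radius_px Cell radius in px.
#' @param cell_center_px `(y, x)` cell centre; default image centre.
#' @param n_vesicles_per_channel Integer vector, spots per channel.
#' @param coloc_fraction Fraction in `[0, 1]` of channel-2 spots
#'   co-positioned with channel-1 spots.
#' @param coloc_offset_nm Maximum true pair offset in nm.
#' @param exclusion_nm Minimum distance of non-paired channel-2 spots from
#'   every channel-1 spot; default twice the 320 nm cutoff so chance
#'   colocalization among unpaired spots is excluded by construction.
#' @param min_spacing_nm Minimum same-channel spot spacing (keeps spots
#'   individually resolvable).
#' @param dispersion_scale Mean radial spot position as a fraction of the
#'   usable cell radius, in `(0, 1)`.
#' @param psf_sigma_px Gaussian PSF sigma in px.
#' @param spot_photons Expected total photons per spot.
#' @param background_level Mean background photon count per pixel.
#' @param cell_level Additional mean photon count inside the cell body.
#' @param read_noise_sd SD of the additive Gaussian read noise (counts).
#' @param n_frames Number of frames.
#' @param appearance `"all"` (every spot in every frame) or `"cumulative"`
#'   (spot j of a channel appears from frame j onward, emulating vesicles
#'   forming one per frame).
#' @param channel_names Channel labels.
#' @return A list of class `synth_image_config`.
#' @export
synth_image_config <- function(image_size_px = c(128L, 128L),
                               pixel_size_nm = 160,
                               cell_radius_px = 40,
                               cell_center_px = NULL,
                               n_vesicles_per_channel = c(12L, 12L),
                               coloc_fraction = 0,
                               coloc_offset_nm = 0,
                               exclusion_nm = 640,
                               min_spacing_nm = 800,
                               dispersion_scale = 0.5,
                               psf_sigma_px = 1.3,
                               spot_photons = 1e4,
                               background_level = 100,
                               cell_level = 60,
                               read_noise_sd = 3,
                               n_frames = 1L,
                               appearance = c("all", "cumulative"),
                               channel_names = c("ch1", "ch2")) {
  appearance <- match.arg(appearance)
  if (is.null(cell_center_px)) cell_center_px <- (image_size_px + 1) / 2
  stopifnot(
    "coloc_fraction must lie in [0, 1]" =
      coloc_fraction >= 0 && coloc_fraction <= 1,
    "pixel_size_nm must be positive" = pixel_size_nm > 0,
    "cell_radius_px must be positive" = cell_radius_px > 0,
    "psf_sigma_px must be positive" = psf_sigma_px > 0,
    "dispersion_scale must lie in (0, 1)" =
      dispersion_scale > 0 && dispersion_scale < 1,
    "coloc_offset_nm must be non-negative" = coloc_offset_nm >= 0,
    "n_vesicles_per_channel must be non-negative" =
      all(n_vesicles_per_channel >= 0),
    "need one count and one name per channel" =
      length(n_vesicles_per_channel) == length(channel_names)
  )
  structure(
    list(
      image_size_px = as.integer(image_size_px),
      pixel_size_nm = pixel_size_nm,
      cell_radius_px = cell_radius_px,
      cell_center_px = as.numeric(cell_center_px),
      n_vesicles_per_channel = as.integer(n_vesicles_per_channel),
      coloc_fraction = coloc_fraction,
      coloc_offset_nm = coloc_offset_nm,
      exclusion_nm = exclusion_nm,
      min_spacing_nm = min_spacing_nm,
      dispersion_scale = dispersion_scale,
      psf_sigma_px = psf_sigma_px,
      spot_photons = spot_photons,
      background_level = background_level,
      cell_level = cell_level,
      read_noise_sd = read_noise_sd,
      n_frames = as.integer(n_frames),
      appearance = appearance,
      channel_names = channel_names
    ),
    class = "synth_image_config"
  )
}

# Add a 2-D Gaussian spot (total integral = photons) into `img` in place.
add_gaussian_spot <- function(img, y, x, sigma, photons) {
  half <- ceiling(5 * sigma)
  ys <- max(1L, floor(y - half)):min(nrow(img), ceiling(y + half))
  xs <- max(1L, floor(x - half)):min(ncol(img), ceiling(x + half))
  amp <- photons / (2 * pi * sigma^2)
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
  img
}

# Poisson shot noise plus Gaussian read noise, clamped at zero.
apply_noise <- function(clean, read_noise_sd) {
  n <- length(clean)
  noisy <- stats::rpois(n, lambda = as.vector(clean)) +
    stats::rnorm(n, 0, read_noise_sd)
  noisy[noisy < 0] <- 0
  array(noisy, dim = dim(clean))
}

# Draw one spot position from the radial Beta model; rejection-sample
# against the `keepout` predicate. Errors out when placement is infeasible.
draw_position <- function(config, keepout = NULL, max_tries = 5000L) {
  r_max <- config$cell_radius_px - 3 * config$psf_sigma_px
  if (r_max <= 0) stop("cell too small for the configured PSF", call. = FALSE)
  k <- 4
  s <- config$dispersion_scale
  for (i in seq_len(max_tries)) {
    r <- r_max * stats::rbeta(1, k * s, k * (1 - s))
    th <- stats::runif(1, 0, 2 * pi)
    pos <- config$cell_center_px + r * c(sin(th), cos(th))
    if (is.null(keepout) || !keepout(pos)) return(pos)
  }
  stop("spot placement infeasible: could not satisfy spacing constraints ",
       "for the configured cell area and spot count", call. = FALSE)
}

min_dist_nm <- function(pos, others_px, pixel_size_nm) {
  if (is.null(others_px) || nrow(others_px) == 0) return(Inf)
  sqrt(min((others_px[, 1] - pos[1])^2 + (others_px[, 2] - pos[2])^2)) *
    pixel_size_nm
}

#' Generate a synthetic two-channel cell image with ground truth
#'
#' Renders a disk-shaped cell on a noisy background and populates it with
#' diffraction-limited vesicle spots (2-D Gaussians) in each channel, with an
#' exactly imposed fraction of channel-2 spots co-positioned with channel-1
#' spots. All randomness flows from one seeded generator, so identical
#' config + seed gives bit-identical output.
#'
#' @param config A [synth_image_config()].
#' @param seed Integer seed.
#' @return A list with elements `stack` (a [frame_stack()]) and `truth`, a
#'   list holding `spots` (tibble: channel, spot_id, frame_first, y/x in px
#'   and nm, photons, pair_id), `cell` (centre and radius), `clean` (the
#'   noise-free array) and the generating `config`.
#' @export
generate_cell_image <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_image_config"))
  withr::with_seed(seed, generate_cell_image_impl(config))
}

generate_cell_image_impl <- function(config) {
  px <- config$pixel_size_nm
  n_ch <- length(config$n_vesicles_per_channel)
  sz <- config$image_size_px

  placed <- vector("list", n_ch)
  # channel 1 (and any channel beyond 2): independent placement with
  # same-channel spacing
  for (ch in seq_len(n_ch)[-2]) {
    pts <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(config$n_vesicles_per_channel[ch])) {
      pos <- draw_position(config, keepout = function(p) {
        min_dist_nm(p, pts, px) <= config$min_spacing_nm
      })
      pts <- rbind(pts, pos)
    }
    placed[[ch]] <- pts
  }
  # channel 2: paired spots first (exact count), then excluded spots
  if (n_ch >= 2) {
    n_b <- config$n_vesicles_per_channel[2]
    n_pair <- round(config$coloc_fraction * n_b)
    a_pts <- placed[[1]]
    if (n_pair > nrow(a_pts)) {
      stop("coloc_fraction requires more pairs than channel-1 spots exist",
           call. = FALSE)
    }
    pair_with <- if (n_pair > 0) sample(nrow(a_pts), n_pair) else integer(0)
    b_pts <- matrix(numeric(0), ncol = 2)
    b_pair_id <- integer(0)
    for (j in seq_len(n_pair)) {
      anchor <- a_pts[pair_with[j], ]
      if (config$coloc_offset_nm == 0) {
        pos <- anchor
      } else {
        d <- config$coloc_offset_nm * sqrt(stats::runif(1)) / px
        th <- stats::runif(1, 0, 2 * pi)
        pos <- anchor + d * c(sin(th), cos(th))
      }
      b_pts <- rbind(b_pts, pos)
      b_pair_id <- c(b_pair_id, pair_with[j])
    }
    for (j in seq_len(n_b - n_pair)) {
      pos <- draw_position(config, keepout = function(p) {
        min_dist_nm(p, a_pts, px) <= config$exclusion_nm ||
          min_dist_nm(p, b_pts, px) <= config$min_spacing_nm
      })
      b_pts <- rbind(b_pts, pos)
      b_pair_id <- c(b_pair_id, NA_integer_)
    }
    placed[[2]] <- b_pts
    attr(placed[[2]], "pair_id") <- b_pair_id
  }

  spots <- purrr::map_dfr(seq_len(n_ch), function(ch) {
    pts <- placed[[ch]]
    n <- nrow(pts)
    if (n == 0) {
      return(tibble::tibble(
        channel = character(0), spot_id = integer(0), frame_first = integer(0),
        y_px = numeric(0), x_px = numeric(0), y_nm = numeric(0),
        x_nm = numeric(0), photons = numeric(0), pair_id = integer(0)
      ))
    }
    pid <- attr(pts, "pair_id")
    if (is.null(pid)) pid <- rep(NA_integer_, n)
    tibble::tibble(
      channel = config$channel_names[ch],
      spot_id = seq_len(n),
      frame_first = if (config$appearance == "cumulative") seq_len(n) else 1L,
      y_px = pts[, 1], x_px = pts[, 2],
      y_nm = pts[, 1] * px, x_nm = pts[, 2] * px,
      photons = rep_len(config$spot_photons, n),
      pair_id = pid
    )
  })

  # cell body: disk with a softened rim (half-pixel logistic edge)
  yy <- matrix(seq_len(sz[1]), sz[1], sz[2])
  xx <- matrix(seq_len(sz[2]), sz[1], sz[2], byrow = TRUE)
  rr <- sqrt((yy - config$cell_center_px[1])^2 +
             (xx - config$cell_center_px[2])^2)
  body <- config$background_level +
    config$cell_level / (1 + exp((rr - config$cell_radius_px) / 0.5))

  clean <- array(0, dim = c(sz[1], sz[2], n_ch, config$n_frames))
  for (t in seq_len(config$n_frames)) {
    for (ch in seq_len(n_ch)) {
      img <- body
      sp <- spots[spots$channel == config$channel_names[ch] &
                  spots$frame_first <= t, ]
      for (j in seq_len(nrow(sp))) {
        img <- add_gaussian_spot(img, sp$y_px[j], sp$x_px[j],
                                 config$psf_sigma_px, sp$photons[j])
      }
      clean[, , ch, t] <- img
    }
  }
  noisy <- array(0, dim = dim(clean))
  for (t in seq_len(config$n_frames)) {
    for (ch in seq_len(n_ch)) {
      noisy[, , ch, t] <- apply_noise(clean[, , ch, t], config$read_noise_sd)
    }
  }

  stack <- frame_stack(noisy, pixel_size_nm = px,
                       channel_names = config$channel_names)
  truth <- list(
    spots = spots,
    cell = list(center_px = config$cell_center_px,
                radius_px = config$cell_radius_px),
    clean = clean,
    config = config
  )
  list(stack = stack, truth = truth)
}
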