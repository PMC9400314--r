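cfg_small <- function(n_vesicles_per_channel = c(8L, 8L), ...) {
  synth_image_config(image_size_px = c(96L, 96L), cell_radius_px = 32,
                     n_vesicles_per_channel = n_vesicles_per_channel, ...)
}

test_that("same config and seed give bit-identical stacks and truth", {
  cfg <- cfg_small(coloc_fraction = 0.5)
  a <- generate_cell_image(cfg, seed = 11)
  b <- generate_cell_image(cfg, seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$spots, b$truth$spots)
  c <- generate_cell_image(cfg, seed = 12)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("imposed colocalization fraction is exact and pairs are tight", {
  for (f in c(0, 0.25, 0.5, 1)) {
    sim <- generate_cell_image(cfg_small(coloc_fraction = f,
                                         coloc_offset_nm = 200), seed = 3)
    sp <- sim$truth$spots
    b <- sp[sp$channel == "ch2", ]
    expect_equal(sum(!is.na(b$pair_id)), round(f * 8))
    a <- sp[sp$channel == "ch1", ]
    for (i in which(!is.na(b$pair_id))) {
      mate <- a[a$spot_id == b$pair_id[i], ]
      d <- sqrt((b$y_nm[i] - mate$y_nm)^2 + (b$x_nm[i] - mate$x_nm)^2)
      expect_lte(d, 200)
    }
    # unpaired channel-2 spots sit beyond the exclusion radius from all
    # channel-1 spots
    for (i in which(is.na(b$pair_id))) {
      d <- sqrt((b$y_nm[i] - a$y_nm)^2 + (b$x_nm[i] - a$x_nm)^2)
      expect_gt(min(d), sim$truth$config$exclusion_nm)
    }
  }
})

test_that("coloc_fraction 1 with offset 0 duplicates channel-1 positions", {
  sim <- generate_cell_image(cfg_small(coloc_fraction = 1,
                                       coloc_offset_nm = 0), seed = 5)
  sp <- sim$truth$spots
  a <- sp[sp$channel == "ch1", c("y_px", "x_px")]
  b <- sp[sp$channel == "ch2", c("y_px", "x_px")]
  perm <- match(
    paste(signif(b$y_px, 12), signif(b$x_px, 12)),
    paste(signif(a$y_px, 12), signif(a$x_px, 12))
  )
  expect_false(any(is.na(perm)))
})

test_that("all true spots lie inside the cell and photons integrate", {
  sim <- generate_cell_image(cfg_small(), seed = 9)
  sp <- sim$truth$spots
  ctr <- sim$truth$cell$center_px
  r <- sqrt((sp$y_px - ctr[1])^2 + (sp$x_px - ctr[2])^2)
  expect_true(all(r < sim$truth$cell$radius_px))

  # rendered photon count per spot: clean image minus background/cell body
  cfg1 <- synth_image_config(image_size_px = c(64L, 64L), cell_radius_px = 20,
                             n_vesicles_per_channel = c(1L, 0L),
                             spot_photons = 1e4)
  sim1 <- generate_cell_image(cfg1, seed = 2)
  cfg0 <- cfg1
  cfg0$n_vesicles_per_channel <- c(0L, 0L)
  sim0 <- generate_cell_image(cfg0, seed = 2)
  rendered <- sum(sim1$truth$clean[, , 1, 1] - sim0$truth$clean[, , 1, 1])
  expect_lt(abs(rendered / 1e4 - 1), 0.01)
})

test_that("zero-vesicle config yields pure background plus cell body", {
  sim <- generate_cell_image(cfg_small(n_vesicles_per_channel = c(0L, 0L)),
                             seed = 1)
  expect_equal(nrow(sim$truth$spots), 0)
  expect_lt(max(sim$truth$clean),
            sim$truth$config$background_level +
              sim$truth$config$cell_level + 1)
})

test_that("infeasible spot packing errors out", {
  cfg <- synth_image_config(image_size_px = c(64L, 64L), cell_radius_px = 10,
                            n_vesicles_per_channel = c(80L, 0L),
                            min_spacing_nm = 2000)
  expect_error(generate_cell_image(cfg, seed = 1), "infeasible")
})

test_that("TIRF generator imposes labels exactly and respects n_frames", {
  s1 <- generate_tirf_series(n_events = 20, cofusion_rate = 1, seed = 4)
  expect_true(all(s1$truth$events$cofusion))
  s0 <- generate_tirf_series(n_events = 20, cofusion_rate = 0, seed = 4)
  expect_false(any(s0$truth$events$cofusion))
  expect_error(generate_tirf_series(n_frames = 3, seed = 1), "at least 4")
  expect_error(generate_tirf_series(cofusion_rate = 1.2, seed = 1),
               "cofusion_rate")

  a <- generate_tirf_series(n_events = 10, seed = 6)
  b <- generate_tirf_series(n_events = 10, seed = 6)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("grouped time series carries its truth and validates input", {
  sim <- generate_grouped_timeseries(n_per_group = 10,
                                     timepoints = seq(0, 50, 10),
                                     shift_start_index = 3,
                                     effect_size = 2, noise_sd = 0.5,
                                     seed = 8)
  expect_equal(sim$truth$divergence_index, 3L)
  expect_equal(nrow(sim$series), 6 * 20)
  # shift applied from the stated index onward
  means <- sim$series |>
    dplyr::group_by(timepoint_index, group) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m)
  expect_true(all((means$B - means$A)[3:6] > 1))
  expect_true(all(abs((means$B - means$A)[1:2]) < 1))

  null_sim <- generate_grouped_timeseries(effect_size = 0, seed = 1)
  expect_true(is.na(null_sim$truth$divergence_index))
  expect_error(generate_grouped_timeseries(n_per_group = 0, seed = 1),
               "positive")
  expect_error(generate_grouped_timeseries(shift_start_index = 99, seed = 1),
               "shift_start_index")
})

test_that("compartment movie has thresholdable blobs with known mask", {
  sim <- generate_compartment_series(seed = 2)
  expect_gt(sim$truth$area_px, 0)
  expect_equal(dim(sim$stack$data)[4], length(sim$truth$cargo_levels))
  a <- generate_compartment_series(seed = 2)
  expect_identical(a$stack$data, sim$stack$data)
})
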