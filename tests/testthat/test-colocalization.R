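test_that("nearest-neighbour distances equal the exhaustive oracle exactly", {
  set.seed(31)
  for (rep in 1:10) {
    ref <- random_points(sample(5:50, 1), c(128, 128))
    qry <- random_points(sample(5:50, 1), c(128, 128))
    expect_identical(nn_distances(ref, qry), oracle_nn(ref, qry))
  }
})

test_that("forced geometries give forced distances", {
  a <- tibble::tibble(y_nm = c(0, 100), x_nm = c(0, 50))
  expect_equal(nn_distances(a, a), c(0, 0))
  one <- tibble::tibble(y_nm = 0, x_nm = 0)
  other <- tibble::tibble(y_nm = 0, x_nm = 320)
  expect_equal(nn_distances(one, other), 320)
  expect_error(nn_distances(one, one[0, ]), "no cross-channel objects")
})

test_that("double-positive boundary is inclusive and percent is a recount", {
  res <- classify_double_positive(c(0, 320, 320.1), coloc_params())
  expect_equal(res$double_positive, c(TRUE, TRUE, FALSE))
  expect_equal(res$percent_double_positive, 200 / 3, tolerance = 1e-10)

  expect_equal(
    classify_double_positive(rep(0, 7))$percent_double_positive, 100)
  expect_error(classify_double_positive(numeric(0)), "no distances")

  set.seed(5)
  for (rep in 1:10) {
    d <- runif(40, 0, 800)
    res <- classify_double_positive(d)
    n_manual <- 0
    for (x in d) if (x <= 320) n_manual <- n_manual + 1
    expect_equal(res$percent_double_positive, 100 * n_manual / length(d))
  }
})

test_that("percent double-positive is non-decreasing in the cutoff", {
  set.seed(9)
  d <- runif(60, 0, 1500)
  pcts <- vapply(seq(50, 1500, by = 50), function(cut) {
    classify_double_positive(d, coloc_params(cutoff_nm = cut))$percent_double_positive
  }, numeric(1))
  expect_false(is.unsorted(pcts))
})

test_that("nn distances are invariant under translation and rotation", {
  set.seed(17)
  ref <- random_points(20, c(100, 100))
  qry <- random_points(25, c(100, 100))
  base <- nn_distances(ref, qry)
  mv <- function(df, dy, dx, th) {
    y <- df$y_nm + dy; x <- df$x_nm + dx
    tibble::tibble(y_nm = cos(th) * y - sin(th) * x,
                   x_nm = sin(th) * y + cos(th) * x)
  }
  expect_equal(nn_distances(mv(ref, 500, -300, 0.7), mv(qry, 500, -300, 0.7)),
               base, tolerance = 1e-9)
})

test_that("random control matches the Monte-Carlo-corrected closed form", {
  R <- 50
  mask <- matrix(FALSE, 110, 110)
  yy <- row(mask); xx <- col(mask)
  mask[(yy - 55)^2 + (xx - 55)^2 <= R^2] <- TRUE
  cell <- cell_region_from_mask(mask, pixel_size_nm = 100)
  m <- 40  # query points
  params <- coloc_params(cutoff_nm = 320, n_random_iterations = 150, seed = 2)
  ctrl <- random_control(cell, 40, m, params)

  # closed form, edge effects ignored: 100 * (1 - (1 - pi d^2 / A)^m)
  A <- sum(mask) * 100^2
  closed <- 100 * (1 - (1 - pi * 320^2 / A)^m)

  # independent Monte-Carlo oracle with plain rejection sampling
  set.seed(99)
  orc <- replicate(300, {
    draw <- function(n) {
      pts <- matrix(nrow = 0, ncol = 2)
      while (nrow(pts) < n) {
        y <- runif(1, 5, 105); x <- runif(1, 5, 105)
        if ((y - 55)^2 + (x - 55)^2 <= R^2) pts <- rbind(pts, c(y, x))
      }
      pts * 100
    }
    r <- draw(40); q <- draw(m)
    d2 <- outer(r[, 1], q[, 1], "-")^2 + outer(r[, 2], q[, 2], "-")^2
    100 * mean(sqrt(apply(d2, 1, min)) <= 320)
  })
  se <- sqrt(ctrl$se_percent^2 + var(orc) / length(orc))
  expect_lt(abs(ctrl$mean_percent - mean(orc)), 3 * se)
  # the raw closed form is itself close (edge effects are small at d << R)
  expect_lt(abs(ctrl$mean_percent - closed), max(3 * se, 0.075 * closed))
})

test_that("a cutoff beyond the cell diameter forces a 100% control", {
  mask <- matrix(FALSE, 40, 40)
  mask[15:25, 15:25] <- TRUE
  cell <- cell_region_from_mask(mask, pixel_size_nm = 100)
  ctrl <- random_control(cell, 5, 5,
                         coloc_params(cutoff_nm = 1e5,
                                      n_random_iterations = 20, seed = 3))
  expect_true(all(ctrl$percent == 100))
})

test_that("observed colocalization beats chance when truly imposed", {
  cfg <- synth_image_config(coloc_fraction = 0.75, coloc_offset_nm = 0)
  sim <- generate_cell_image(cfg, seed = 21)
  d1 <- detect_vesicles(sim$stack, 1, 1)
  d2 <- detect_vesicles(sim$stack, 2, 1)
  cell <- segment_cell(sim$stack, 1, 1)
  obs <- classify_double_positive(nn_distances(d2, d1))
  ctrl <- random_control(cell, nrow(d2), nrow(d1),
                         coloc_params(n_random_iterations = 50, seed = 4))
  expect_gt(obs$percent_double_positive, ctrl$mean_percent)
})

test_that("tidy and glance expose the nn result as tibbles", {
  res <- classify_double_positive(c(10, 500))
  expect_equal(nrow(tidy(res)), 2)
  g <- glance(res)
  expect_equal(g$percent_double_positive, 50)
  expect_equal(g$cutoff_nm, 320)
})
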