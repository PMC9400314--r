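test_that("activated/resting fold change matches hand arithmetic", {
  tab <- tibble::tibble(
    condition = c("activated", "resting"),
    median_fi = c(150, 100)
  )
  expect_equal(fold_change_activated_vs_resting(tab), 1.5)

  same <- tibble::tibble(condition = c("activated", "resting"),
                         median_fi = c(88, 88))
  expect_equal(fold_change_activated_vs_resting(same), 1)

  # with unstained subtraction first: (150-10)/(100-20) = 1.75
  toy <- tibble::tibble(
    condition = c("activated", "activated", "resting", "resting"),
    stain = c("stained", "unstained", "stained", "unstained"),
    median_fi = c(150, 10, 100, 20)
  )
  expect_equal(
    fold_change_activated_vs_resting(toy, subtract_unstained = TRUE),
    (150 - 10) / (100 - 20)
  )
  # replicates are averaged before the ratio
  reps <- tibble::tibble(
    condition = c("activated", "activated", "resting"),
    median_fi = c(140, 160, 100)
  )
  expect_equal(fold_change_activated_vs_resting(reps), 1.5)

  bad <- tibble::tibble(condition = c("activated", "resting"),
                        median_fi = c(5, 0))
  expect_error(fold_change_activated_vs_resting(bad), "positive")
})

test_that("timepoint filtering picks the matched rows", {
  tab <- tibble::tibble(
    condition = rep(c("activated", "resting"), 2),
    timepoint = c(0, 0, 5, 5),
    median_fi = c(100, 100, 149, 100)
  )
  expect_equal(fold_change_activated_vs_resting(tab, timepoint = 0), 1)
  expect_equal(fold_change_activated_vs_resting(tab, timepoint = 5), 1.49)
})

test_that("recycling series is referenced to t = 0 and scale-invariant", {
  tab <- tibble::tibble(timepoint = c(0, 5, 10), median_fi = c(100, 150, 120))
  res <- recycling_relative_to_t0(tab)
  expect_equal(res$fold_vs_t0, c(1, 1.5, 1.2))

  scaled <- dplyr::mutate(tab, median_fi = median_fi * 7.3)
  expect_equal(recycling_relative_to_t0(scaled)$fold_vs_t0, res$fold_vs_t0)

  expect_error(recycling_relative_to_t0(
    tibble::tibble(timepoint = c(5, 10), median_fi = c(1, 2))), "t = 0")
})

test_that("treated/control normalization is a plain guarded ratio", {
  expect_equal(normalize_to_control(135, 100), 1.35)
  expect_equal(normalize_to_control(88, 88), 1)
  expect_equal(normalize_to_control(c(10, 20), c(5, 8)), c(2, 2.5))
  expect_error(normalize_to_control(10, 0), "positive")
})

test_that("conjugate fraction follows the minority rule with -SEE subtraction", {
  res <- conjugate_fraction(4000, 5000, 500,
                            control_singles_t = 4410,
                            control_singles_b = 5000,
                            control_conjugates = 90)
  expect_equal(res$raw_percent, 100 * 500 / 4500)
  expect_equal(res$control_percent, 2.0)
  expect_equal(res$percent, 100 * 500 / 4500 - 2.0)

  # no conjugates anywhere -> 0
  expect_equal(conjugate_fraction(100, 100, 0, 100, 100, 0)$percent, 0)
  # equal raw percentages cancel exactly
  eq <- conjugate_fraction(1000, 2000, 100, 1000, 2000, 100)
  expect_equal(eq$percent, 0)
  # negative corrected values are reported, not clamped
  neg <- conjugate_fraction(1000, 2000, 10, 1000, 2000, 100)
  expect_lt(neg$percent, 0)
  expect_error(conjugate_fraction(0, 10, 0), "minority")
})

test_that("conjugate fraction is symmetric in which dye marks which cell", {
  set.seed(67)
  for (rep in 1:10) {
    st <- sample(500:5000, 1); sb <- sample(500:5000, 1)
    cj <- sample(0:400, 1)
    a <- conjugate_fraction(st, sb, cj)
    b <- conjugate_fraction(sb, st, cj)
    expect_equal(a$percent, b$percent)
  }
})

test_that("band normalization matches hand arithmetic and ignores actin units", {
  single <- tibble::tibble(lane = 1, target = 123, actin = 456)
  expect_equal(normalize_bands(single)$normalized, 1)

  two <- tibble::tibble(lane = 1:2, target = c(100, 50), actin = c(100, 100))
  expect_equal(normalize_bands(two)$normalized, c(1, 0.5))

  set.seed(71)
  tab <- tibble::tibble(lane = 1:5, target = runif(5, 10, 100),
                        actin = runif(5, 50, 150))
  base <- normalize_bands(tab)$normalized
  doubled <- dplyr::mutate(tab, actin = actin * 2)
  expect_equal(normalize_bands(doubled)$normalized, base)
  rescaled <- dplyr::mutate(tab, target = target * 3.7)
  expect_equal(normalize_bands(rescaled)$normalized, base)

  expect_error(normalize_bands(
    tibble::tibble(lane = 1, target = 1, actin = 0)), "actin")
})

test_that("blots normalize independently when several are supplied", {
  tab <- tibble::tibble(
    blot = rep(c("b1", "b2"), each = 2),
    lane = c(1, 2, 1, 2),
    target = c(100, 50, 10, 5),
    actin = c(100, 100, 20, 20)
  )
  res <- normalize_bands(tab)
  expect_equal(res$normalized, c(1, 0.5, 1, 0.5))
})
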