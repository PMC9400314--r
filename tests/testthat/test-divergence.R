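test_that("rank-sum p-values match exact enumeration on canonical cases", {
  p <- ranksum_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(as.numeric(p), 0.1)
  expect_equal(attr(p, "method"), "exact")
  expect_equal(as.numeric(p), oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6)))

  # identical samples carry zero evidence
  expect_equal(as.numeric(ranksum_p(c(1.5, 2.5), c(1.5, 2.5))), 1)
  expect_error(ranksum_p(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration agrees with the package across random draws", {
  set.seed(47)
  for (rep in 1:25) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    a <- round(runif(m, 0, 100), 6)
    b <- round(runif(n, 0, 100), 6)
    p <- ranksum_p(a, b)
    expect_equal(attr(p, "method"), "exact")
    expect_equal(as.numeric(p), oracle_ranksum_exact(a, b), tolerance = 1e-12)
  }
})

test_that("normal approximation stays within 0.05 of the exact value", {
  set.seed(53)
  for (rep in 1:50) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    a <- runif(m); b <- runif(n, 0.2, 1.2)
    p_norm <- ranksum_p(a, b, method = "normal")
    expect_lte(abs(as.numeric(p_norm) - oracle_ranksum_exact(a, b)), 0.05)
  }
})

test_that("ties and large samples switch to the corrected approximation", {
  p <- ranksum_p(c(1, 2, 2, 3), c(2, 4, 5))
  expect_equal(attr(p, "method"), "normal")
  p2 <- ranksum_p(rnorm(25), rnorm(25))
  expect_equal(attr(p2, "method"), "normal")
})

test_that("p-values are rank-based: monotone-invariant and label-symmetric", {
  set.seed(59)
  a <- rnorm(8); b <- rnorm(9, 0.8)
  base <- as.numeric(ranksum_p(a, b))
  expect_equal(as.numeric(ranksum_p(exp(a), exp(b))), base)
  expect_equal(as.numeric(ranksum_p(a^3, b^3)), base)
  expect_equal(as.numeric(ranksum_p(b, a)), base)
})

series_from_p <- function(p_wanted, n = 12) {
  # construct timepoints whose rank-sum p is forced: identical samples give
  # p = 1 (> alpha); fully separated samples of size 12 give p ~ 7e-7
  purrr::map_dfr(seq_along(p_wanted), function(i) {
    if (p_wanted[i] > 0.05) {
      vals_a <- vals_b <- seq_len(n)
    } else {
      vals_a <- seq_len(n); vals_b <- seq_len(n) + 100
    }
    tibble::tibble(timepoint_index = i, time = i * 10,
                   group = rep(c("A", "B"), each = n),
                   value = c(vals_a, vals_b))
  })
}

test_that("the divergence index obeys the all-subsequent rule", {
  # significant from the 2nd timepoint on -> index 2
  res <- time_of_divergence(series_from_p(c(0.5, 0.01, 0.01, 0.01)),
                            alpha = 0.05)
  expect_equal(res$divergence$divergence_index, 2L)
  expect_equal(res$divergence$divergence_time, 20)

  # an early significant dip does not count
  res2 <- time_of_divergence(series_from_p(c(0.01, 0.5, 0.01, 0.01)),
                             alpha = 0.05)
  expect_equal(res2$divergence$divergence_index, 3L)

  # never significant -> no divergence
  res3 <- time_of_divergence(series_from_p(c(0.5, 0.5, 0.5)), alpha = 0.05)
  expect_true(is.na(res3$divergence$divergence_index))

  # all significant -> diverges from the first timepoint
  res4 <- time_of_divergence(series_from_p(c(0.01, 0.01)), alpha = 0.05)
  expect_equal(res4$divergence$divergence_index, 1L)
})

test_that("the boundary p = alpha is inclusive", {
  # with samples {1,2,3} vs {4,5,6} the exact p is 0.10
  ser <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(timepoint_index = i, time = i,
                   group = rep(c("A", "B"), each = 3),
                   value = c(1, 2, 3, 4, 5, 6))
  })
  res <- time_of_divergence(ser, alpha = 0.10)
  expect_equal(res$divergence$divergence_index, 1L)
  res2 <- time_of_divergence(ser, alpha = 0.0999)
  expect_true(is.na(res2$divergence$divergence_index))
})

test_that("truncating after divergence keeps the index; appending p > alpha cancels it", {
  ser <- series_from_p(c(0.5, 0.01, 0.01, 0.01))
  full <- time_of_divergence(ser, alpha = 0.05)
  cut <- time_of_divergence(ser[ser$timepoint_index <= 3, ], alpha = 0.05)
  expect_equal(cut$divergence$divergence_index,
               full$divergence$divergence_index)
  appended <- dplyr::bind_rows(
    ser,
    series_from_p(0.9) |> dplyr::mutate(timepoint_index = 5, time = 50)
  )
  res <- time_of_divergence(appended, alpha = 0.05)
  expect_true(is.na(res$divergence$divergence_index))
})

test_that("both significance levels are reported like the figure annotations", {
  sim <- generate_grouped_timeseries(effect_size = 10, noise_sd = 1,
                                     shift_start_index = 4, seed = 61)
  res <- time_of_divergence(sim$series)
  expect_equal(res$divergence$alpha, c(0.05, 0.01))
  expect_equal(nrow(tidy(res)), 8)
  g <- glance(res)
  expect_true(all(c("divergence_index_alpha_0.05",
                    "divergence_index_alpha_0.01") %in% names(g)))
})

test_that("strong effects are recovered at the true divergence index", {
  hits <- vapply(1:20, function(s) {
    sim <- generate_grouped_timeseries(effect_size = 10, noise_sd = 1,
                                       shift_start_index = 4, seed = 200 + s)
    res <- time_of_divergence(sim$series, alpha = 0.01)
    identical(res$divergence$divergence_index, 4L)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the power study reports recovery, latency and the null rate", {
  tab <- divergence_power_study(effect_sizes = c(0, 10), n_seeds = 30,
                                alpha = 0.01, seed = 5)
  expect_equal(nrow(tab), 2)
  null_row <- tab[tab$effect_size == 0, ]
  expect_true(is.na(null_row$recovery_rate))
  expect_lte(null_row$false_divergence_rate, 0.35)
  strong <- tab[tab$effect_size == 10, ]
  expect_gte(strong$recovery_rate, 0.9)
  expect_lt(abs(strong$mean_latency), 0.5)
})
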