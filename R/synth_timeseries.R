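#' Generate a grouped two-sample time series with a known divergence point
#'
#' Emulates pooled per-cell intensity distributions for two experimental
#' groups measured at common timepoints (the data structure behind a
#' per-timepoint rank-sum divergence analysis). Both groups share a common
#' baseline trend with Gaussian noise; from `shift_start_index` onward the
#' second group's distribution is location-shifted by `effect_size`.
#'
#' @param n_per_group Observations per group per timepoint (scalar or
#'   length-2 vector for unequal group sizes). Default 15, the order of
#'   pooled imaged cells per group such experiments yield.
#' @param timepoints Strictly increasing numeric timepoints (s).
#' @param shift_start_index 1-based index of the first shifted timepoint.
#' @param effect_size Location shift applied to group B.
#' @param noise_sd Gaussian noise SD around the baseline trend.
#' @param baseline Optional function `f(timepoints)` giving the shared mean
#'   trend; default a slow linear rise.
#' @param seed Integer seed.
#' @return A list with `series` — a tibble `(timepoint_index, time,
#'   group, value)` — and `truth` with `divergence_index` (`NA` when
#'   `effect_size` is 0, i.e. no divergence exists).
#' @export
generate_grouped_timeseries <- function(n_per_group = 15L,
                                        timepoints = seq(0, 70, by = 10),
                                        shift_start_index = 4L,
                                        effect_size = 1,
                                        noise_sd = 1,
                                        baseline = NULL,
                                        seed = 1L) {
  if (any(n_per_group <= 0)) {
    stop("n_per_group must be positive", call. = FALSE)
  }
  n_tp <- length(timepoints)
  stopifnot(
    "timepoints must be strictly increasing" = all(diff(timepoints) > 0),
    "shift_start_index out of range" =
      shift_start_index >= 1 && shift_start_index <= n_tp,
    "noise_sd must be positive" = noise_sd > 0
  )
  n_per_group <- rep_len(as.integer(n_per_group), 2L)
  if (is.null(baseline)) {
    span <- diff(range(timepoints))
    baseline <- function(t) 10 + 2 * (t - timepoints[1]) / max(span, 1)
  }
  mu <- baseline(timepoints)
  withr::with_seed(seed, {
    series <- purrr::map_dfr(seq_len(n_tp), function(i) {
      shift <- if (i >= shift_start_index) effect_size else 0
      tibble::tibble(
        timepoint_index = i,
        time = timepoints[i],
        group = rep(c("A", "B"), n_per_group),
        value = c(
          stats::rnorm(n_per_group[1], mu[i], noise_sd),
          stats::rnorm(n_per_group[2], mu[i] + shift, noise_sd)
        )
      )
    })
    truth <- list(
      divergence_index = if (effect_size == 0) NA_integer_
                         else as.integer(shift_start_index),
      effect_size = effect_size,
      noise_sd = noise_sd
    )
    list(series = series, truth = truth)
  })
}
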