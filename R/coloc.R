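#' Colocalization parameters
#'
#' @param cutoff_nm Nearest-neighbour distance at or below which a vesicle
#'   counts as double-positive. Default 320 nm, the object-based cutoff
#'   used for confocal T cell endosome data (about two pixels at typical
#'   confocal sampling, consistent with a centroid-to-centroid criterion).
#' @param n_random_iterations Iterations of the random-point control.
#' @param seed Integer seed for the random control.
#' @return A list of class `coloc_params`.
#' @export
coloc_params <- function(cutoff_nm = 320, n_random_iterations = 100L,
                         seed = 1L) {
  stopifnot(
    "cutoff_nm must be positive" = cutoff_nm > 0,
    "n_random_iterations must be positive" = n_random_iterations >= 1
  )
  structure(
    list(cutoff_nm = cutoff_nm,
         n_random_iterations = as.integer(n_random_iterations),
         seed = as.integer(seed)),
    class = "coloc_params"
  )
}

#' Cross-channel nearest-neighbour distances
#'
#' For every vesicle of the reference set, the Euclidean distance (nm) to
#' its nearest vesicle in the query set. Directional: distances are
#' reported per reference vesicle and never averaged across directions.
#'
#' @param reference,query Tibbles with `y_nm`, `x_nm` columns (e.g. from
#'   [detect_vesicles()]), in the same frame and coordinate system.
#' @return Numeric vector, one distance per reference row.
#' @export
nn_distances <- function(reference, query) {
  stopifnot(
    all(c("y_nm", "x_nm") %in% names(reference)),
    all(c("y_nm", "x_nm") %in% names(query))
  )
  if (nrow(query) == 0) {
    stop("no cross-channel objects: query set is empty", call. = FALSE)
  }
  if (nrow(reference) == 0) return(numeric(0))
  d2 <- outer(reference$y_nm, query$y_nm, "-")^2 +
    outer(reference$x_nm, query$x_nm, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Classify double-positive vesicles from nearest-neighbour distances
#'
#' A vesicle is double-positive when its nearest cross-channel neighbour is
#' at or within the cutoff (inclusive boundary).
#'
#' @param distances Non-negative distances in nm, per reference vesicle.
#' @param params A [coloc_params()].
#' @return A list of class `nn_result`: `distances_nm`, `double_positive`
#'   (logical), `percent_double_positive`, `cutoff_nm`, `n`.
#' @export
classify_double_positive <- function(distances, params = coloc_params()) {
  if (length(distances) == 0) {
    stop("no distances to classify", call. = FALSE)
  }
  stopifnot("distances must be non-negative" = all(distances >= 0))
  flag <- distances <= params$cutoff_nm
  structure(
    list(
      distances_nm = as.numeric(distances),
      double_positive = flag,
      percent_double_positive = 100 * mean(flag),
      cutoff_nm = params$cutoff_nm,
      n = length(distances)
    ),
    class = "nn_result"
  )
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf(
    "<nn_result> %d vesicles, %.1f%% double-positive at <= %g nm\n",
    x$n, x$percent_double_positive, x$cutoff_nm
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nn_result <- function(x, ...) {
  tibble::tibble(
    nn_distance_nm = x$distances_nm,
    double_positive = x$double_positive
  )
}

#' @export
glance.nn_result <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    percent_double_positive = x$percent_double_positive,
    cutoff_nm = x$cutoff_nm
  )
}

# Uniform points inside a cell mask: uniform over mask pixels plus
# continuous jitter within the pixel.
sample_points_in_mask <- function(cell, n) {
  px_idx <- which(cell$mask, arr.ind = TRUE)
  if (nrow(px_idx) < 1) stop("mask too small to place points", call. = FALSE)
  pick <- sample.int(nrow(px_idx), n, replace = TRUE)
  tibble::tibble(
    y_px = px_idx[pick, 1] + stats::runif(n, -0.5, 0.5),
    x_px = px_idx[pick, 2] + stats::runif(n, -0.5, 0.5)
  )
}

#' Random-point colocalization control
#'
#' Places two sets of uniformly distributed points inside the cell mask,
#' computes their double-positive percentage exactly as for real vesicles,
#' and repeats. The chance colocalization level it estimates is what an
#' observed percentage must exceed to mean anything. Deterministic given
#' the seed in `params`.
#'
#' @param cell A `cell_region` (from [segment_cell()] or
#'   [cell_region_from_mask()]).
#' @param n_reference,n_query Points per set; by convention the observed
#'   per-channel vesicle counts of the same cell, which preserves density.
#' @param params A [coloc_params()].
#' @return A list of class `random_control`: `percent` (per iteration),
#'   `mean_percent`, `sd_percent`, `se_percent`, `n_iterations`.
#' @export
random_control <- function(cell, n_reference, n_query,
                           params = coloc_params()) {
  stopifnot(inherits(cell, "cell_region"))
  if (n_reference < 1 || n_query < 1) {
    stop("need at least one point per set", call. = FALSE)
  }
  px <- cell$pixel_size_nm
  percent <- withr::with_seed(params$seed, {
    vapply(seq_len(params$n_random_iterations), function(i) {
      ref <- sample_points_in_mask(cell, n_reference)
      qry <- sample_points_in_mask(cell, n_query)
      ref$y_nm <- ref$y_px * px; ref$x_nm <- ref$x_px * px
      qry$y_nm <- qry$y_px * px; qry$x_nm <- qry$x_px * px
      d <- nn_distances(ref, qry)
      100 * mean(d <= params$cutoff_nm)
    }, numeric(1))
  })
  structure(
    list(
      percent = percent,
      mean_percent = mean(percent),
      sd_percent = stats::sd(percent),
      se_percent = stats::sd(percent) / sqrt(length(percent)),
      n_iterations = params$n_random_iterations,
      cutoff_nm = params$cutoff_nm
    ),
    class = "random_control"
  )
}

#' @export
print.random_control <- function(x, ...) {
  cat(sprintf(
    "<random_control> %.2f%% +/- %.2f%% (SD) chance double-positive over %d iterations\n",
    x$mean_percent, x$sd_percent, x$n_iterations
  ))
  invisible(x)
}

#' Directed colocalization of two detection sets with random control
#'
#' Convenience wrapper running the full object-based analysis for one cell:
#' nearest-neighbour distances from reference to query, double-positive
#' classification at the cutoff, and a random-point control matched to the
#' observed counts.
#'
#' @param reference,query Detection tibbles (see [nn_distances()]).
#' @param cell A `cell_region` for the random control; skipped when `NULL`.
#' @param params A [coloc_params()].
#' @return A tibble with one row: `n_reference`, `n_query`,
#'   `percent_double_positive`, `random_mean_percent`, `random_sd_percent`,
#'   `cutoff_nm`.
#' @export
colocalize <- function(reference, query, cell = NULL,
                       params = coloc_params()) {
  res <- classify_double_positive(nn_distances(reference, query), params)
  ctrl <- if (!is.null(cell)) {
    random_control(cell, max(nrow(reference), 1), max(nrow(query), 1), params)
  }
  tibble::tibble(
    n_reference = nrow(reference),
    n_query = nrow(query),
    percent_double_positive = res$percent_double_positive,
    random_mean_percent = if (is.null(ctrl)) NA_real_ else ctrl$mean_percent,
    random_sd_percent = if (is.null(ctrl)) NA_real_ else ctrl$sd_percent,
    cutoff_nm = params$cutoff_nm
  )
}
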