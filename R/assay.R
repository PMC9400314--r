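#' Fold change of activated over resting median fluorescence
#'
#' The uptake / recycling ratio: activated MedianFI divided by resting
#' MedianFI at one timepoint. When `subtract_unstained = TRUE`, the
#' matching unstained sample's median is subtracted from each condition's
#' (replicate-averaged) median first — the Methods-prescribed order for
#' activation-marker assays; uptake and recycling assays default to the
#' plain ratio.
#'
#' @param table Tibble with columns `condition` (`"activated"` /
#'   `"resting"`), `median_fi`, optionally `timepoint`, `stain`
#'   (`"stained"` / `"unstained"`) and `replicate`.
#' @param timepoint Timepoint to evaluate; `NULL` uses the whole table.
#' @param subtract_unstained Subtract the matching unstained median first.
#' @return The activated/resting ratio (scalar).
#' @export
fold_change_activated_vs_resting <- function(table, timepoint = NULL,
                                             subtract_unstained = FALSE) {
  stopifnot(all(c("condition", "median_fi") %in% names(table)))
  if (!is.null(timepoint)) {
    stopifnot("timepoint" %in% names(table))
    table <- table[table$timepoint == timepoint, ]
  }
  med <- function(cond) {
    rows <- table[table$condition == cond, ]
    if (nrow(rows) == 0) {
      stop(sprintf("no '%s' rows for the requested timepoint", cond),
           call. = FALSE)
    }
    if (subtract_unstained && "stain" %in% names(table)) {
      stained <- mean(rows$median_fi[rows$stain == "stained"])
      unstained <- mean(rows$median_fi[rows$stain == "unstained"])
      if (is.nan(stained) || is.nan(unstained)) {
        stop(sprintf("'%s' needs stained and unstained rows", cond),
             call. = FALSE)
      }
      stained - unstained
    } else {
      mean(rows$median_fi)
    }
  }
  resting <- med("resting")
  if (resting <= 0) {
    stop("resting median must be positive", call. = FALSE)
  }
  med("activated") / resting
}

#' Recycling signal relative to the t = 0 measurement
#'
#' Each timepoint's MedianFI divided by the MedianFI at t = 0, the form in
#' which recycling time courses are compared across cell lines. Invariant
#' to uniform rescaling of all medians.
#'
#' @param table Tibble with columns `timepoint` and `median_fi` (one row
#'   per timepoint, or replicates that are averaged first).
#' @return A tibble `(timepoint, median_fi, fold_vs_t0)`.
#' @export
recycling_relative_to_t0 <- function(table) {
  stopifnot(all(c("timepoint", "median_fi") %in% names(table)))
  tab <- table |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(median_fi = mean(.data$median_fi), .groups = "drop") |>
    dplyr::arrange(.data$timepoint)
  t0 <- tab$median_fi[tab$timepoint == 0]
  if (length(t0) != 1) stop("missing t = 0 measurement", call. = FALSE)
  if (t0 <= 0) stop("t = 0 median must be positive", call. = FALSE)
  dplyr::mutate(tab, fold_vs_t0 = .data$median_fi / t0)
}

#' Treated-over-control normalization
#'
#' The labile-iron-pool / ROS read-out: treated MedianFI divided by the
#' matched control MedianFI.
#'
#' @param treated_median,control_median Scalars (or equal-length vectors,
#'   normalized pairwise).
#' @return `treated_median / control_median`.
#' @export
normalize_to_control <- function(treated_median, control_median) {
  if (any(control_median <= 0)) {
    stop("control median must be positive", call. = FALSE)
  }
  treated_median / control_median
}

#' Specific conjugate fraction, minority-referenced and background-corrected
#'
#' Conjugates (double-positive events) relative to the total cell number
#' (singles + conjugates) of whichever cell type is in the minority in that
#' sample; the same percentage computed on the unpulsed control sample
#' (no superantigen) is subtracted as unspecific background. A negative
#' corrected percentage is reported as computed, never clamped — clamping
#' would bias group means.
#'
#' @param singles_t,singles_b,conjugates Event counts of the pulsed sample.
#' @param control_singles_t,control_singles_b,control_conjugates Counts of
#'   the matched unpulsed control; omit all three for an uncorrected
#'   percentage.
#' @return A tibble `(raw_percent, control_percent, percent)`.
#' @export
conjugate_fraction <- function(singles_t, singles_b, conjugates,
                               control_singles_t = NULL,
                               control_singles_b = NULL,
                               control_conjugates = NULL) {
  raw_pct <- function(st, sb, cj) {
    stopifnot(st >= 0, sb >= 0, cj >= 0)
    minority_total <- min(st + cj, sb + cj)
    if (minority_total == 0) {
      stop("zero cells of the minority type", call. = FALSE)
    }
    100 * cj / minority_total
  }
  raw <- raw_pct(singles_t, singles_b, conjugates)
  ctrl <- if (!is.null(control_singles_t)) {
    raw_pct(control_singles_t, control_singles_b, control_conjugates)
  } else {
    0
  }
  tibble::tibble(
    raw_percent = raw,
    control_percent = ctrl,
    percent = raw - ctrl
  )
}

#' Normalize western-blot band intensities
#'
#' Two steps: every target band is divided by the brightest target band on
#' the blot, and every loading-control (actin) band by the brightest actin
#' band; the scaled target is then divided by the scaled actin of its
#' lane. Scaling the actin to its own blot maximum first makes the result
#' invariant to actin units.
#'
#' @param bands Tibble with columns `lane`, `target`, `actin` (one blot) —
#'   optionally `blot` for several blots, normalized independently.
#' @return The input tibble with `target_rel`, `actin_rel` and
#'   `normalized` columns.
#' @export
normalize_bands <- function(bands) {
  stopifnot(all(c("target", "actin") %in% names(bands)))
  if (!"blot" %in% names(bands)) bands$blot <- "blot1"
  stopifnot(all(bands$target >= 0), all(bands$actin > 0))
  brightest <- tapply(bands$target, bands$blot, max)
  if (any(brightest <= 0)) {
    stop("brightest target band must be positive on every blot",
         call. = FALSE)
  }
  bands |>
    dplyr::group_by(.data$blot) |>
    dplyr::mutate(
      target_rel = .data$target / max(.data$target),
      actin_rel = .data$actin / max(.data$actin),
      normalized = .data$target_rel / .data$actin_rel
    ) |>
    dplyr::ungroup()
}
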