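#' Fusion-classification parameters
#'
#' @param drop_threshold Fractional intensity drop above which (strictly)
#'   an event counts as co-fusing; default 0.10, the 10% rule.
#' @param last_k Number of trailing frames averaged; default 3.
#' @param footprint_radius_px Radius of the disk footprint over which the
#'   per-frame maximum is taken; default 3 px.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(drop_threshold = 0.10, last_k = 3L,
                          footprint_radius_px = 3L) {
  stopifnot(
    "drop_threshold must lie in (0, 1)" =
      drop_threshold > 0 && drop_threshold < 1,
    "last_k must be at least 1" = last_k >= 1,
    "footprint_radius_px must be positive" = footprint_radius_px >= 1
  )
  structure(
    list(drop_threshold = drop_threshold, last_k = as.integer(last_k),
         footprint_radius_px = as.integer(footprint_radius_px)),
    class = "fusion_params"
  )
}

#' Extract a per-frame maximum-intensity trace at an event footprint
#'
#' For every frame of the event window, the maximum raw intensity inside a
#' disk footprint centred on the event. This is the per-event series the
#' 10% co-fusion rule is evaluated on.
#'
#' @param stack A [frame_stack()].
#' @param channel Channel to trace (for co-fusion calls: the marker
#'   channel).
#' @param centre `(y, x)` footprint centre in px.
#' @param window Integer vector of frame indices (the event window),
#'   default all frames.
#' @param params A [fusion_params()].
#' @param event_id Optional identifier carried through.
#' @return An object of class `fusion_trace`: `intensity` (per-frame
#'   maxima), `frames`, `centre_px`, `radius_px`, `channel`, `event_id`.
#' @export
extract_event_trace <- function(stack, channel, centre, window = NULL,
                                params = fusion_params(), event_id = NA) {
  stopifnot(inherits(params, "fusion_params"), length(centre) == 2)
  if (is.null(window)) window <- seq_len(n_frames(stack))
  window <- as.integer(window)
  if (length(window) < params$last_k + 1L) {
    stop(sprintf(
      "event window must span at least last_k + 1 = %d frames",
      params$last_k + 1L
    ), call. = FALSE)
  }
  if (min(window) < 1 || max(window) > n_frames(stack)) {
    stop("event window outside the movie", call. = FALSE)
  }
  d <- dim(stack$data)
  r <- params$footprint_radius_px
  ys <- max(1L, floor(centre[1] - r)):min(d[1], ceiling(centre[1] + r))
  xs <- max(1L, floor(centre[2] - r)):min(d[2], ceiling(centre[2] + r))
  if (length(ys) == 0 || length(xs) == 0) {
    stop("footprint outside the image", call. = FALSE)
  }
  in_disk <- outer((ys - centre[1])^2, (xs - centre[2])^2, "+") <= r^2
  if (!any(in_disk)) {
    stop("footprint contains no pixels", call. = FALSE)
  }
  trace <- vapply(window, function(t) {
    win <- frame_matrix(stack, channel, t)[ys, xs, drop = FALSE]
    max(win[in_disk])
  }, numeric(1))
  structure(
    list(
      intensity = trace,
      frames = window,
      centre_px = as.numeric(centre),
      radius_px = r,
      channel = stack$channel_names[resolve_channel(stack, channel)],
      frame_interval_s = stack$frame_interval_s,
      event_id = event_id
    ),
    class = "fusion_trace"
  )
}

#' @export
print.fusion_trace <- function(x, ...) {
  cat(sprintf(
    "<fusion_trace> event %s, channel '%s', frames %d-%d, footprint r=%d px\n",
    as.character(x$event_id), x$channel, min(x$frames), max(x$frames),
    x$radius_px
  ))
  invisible(x)
}

#' Classify a fusion event by the 10% intensity-drop rule
#'
#' Let `M0` be the maximum intensity of the initial frame of the event
#' window and `Mbar` the mean of the per-frame maxima over the last
#' `last_k` frames. The event counts as carrying the traced marker when
#' `(M0 - Mbar) / M0 > drop_threshold` — a strict inequality, so a drop of
#' exactly 10% classifies negative. "Mean maximum intensity from the last
#' three frames" is read as the mean of the three per-frame maxima;
#' `reading = "max_of_last"` selects the alternative reading (maximum over
#' the last `last_k` frames).
#'
#' The rule is a ratio, hence invariant under positive scaling of the
#' trace.
#'
#' @param trace A `fusion_trace` (or bare numeric vector of per-frame
#'   maxima).
#' @param params A [fusion_params()].
#' @param reading `"mean_of_last"` (default) or `"max_of_last"`.
#' @return Logical: `TRUE` when the event co-fuses with the traced marker.
#' @export
classify_cofusion <- function(trace, params = fusion_params(),
                              reading = c("mean_of_last", "max_of_last")) {
  reading <- match.arg(reading)
  intensity <- if (inherits(trace, "fusion_trace")) trace$intensity else trace
  if (length(intensity) < params$last_k + 1L) {
    stop("trace shorter than last_k + 1 frames", call. = FALSE)
  }
  m0 <- intensity[1]
  if (m0 <= 0) stop("no signal in initial frame", call. = FALSE)
  last <- utils::tail(intensity, params$last_k)
  mbar <- if (reading == "mean_of_last") mean(last) else max(last)
  (m0 - mbar) / m0 > params$drop_threshold
}

#' Summarize co-fusion calls per condition
#'
#' @param calls Logical vector of per-event co-fusion calls, or a tibble
#'   with columns `cofusion` (logical) and optionally `condition`.
#' @param condition Grouping label(s) when `calls` is a bare vector.
#' @return A tibble of class `cofusion_summary`: one row per condition with
#'   `n_events`, `n_with_marker`, `percent_with_marker`.
#' @export
cofusion_percentage <- function(calls, condition = "all") {
  if (is.data.frame(calls)) {
    df <- calls
    if (!"condition" %in% names(df)) df$condition <- condition
    stopifnot("cofusion" %in% names(df))
  } else {
    if (length(calls) == 0) stop("zero events", call. = FALSE)
    df <- tibble::tibble(cofusion = as.logical(calls),
                         condition = rep_len(condition, length(calls)))
  }
  if (nrow(df) == 0) stop("zero events", call. = FALSE)
  out <- df |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      n_with_marker = sum(.data$cofusion),
      percent_with_marker = 100 * mean(.data$cofusion),
      .groups = "drop"
    )
  class(out) <- c("cofusion_summary", class(out))
  out
}

#' Classify every event of an event table against a movie
#'
#' Manual-event mode: events arrive as a table of centres and windows
#' (mirroring visually identified fusion events), the marker channel is
#' traced at each footprint and the 10% rule applied.
#'
#' @param stack A [frame_stack()].
#' @param events Tibble with `event_id`, `y_px`, `x_px` and optionally
#'   `frame_start`, `frame_end` (default: whole movie).
#' @param channel Marker channel to classify.
#' @param params A [fusion_params()].
#' @param reading Passed to [classify_cofusion()].
#' @return The events tibble with a logical `cofusion` column.
#' @export
classify_events <- function(stack, events, channel = 2,
                            params = fusion_params(),
                            reading = "mean_of_last") {
  stopifnot(all(c("event_id", "y_px", "x_px") %in% names(events)))
  nf <- n_frames(stack)
  events$cofusion <- vapply(seq_len(nrow(events)), function(i) {
    w0 <- if ("frame_start" %in% names(events)) events$frame_start[i] else 1L
    w1 <- if ("frame_end" %in% names(events)) events$frame_end[i] else nf
    tr <- extract_event_trace(stack, channel,
                              c(events$y_px[i], events$x_px[i]),
                              window = seq.int(w0, w1), params = params,
                              event_id = events$event_id[i])
    classify_cofusion(tr, params, reading)
  }, logical(1))
  tibble::as_tibble(events)
}
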