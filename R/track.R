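#' Link per-frame detections into vesicle tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: the
#' globally closest unassigned pair is linked first, then the next, while
#' the displacement stays within `max_link_displacement_px`; remaining
#' detections start new tracks. No gap closing — a vesicle missing in one
#' frame terminates its track. Where no ambiguity exists this equals the
#' minimal-total-displacement assignment.
#'
#' @param detections A tibble of detections across frames, as produced by
#'   [detect_vesicles()] (needs columns `frame`, `y_px`, `x_px`).
#' @param params A [detection_params()]; only `max_link_displacement_px`
#'   is used.
#' @return The input tibble with a `track_id` column, ordered by track then
#'   frame. Within a track, frame indices are consecutive and unique.
#' @export
link_tracks <- function(detections, params = detection_params()) {
  stopifnot(
    is.data.frame(detections),
    all(c("frame", "y_px", "x_px") %in% names(detections))
  )
  det <- dplyr::arrange(detections, .data$frame)
  n <- nrow(det)
  if (n == 0) {
    det$track_id <- integer(0)
    return(tibble::as_tibble(det))
  }
  track_id <- rep(NA_integer_, n)
  next_id <- 1L
  frames <- sort(unique(det$frame))
  gate2 <- params$max_link_displacement_px^2

  idx_prev <- which(det$frame == frames[1])
  track_id[idx_prev] <- seq_len(length(idx_prev))
  next_id <- length(idx_prev) + 1L

  for (f in frames[-1]) {
    idx_cur <- which(det$frame == f)
    # only link across an exact +1 frame step (no gap closing)
    prev_frame <- f - 1L
    idx_prev_f <- idx_prev[det$frame[idx_prev] == prev_frame]
    if (length(idx_prev_f) > 0 && length(idx_cur) > 0) {
      d2 <- outer(det$y_px[idx_prev_f], det$y_px[idx_cur], "-")^2 +
        outer(det$x_px[idx_prev_f], det$x_px[idx_cur], "-")^2
      repeat {
        m <- which.min(d2)
        if (length(m) == 0 || d2[m] > gate2) break
        i <- (m - 1) %% nrow(d2) + 1
        j <- (m - 1) %/% nrow(d2) + 1
        track_id[idx_cur[j]] <- track_id[idx_prev_f[i]]
        d2[i, ] <- Inf
        d2[, j] <- Inf
        if (all(is.infinite(d2))) break
      }
    }
    new <- idx_cur[is.na(track_id[idx_cur])]
    if (length(new) > 0) {
      track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    idx_prev <- idx_cur
  }
  det$track_id <- track_id
  tibble::as_tibble(dplyr::arrange(det, .data$track_id, .data$frame))
}
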