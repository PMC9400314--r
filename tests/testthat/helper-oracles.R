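# Independent brute-force oracles used across the suite. These deliberately
# use plain loops and enumeration, never the package's own code paths.

# Exhaustive all-pairs nearest-neighbour distances (nm).
oracle_nn <- function(ref, qry) {
  out <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    best <- Inf
    for (j in seq_len(nrow(qry))) {
      d <- sqrt((ref$y_nm[i] - qry$y_nm[j])^2 +
                (ref$x_nm[i] - qry$x_nm[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Per-pixel accumulation of the intensity-weighted centre of mass.
oracle_com <- function(image, mask) {
  sy <- sx <- tot <- 0
  for (y in seq_len(nrow(image))) {
    for (x in seq_len(ncol(image))) {
      if (mask[y, x]) {
        w <- image[y, x]
        sy <- sy + y * w
        sx <- sx + x * w
        tot <- tot + w
      }
    }
  }
  c(sy, sx) / tot
}

# Per-pixel accumulation of the dispersion statistic.
oracle_dispersion <- function(image, mask) {
  ctr <- oracle_com(image, mask)
  s <- tot <- 0
  for (y in seq_len(nrow(image))) {
    for (x in seq_len(ncol(image))) {
      if (mask[y, x]) {
        w <- image[y, x]
        s <- s + w * sqrt((y - ctr[1])^2 + (x - ctr[2])^2)
        tot <- tot + w
      }
    }
  }
  s / tot
}

# Masked mean with explicit background-zeroing, per-pixel.
oracle_masked_mean <- function(cargo, mask, bg) {
  s <- 0; n <- 0
  for (y in seq_len(nrow(cargo))) {
    for (x in seq_len(ncol(cargo))) {
      if (mask[y, x]) {
        s <- s + max(cargo[y, x] - bg, 0)
        n <- n + 1
      }
    }
  }
  s / n
}

# Per-frame maximum inside a disk footprint, per-pixel.
oracle_footprint_max <- function(stack, channel, centre, radius, frames) {
  vapply(frames, function(t) {
    img <- stack$data[, , channel, t]
    best <- -Inf
    for (y in seq_len(nrow(img))) {
      for (x in seq_len(ncol(img))) {
        if ((y - centre[1])^2 + (x - centre[2])^2 <= radius^2 &&
            img[y, x] > best) {
          best <- img[y, x]
        }
      }
    }
    best
  }, numeric(1))
}

# Exact two-sided rank-sum p-value by enumeration of all C(m+n, m)
# assignments of the pooled ranks (tie-free samples only).
oracle_ranksum_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(idx) {
    sum(sort(r)[idx]) - m * (m + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Exhaustive minimal-total-displacement assignment between two frames with
# equal point counts (<= ~6), all pairings within the gate required.
# Returns the permutation p with cur[p[i]] linked to prev[i], or NULL when
# no full within-gate matching exists.
oracle_min_assignment <- function(prev, cur, gate) {
  n <- nrow(prev)
  stopifnot(nrow(cur) == n)
  d <- sqrt(outer(prev$y_px, cur$y_px, "-")^2 +
            outer(prev$x_px, cur$x_px, "-")^2)
  best <- NULL; best_cost <- Inf
  for (pm in combinat_perms(n)) {
    dd <- d[cbind(seq_len(n), pm)]
    if (all(dd <= gate) && sum(dd) < best_cost) {
      best <- pm; best_cost <- sum(dd)
    }
  }
  best
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1)) {
      out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  }
  out
}

# Random detection-like tibble on a given area.
random_points <- function(n, size_px, pixel_size_nm = 160) {
  tibble::tibble(
    y_px = stats::runif(n, 1, size_px[1]),
    x_px = stats::runif(n, 1, size_px[2]),
    y_nm = NA_real_, x_nm = NA_real_
  ) |>
    dplyr::mutate(y_nm = y_px * pixel_size_nm, x_nm = x_px * pixel_size_nm)
}
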