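# Independent brute-force oracles. These deliberately re-derive results by
# naive enumeration (explicit loops, literal formulas) and never call the
# package's fast paths.

# --- GLCM / Haralick ------------------------------------------------------

# ordered-pair enumeration GLCM on an integer level matrix (0-based levels)
bf_glcm <- function(q, distance, angle, n_levels, symmetric = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  P <- matrix(0, n_levels, n_levels)
  h <- nrow(q); w <- ncol(q)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      y2 <- y + off[1]; x2 <- x + off[2]
      if (y2 >= 1 && y2 <= h && x2 >= 1 && x2 <= w) {
        i <- q[y, x] + 1; j <- q[y2, x2] + 1
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# literal Haralick formulas on a normalized GLCM (1-based gray indices)
bf_selected_features <- function(P) {
  ng <- nrow(P)
  f_sa <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    f_sa <- f_sa + (i + j) * P[i, j]
  }
  f_sv <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    f_sv <- f_sv + (i + j - f_sa)^2 * P[i, j]
  }
  mu <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) mu <- mu + i * P[i, j]
  f_var <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    f_var <- f_var + (i - mu)^2 * P[i, j]
  }
  c(sum_average = f_sa, sum_variance = f_sv, variance_sos = f_var)
}

# brute-force analogue of haralick_selected (mean over the 4 angles)
bf_haralick_selected <- function(q, distances, n_levels) {
  out <- numeric(0)
  for (d in distances) {
    acc <- c(sum_average = 0, sum_variance = 0, variance_sos = 0)
    for (ang in c(0, 45, 90, 135)) {
      acc <- acc + bf_selected_features(bf_glcm(q, d, ang, n_levels))
    }
    acc <- acc / 4
    names(acc) <- paste0(names(acc), "_d", d)
    out <- c(out, acc)
  }
  out
}

# --- mesh statistics ------------------------------------------------------

# queue-based 4-connected flood fill of the inverted mask; meshes are
# background components that never touch the border
bf_mesh_stats <- function(mask, pixel_size_nm) {
  inv <- !mask
  h <- nrow(inv); w <- ncol(inv)
  seen <- matrix(FALSE, h, w)
  areas <- numeric(0)
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!inv[y0, x0] || seen[y0, x0]) next
    queue <- list(c(y0, x0)); seen[y0, x0] <- TRUE
    px <- 0; touches <- FALSE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      y <- p[1]; x <- p[2]
      px <- px + 1
      if (y == 1 || y == h || x == 1 || x == w) touches <- TRUE
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + o[1]; xx <- x + o[2]
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            inv[yy, xx] && !seen[yy, xx]) {
          seen[yy, xx] <- TRUE
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
    if (!touches) areas <- c(areas, px)
  }
  n <- length(areas)
  list(n_meshes = n,
       mean_mesh_area_nm2 = if (n) mean(areas) * pixel_size_nm^2 else NA_real_,
       var_mesh_area_nm2 = if (n >= 2) stats::var(areas * pixel_size_nm^2)
                           else if (n == 1) 0 else NA_real_,
       pct_segmented_area = 100 * sum(mask) / length(mask))
}

# --- average linkage ------------------------------------------------------

# naive O(n^3) agglomerative average linkage on a distance matrix; returns
# the merge heights in order and the partition at each cluster count
bf_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, bestd)
    part <- integer(n)
    for (k in seq_along(clusters)) part[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = rev(partitions))
}

# do two labelings describe the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, `==`) == outer(b, b, `==`))
}

# small helper: deterministic random test image as a pixel_image
random_level_image <- function(h, w, n_levels, seed) {
  withr::with_seed(seed,
    pixel_image(matrix(sample(0:(n_levels - 1), h * w, TRUE), h, w),
                pixel_size_nm = 20))
}
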