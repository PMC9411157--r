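#' Gaussian prefilter for texture analysis
#'
#' Smooths an image with a 3 x 3 kernel sampled from a sigma = 1 px
#' Gaussian and renormalized to sum 1, the standard preprocessing step
#' before co-occurrence texture extraction. Borders are handled by
#' reflection.
#'
#' @param image a `pixel_image` of at least 3 x 3 px.
#' @return The filtered `pixel_image`.
#' @export
prefilter_gaussian <- function(image) {
  stopifnot(inherits(image, "pixel_image"))
  if (nrow(image$pixels) < 3 || ncol(image$pixels) < 3) {
    stop("image smaller than the 3 x 3 filter kernel")
  }
  k <- gaussian_kernel(sigma = 1, radius = 1L)
  pixel_image(pmax(convolve_reflect(image$pixels, k), 0),
              image$pixel_size_nm, image$channel_name)
}

#' Quantize intensities to a fixed number of gray levels
#'
#' Images whose values are already integers within `[0, n_levels - 1]`
#' (e.g. 8-bit data with 256 levels) are used as-is; anything else is
#' linearly rebinned onto `0 .. n_levels - 1`.
#'
#' @param image a `pixel_image`.
#' @param n_levels number of gray levels (default 256, matching 8-bit
#'   acquisition).
#' @return Integer matrix of levels in `0 .. n_levels - 1`.
#' @export
quantize_levels <- function(image, n_levels = 256L) {
  px <- image$pixels
  if (all(px == round(px)) && max(px) <= n_levels - 1) {
    return(matrix(as.integer(px), nrow(px), ncol(px)))
  }
  rng <- range(px)
  if (diff(rng) == 0) return(matrix(0L, nrow(px), ncol(px)))
  q <- floor((px - rng[1]) / diff(rng) * n_levels)
  q[q > n_levels - 1] <- n_levels - 1L
  matrix(as.integer(q), nrow(px), ncol(px))
}

# pixel offset (dy, dx) for the four standard GLCM directions
glcm_offset <- function(angle, distance_px) {
  d <- as.integer(distance_px)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels at a fixed pixel offset. With
#' `symmetric = TRUE` (the default) each pair is accumulated in both
#' directions, so the matrix equals its transpose. Entries are normalized
#' to sum 1.
#'
#' @param image a `pixel_image` (quantized internally to `n_levels`).
#' @param distance_px offset length in pixels; co-occurrence is evaluated
#'   at 1, 3, 5 and 10 px for meshwork classification.
#' @param angle one of 0, 45, 90, 135 degrees.
#' @param n_levels number of gray levels.
#' @param symmetric accumulate pairs in both directions.
#' @return A list of class `glcm_matrix` with fields `matrix`,
#'   `distance_px`, `angle`, `n_levels`, `symmetric`.
#' @export
compute_glcm <- function(image, distance_px, angle, n_levels = 256L,
                         symmetric = TRUE) {
  stopifnot(inherits(image, "pixel_image"))
  q <- quantize_levels(image, n_levels)
  off <- glcm_offset(angle, distance_px)
  h <- nrow(q); w <- ncol(q)
  ys <- seq_len(h); xs <- seq_len(w)
  ys2 <- ys + off[1]; xs2 <- xs + off[2]
  oky <- ys2 >= 1 & ys2 <= h
  okx <- xs2 >= 1 & xs2 <= w
  if (!any(oky) || !any(okx)) stop("offset leaves zero valid pixel pairs")
  a <- q[ys[oky], xs[okx], drop = FALSE]
  b <- q[ys2[oky], xs2[okx], drop = FALSE]
  counts <- tabulate(as.vector(a) * n_levels + as.vector(b) + 1L,
                     nbins = n_levels * n_levels)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)  # [i = a, j = b]
  if (symmetric) P <- P + t(P)
  tot <- sum(P)
  if (tot == 0) stop("offset leaves zero valid pixel pairs")
  structure(list(matrix = P / tot, distance_px = as.integer(distance_px),
                 angle = angle, n_levels = as.integer(n_levels),
                 symmetric = symmetric),
            class = "glcm_matrix")
}

# the three selected Haralick statistics of one normalized GLCM.
# Gray levels are indexed 1-based inside the formulas (k in [2, 2*Ng]).
glcm_selected_features <- function(P) {
  ng <- nrow(P)
  px_marg <- rowSums(P)
  idx <- seq_len(ng)
  # moments of i + j under p(i, j) (equivalent to summing over p_{x+y})
  kmat <- outer(idx, idx, `+`)
  f_sa <- sum(kmat * P)
  f_sv <- sum((kmat - f_sa)^2 * P)
  mu <- sum(idx * px_marg)
  f_var <- sum((idx - mu)^2 * px_marg)
  c(sum_average = f_sa, sum_variance = f_sv, variance_sos = f_var)
}

#' Selected Haralick texture features
#'
#' Computes the three co-occurrence texture statistics used for meshwork
#' classification -- sum average, sum variance, and sum of squares:
#' variance -- at each requested distance, on each of the four standard
#' directions (0, 45, 90, 135 degrees), and averages them over the
#' directions. The caller is expected to have applied
#' [prefilter_gaussian()] first.
#'
#' With 1-based gray-level indexing the formulas are
#' `f_SA = sum_k k * p_{x+y}(k)`, `f_SV = sum_k (k - f_SA)^2 * p_{x+y}(k)`,
#' and `f_VAR = sum_ij (i - mu)^2 * p(i, j)` with `mu` the co-occurrence
#' gray-level mean.
#'
#' @param image a `pixel_image`.
#' @param distances_px integer distances; default `c(1, 3, 5, 10)`.
#' @param n_levels gray levels for quantization (default 256).
#' @return Named numeric vector of `3 * length(distances_px)` features,
#'   named like `sum_average_d1`.
#' @export
haralick_selected <- function(image, distances_px = c(1L, 3L, 5L, 10L),
                              n_levels = 256L) {
  stopifnot(inherits(image, "pixel_image"))
  angles <- c(0, 45, 90, 135)
  out <- numeric(0)
  for (d in distances_px) {
    acc <- c(sum_average = 0, sum_variance = 0, variance_sos = 0)
    for (ang in angles) {
      g <- compute_glcm(image, d, ang, n_levels = n_levels)
      acc <- acc + glcm_selected_features(g$matrix)
    }
    acc <- acc / length(angles)
    names(acc) <- paste0(names(acc), "_d", d)
    out <- c(out, acc)
  }
  out
}
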