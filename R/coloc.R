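#' Costes automatic thresholds for two-channel colocalization
#'
#' Fits the channel-2-vs-channel-1 intensity relation by orthogonal (total
#' least squares) regression, then walks candidate thresholds `T1` down
#' from the channel-1 maximum along the sorted unique channel-1 intensities
#' with `T2 = a * T1 + b`, stopping at the first level where the Pearson
#' correlation of the pixels below both thresholds falls to <= 0 (or the
#' candidates are exhausted). If the global Pearson is <= 0 or the
#' regression slope is <= 0 the thresholds fall back to the channel minima
#' so that all pixels are retained.
#'
#' @param ch1,ch2 `pixel_image`s of identical shape with >= 100 pixels.
#' @param roi optional `roi_spec` applied to both channels.
#' @param ordinary_regression use ordinary instead of orthogonal regression
#'   for the threshold line.
#' @return A list with `t1`, `t2`, `slope`, `intercept`, `fallback`
#'   (logical), and `global_pearson`.
#' @export
costes_thresholds <- function(ch1, ch2, roi = NULL,
                              ordinary_regression = FALSE) {
  stopifnot(inherits(ch1, "pixel_image"), inherits(ch2, "pixel_image"))
  if (!is.null(roi)) {
    ch1 <- crop_roi(ch1, roi); ch2 <- crop_roi(ch2, roi)
  }
  if (!all(dim(ch1$pixels) == dim(ch2$pixels))) {
    stop("channels must have the same shape")
  }
  x <- as.vector(ch1$pixels); y <- as.vector(ch2$pixels)
  if (length(x) < 100) stop("need at least 100 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant channel")
  r_global <- stats::cor(x, y)
  if (ordinary_regression) {
    a <- stats::cov(x, y) / stats::var(x)
  } else {
    # orthogonal regression slope from the covariance eigenstructure
    vx <- stats::var(x); vy <- stats::var(y); cxy <- stats::cov(x, y)
    a <- (vy - vx + sqrt((vy - vx)^2 + 4 * cxy^2)) / (2 * cxy)
  }
  b <- mean(y) - a * mean(x)
  if (r_global <= 0 || a <= 0) {
    return(list(t1 = min(x), t2 = min(y), slope = a, intercept = b,
                fallback = TRUE, global_pearson = r_global))
  }
  cands <- sort(unique(x), decreasing = TRUE)
  t1 <- cands[length(cands)]  # default: lowest level if never uncorrelated
  # exact discrete search, evaluated incrementally: a pixel belongs to the
  # below-threshold set {x < T1, y < a T1 + b} iff T1 > max(x, (y - b)/a),
  # so as T1 descends pixels only ever leave the set; running sums give the
  # below-set Pearson in O(1) per candidate level
  t_exit <- pmax(x, (y - b) / a)
  ord <- order(t_exit, decreasing = TRUE)
  xs <- x[ord]; ys <- y[ord]; te <- t_exit[ord]
  n_tot <- length(x)
  n <- n_tot; sx <- sum(xs); sy <- sum(ys)
  sxx <- sum(xs^2); syy <- sum(ys^2); sxy <- sum(xs * ys)
  ptr <- 1L
  for (cand in cands) {
    while (ptr <= n_tot && te[ptr] >= cand) {
      n <- n - 1L
      sx <- sx - xs[ptr]; sy <- sy - ys[ptr]
      sxx <- sxx - xs[ptr]^2; syy <- syy - ys[ptr]^2
      sxy <- sxy - xs[ptr] * ys[ptr]
      ptr <- ptr + 1L
    }
    if (n < 2) next
    vx_n <- n * sxx - sx^2
    vy_n <- n * syy - sy^2
    if (vx_n <= 0 || vy_n <= 0) next
    r_below <- (n * sxy - sx * sy) / sqrt(vx_n * vy_n)
    if (r_below <= 0) {
      t1 <- cand
      break
    }
  }
  list(t1 = t1, t2 = a * t1 + b, slope = a, intercept = b,
       fallback = FALSE, global_pearson = r_global)
}

#' Pearson correlation above Costes thresholds
#'
#' Computes the Pearson correlation over the pixels above the automatic
#' thresholds (by default the union: `ch1 > T1` OR `ch2 > T2`). When the
#' threshold search fell back (non-positive global correlation or slope),
#' the reported coefficient is the global Pearson, so segregated or
#' excluded channel pairs keep their negative correlation.
#'
#' @inheritParams costes_thresholds
#' @param psf_px point-spread-function size in px, stored for the optional
#'   block-scramble significance test; it does not affect the coefficient.
#' @param combine `"or"` (default) or `"and"` pixel-set rule.
#' @return A list of class `coloc_result`: `pearson_above_threshold`,
#'   `global_pearson`, `t1`, `t2`, `slope`, `intercept`, `n_pixels_used`,
#'   `fallback`, `psf_px`, `combine`.
#' @export
pearson_above_threshold <- function(ch1, ch2, roi = NULL, psf_px = 2,
                                    combine = c("or", "and"),
                                    ordinary_regression = FALSE) {
  combine <- match.arg(combine)
  if (!is.null(roi)) {
    ch1 <- crop_roi(ch1, roi); ch2 <- crop_roi(ch2, roi)
    roi <- NULL
  }
  th <- costes_thresholds(ch1, ch2, ordinary_regression = ordinary_regression)
  x <- as.vector(ch1$pixels); y <- as.vector(ch2$pixels)
  if (th$fallback) {
    sel <- rep(TRUE, length(x))
    r <- th$global_pearson
  } else {
    sel <- if (combine == "or") x > th$t1 | y > th$t2
           else x > th$t1 & y > th$t2
    if (sum(sel) < 2) stop("fewer than 2 pixels above threshold")
    r <- stats::cor(x[sel], y[sel])
  }
  structure(list(pearson_above_threshold = r,
                 global_pearson = th$global_pearson,
                 t1 = th$t1, t2 = th$t2, slope = th$slope,
                 intercept = th$intercept, n_pixels_used = sum(sel),
                 fallback = th$fallback, psf_px = psf_px,
                 combine = combine),
            class = "coloc_result")
}

#' Line profile container
#'
#' @param positions_nm strictly increasing sample positions along the line.
#' @param intensities averaged intensities at those positions.
#' @param endpoints optional 2 x 2 matrix of the line endpoints (px).
#' @param width_px averaging width used during extraction.
#' @return A list of class `line_profile`.
#' @export
line_profile <- function(positions_nm, intensities, endpoints = NULL,
                         width_px = 1) {
  if (length(positions_nm) != length(intensities)) {
    stop("positions and intensities differ in length")
  }
  if (any(diff(positions_nm) <= 0)) stop("positions must strictly increase")
  structure(list(positions_nm = as.numeric(positions_nm),
                 intensities = as.numeric(intensities),
                 endpoints = endpoints, width_px = width_px),
            class = "line_profile")
}

# bilinear interpolation at 0-based (x, y) coordinates
bilinear <- function(px, x, y) {
  h <- nrow(px); w <- ncol(px)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  g <- function(yy, xx) px[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x1) +
    (1 - fx) * fy * g(y1, x0) + fx * fy * g(y1, x1)
}

#' Extract an averaged intensity profile along a straight line
#'
#' Samples the image at one-pixel steps along the line between two
#' endpoints and averages over `width_px` equally spaced parallel offsets
#' spanning the averaging band, using bilinear interpolation. The defaults
#' (0.3 um length, 10 px averaging width) are the standard strand-width
#' measurement settings.
#'
#' @param image a `pixel_image`.
#' @param endpoints 2 x 2 matrix, rows = the two endpoints, columns =
#'   0-based (x, y) pixel coordinates. If only the first endpoint and
#'   `angle_deg` are given, the second is placed `length_nm` away.
#' @param length_nm line length when constructing from `angle_deg`.
#' @param width_px number of parallel offsets averaged (band width in px).
#' @param angle_deg line direction when `endpoints` has one row.
#' @return A `line_profile`.
#' @export
extract_profile <- function(image, endpoints, length_nm = 300,
                            width_px = 10, angle_deg = 0) {
  stopifnot(inherits(image, "pixel_image"))
  endpoints <- matrix(endpoints, ncol = 2)
  ps <- image$pixel_size_nm
  if (nrow(endpoints) == 1) {
    d <- length_nm / ps
    th <- angle_deg * pi / 180
    endpoints <- rbind(endpoints,
                       endpoints[1, ] + d * c(cos(th), sin(th)))
  }
  p1 <- endpoints[1, ]; p2 <- endpoints[2, ]
  v <- p2 - p1
  len_px <- sqrt(sum(v^2))
  if (len_px <= 0) stop("degenerate line")
  u <- v / len_px
  perp <- c(-u[2], u[1])
  n_samples <- max(7L, floor(len_px) + 1L)
  t_px <- seq(0, len_px, length.out = n_samples)
  offsets <- if (width_px > 1) {
    seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  } else 0
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  prof <- numeric(n_samples)
  for (o in offsets) {
    xs <- p1[1] + t_px * u[1] + o * perp[1]
    ys <- p1[2] + t_px * u[2] + o * perp[2]
    if (any(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1)) {
      stop("line (with averaging band) exits the image")
    }
    prof <- prof + bilinear(image$pixels, xs, ys)
  }
  line_profile(t_px * ps, prof / length(offsets), endpoints, width_px)
}

#' Fit a Gaussian to a line profile and report the FWHM
#'
#' Least-squares fit of `amplitude * exp(-(x - center)^2 / (2 sigma^2)) +
#' offset`, initialized from the profile's maximum, argmax and half-range
#' width. The FWHM is reported as `2.35 * sigma`, the conversion factor
#' used for strand-width measurements.
#'
#' @param profile a `line_profile` with >= 7 samples.
#' @return A list of class `gaussian_fit`: `amplitude`, `center_nm`,
#'   `sigma_nm`, `offset`, `fwhm_nm`, `residual_norm`, `converged`.
#' @export
fit_line_profile <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$positions_nm; y <- profile$intensities
  if (length(x) < 7) stop("need at least 7 samples")
  failed <- structure(list(amplitude = NA_real_, center_nm = NA_real_,
                           sigma_nm = NA_real_, offset = NA_real_,
                           fwhm_nm = NA_real_, residual_norm = NA_real_,
                           converged = FALSE),
                      class = "gaussian_fit")
  if (diff(range(y)) == 0) return(failed)
  off0 <- min(y); amp0 <- max(y) - off0; c0 <- x[which.max(y)]
  above <- x[y >= off0 + amp0 / 2]
  sd0 <- max((max(above) - min(above)) / 2.355, diff(range(x)) / 50)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - m)^2 / (2 * s^2)) + o,
      start = list(a = amp0, m = c0, s = sd0, o = off0),
      lower = c(a = 0, m = min(x), s = 1e-6, o = -Inf),
      upper = c(a = Inf, m = max(x), s = diff(range(x)) * 10, o = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["s"]] <= 1e-6 ||
      cf[["s"]] >= diff(range(x)) * 10 - 1e-9) {
    return(failed)
  }
  structure(list(amplitude = unname(cf[["a"]]),
                 center_nm = unname(cf[["m"]]),
                 sigma_nm = unname(cf[["s"]]),
                 offset = unname(cf[["o"]]),
                 fwhm_nm = 2.35 * unname(cf[["s"]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE),
            class = "gaussian_fit")
}

#' Polyline (segmented line) length
#'
#' Length of a traced strand: the sum of Euclidean segment lengths between
#' consecutive points, converted to nm.
#'
#' @param points_px n x 2 matrix of (x, y) pixel coordinates, n >= 2.
#' @param pixel_size_nm physical pixel size in nm.
#' @return Length in nm.
#' @export
polyline_length <- function(points_px, pixel_size_nm) {
  points_px <- matrix(points_px, ncol = 2)
  if (nrow(points_px) < 2) stop("need at least 2 points")
  steps <- sqrt(rowSums(diff(points_px)^2))
  sum(steps) * pixel_size_nm
}
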