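# Internal raster helpers shared by the texture, segmentation and synthesis
# modules. Convolution is delegated to EBImage::filter2 on a reflect-padded
# grid so that all filters see mirrored borders; connected-component
# labelling builds on EBImage::bwlabel (4-connected), with 8-connectivity
# obtained by merging labels across diagonal adjacencies.

# reflect-pad a matrix by `pad` pixels on every side
pad_reflect <- function(m, pad) {
  h <- nrow(m); w <- ncol(m)
  if (pad >= h || pad >= w) stop("image smaller than filter support")
  ri <- c(rev(seq_len(pad) + 1L), seq_len(h), h - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(w), w - seq_len(pad))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflected borders; kernel must have odd dimensions
convolve_reflect <- function(m, kernel) {
  pad <- max(dim(kernel)) %/% 2L
  padded <- pad_reflect(m, pad)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m)), drop = FALSE]
}

# sampled, renormalized 2D Gaussian kernel of given half-width (px)
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# connected components of a logical mask; connectivity 4 or 8.
# Returns an integer label matrix (0 = background).
label_components <- function(mask, connectivity = 4L) {
  mask <- mask != 0
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  # merge 4-connected labels that touch diagonally
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2],
                 , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  remap <- seq_len(max(lab))
  members <- as.integer(igraph::V(g)$name)
  remap[members] <- max(lab) + comp$membership  # temporary ids
  remap0 <- c(0L, remap)                        # slot for background 0
  new <- matrix(remap0[lab + 1L], h, w)
  # renumber consecutively
  u <- sort(unique(new[new > 0L]))
  final <- integer(max(u))
  final[u] <- seq_along(u)
  out <- matrix(0L, h, w)
  out[new > 0L] <- final[new[new > 0L]]
  out
}

# shift a matrix by (dy, dx), filling vacated cells with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# number of foreground 8-neighbours of every pixel
neighbor_count <- function(mask) {
  s <- matrix(0, nrow(mask), ncol(mask))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + shift_mat(mask, dy, dx)
  }
  s
}

# Zhang-Suen thinning of a binary mask to a 1-px-wide 8-connected skeleton
thin_mask <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  # clockwise 8-neighbourhood starting north
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
      b <- Reduce(`+`, nb)
      a <- matrix(0, nrow(m), ncol(m))
      for (k in 1:8) {
        a <- a + (nb[[k]] == 0) * (nb[[if (k == 8) 1 else k + 1]] == 1)
      }
      p2 <- nb[[1]]; p4 <- nb[[3]]; p6 <- nb[[5]]; p8 <- nb[[7]]
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m != 0
}

# Otsu threshold of a nonnegative response matrix (256-bin histogram),
# via EBImage on the [0, 1]-rescaled values
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (m - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}
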