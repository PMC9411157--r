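#' Multiscale curvilinear (tubularity) response
#'
#' Enhances ridge-like structures such as claudin strands. At each scale
#' `r` the image is probed with the scale-normalized Hessian of a Gaussian
#' of sigma = r px (the Gaussian-smoothed equivalent of gradient flux
#' through a circle of radius r); the per-pixel response is the negated
#' smaller Hessian eigenvalue, clamped at 0 so only bright ridges respond,
#' and the final response is the maximum over scales.
#'
#' @param image a `pixel_image`.
#' @param radii_px probing radii in px; the default `c(2, 3, 4)` brackets a
#'   strand FWHM of roughly 3 px at 20 nm/px.
#' @return A `pixel_image` holding the nonnegative response.
#' @export
tubularity <- function(image, radii_px = c(2, 3, 4)) {
  stopifnot(inherits(image, "pixel_image"))
  if (length(radii_px) == 0 || any(radii_px < 1)) {
    stop("radii_px must be non-empty with every radius >= 1")
  }
  px <- image$pixels
  if (max(radii_px) >= min(dim(px)) / 2) {
    stop("radius >= half the ROI size")
  }
  resp <- matrix(0, nrow(px), ncol(px))
  for (r in radii_px) {
    rad <- ceiling(3 * r)
    x <- seq(-rad, rad)
    g <- exp(-x^2 / (2 * r^2)); g <- g / sum(g)
    gx <- -x / r^2 * g                       # first derivative
    gxx <- (x^2 / r^2 - 1) / r^2 * g         # second derivative
    # separable Hessian filters, gamma-normalized by r^2; zero-sum
    # correction removes the DC leakage of the truncated kernels
    hxx <- r^2 * outer(g, gxx); hxx <- hxx - mean(hxx)
    hyy <- r^2 * outer(gxx, g); hyy <- hyy - mean(hyy)
    hxy <- r^2 * outer(gx, gx); hxy <- hxy - mean(hxy)
    ixx <- convolve_reflect(px, hxx)
    iyy <- convolve_reflect(px, hyy)
    ixy <- convolve_reflect(px, hxy)
    tr <- ixx + iyy
    disc <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
    lam_low <- (tr - disc) / 2
    resp <- pmax(resp, -lam_low)
  }
  out <- pixel_image(pmax(resp, 0), image$pixel_size_nm, image$channel_name)
  attr(out, "tubularity_scales_px") <- radii_px
  out
}

#' Threshold a tubularity response into a meshwork mask
#'
#' Applies a fixed threshold and keeps only the largest 8-connected
#' component. An all-below-threshold response yields an empty-flagged mask
#' rather than an error so the quality filter can drop the ROI.
#'
#' @param response a `pixel_image`, typically from [tubularity()].
#' @param threshold finite threshold; `NULL` selects the Otsu threshold of
#'   this response (see [calibrate_threshold()] for freezing one threshold
#'   across a dataset).
#' @return An object of class `meshwork_mask`: logical matrix `mask`,
#'   `pixel_size_nm`, `threshold_used`, `empty` flag.
#' @export
segment_meshwork <- function(response, threshold = NULL) {
  stopifnot(inherits(response, "pixel_image"))
  if (is.null(threshold)) threshold <- otsu_threshold(response$pixels)
  if (!is.finite(threshold)) stop("threshold must be finite")
  raw <- response$pixels >= threshold
  scales <- attr(response, "tubularity_scales_px")
  if (!any(raw)) {
    return(structure(list(mask = raw, pixel_size_nm = response$pixel_size_nm,
                          threshold_used = threshold,
                          tubularity_scales_px = scales, empty = TRUE),
                     class = "meshwork_mask"))
  }
  lab <- label_components(raw, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- sizes == max(sizes)
  if (sum(biggest) > 1L) {
    # tie-break: component whose topmost-leftmost pixel comes first in
    # row-major (y, then x) scan order
    cand <- which(biggest)
    first_idx <- vapply(cand, function(l) {
      pos <- which(lab == l)
      yx <- cbind((pos - 1L) %% nrow(lab), (pos - 1L) %/% nrow(lab))
      min(yx[, 1] * ncol(lab) + yx[, 2])
    }, numeric(1))
    keep <- cand[which.min(first_idx)]
  } else {
    keep <- which(biggest)
  }
  structure(list(mask = lab == keep, pixel_size_nm = response$pixel_size_nm,
                 threshold_used = threshold,
                 tubularity_scales_px = scales, empty = FALSE),
            class = "meshwork_mask")
}

#' Freeze one segmentation threshold across a calibration set
#'
#' The segmentation uses a fixed threshold on the tubularity response. To
#' make that constant reproducible it is taken as the mean Otsu threshold
#' over a calibration set of responses and then applied unchanged to every
#' image of the analysis.
#'
#' @param responses list of `pixel_image` tubularity responses.
#' @return A single numeric threshold.
#' @export
calibrate_threshold <- function(responses) {
  stopifnot(length(responses) >= 1)
  mean(vapply(responses, function(r) otsu_threshold(r$pixels), numeric(1)))
}

#' Skeletonize a meshwork mask and measure its branch graph
#'
#' Thins the mask to a 1-px-wide 8-connected skeleton, decomposes it into
#' endpoint/junction nodes and branch edges, and reports branch counts and
#' lengths plus junction multiplicities. Branch length is the sum of
#' inter-pixel steps (1 or sqrt(2) px) times the pixel size, measured
#' between node pixels; junction pixels that touch each other are merged
#' into a single junction cluster whose multiplicity is the number of
#' incident branches (3 = triple, 4 = quadruple). Branches start at the
#' cluster rim, so steps interior to a junction cluster are not attributed
#' to any branch.
#'
#' @param mask a `meshwork_mask` (non-empty).
#' @return A list of class `skeleton_stats`: `n_branches`,
#'   `avg_branch_len_nm`, `max_branch_len_nm`, `n_junctions_total`,
#'   `n_triple`, `n_quadruple`, and the logical `skeleton` matrix.
#' @export
skeletonize_and_measure <- function(mask) {
  stopifnot(inherits(mask, "meshwork_mask"))
  if (isTRUE(mask$empty) || !any(mask$mask)) stop("empty mask")
  skel <- thin_mask(mask$mask)
  measure_skeleton(skel, mask$pixel_size_nm)
}

# branch/junction analysis of an already 1-px skeleton (logical matrix)
measure_skeleton <- function(skel, pixel_size_nm) {
  h <- nrow(skel); w <- ncol(skel)
  deg <- neighbor_count(matrix(as.numeric(skel), h, w))
  deg[!skel] <- -1
  is_junction <- skel & deg >= 3
  is_end <- skel & deg == 1
  is_node <- is_junction | is_end
  # node ids: junction pixels clustered 8-connected, endpoints individual
  node_id <- matrix(0L, h, w)
  n_junctions <- 0L
  if (any(is_junction)) {
    jlab <- label_components(is_junction, connectivity = 8L)
    n_junctions <- max(jlab)
    node_id[jlab > 0L] <- jlab[jlab > 0L]
  }
  ends <- which(is_end)
  if (length(ends)) node_id[ends] <- n_junctions + seq_along(ends)

  nb_offsets <- expand.grid(dy = -1:1, dx = -1:1)
  nb_offsets <- nb_offsets[!(nb_offsets$dy == 0 & nb_offsets$dx == 0), ]
  neighbors_of <- function(y, x) {
    ys <- y + nb_offsets$dy; xs <- x + nb_offsets$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    cbind(ys[ok], xs[ok])[skel[cbind(ys[ok], xs[ok])], , drop = FALSE]
  }
  step_len <- function(y1, x1, y2, x2) {
    if (y1 != y2 && x1 != x2) sqrt(2) else 1
  }

  visited <- matrix(FALSE, h, w)        # regular (degree-2) pixels walked
  edge_keys <- character(0)             # node-node single-step edges seen
  branch_len <- numeric(0)
  branch_nodes <- list()

  node_pixels <- which(node_id > 0L)
  for (p in node_pixels) {
    y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
    for (i in seq_len(nrow(nb <- neighbors_of(y, x)))) {
      ny <- nb[i, 1]; nx <- nb[i, 2]
      nid <- node_id[ny, nx]
      if (nid > 0L) {
        if (nid == node_id[y, x]) next  # inside the same junction cluster
        key <- paste(sort(c(p, (nx - 1L) * h + ny)), collapse = "-")
        if (key %in% edge_keys) next
        edge_keys <- c(edge_keys, key)
        branch_len <- c(branch_len, step_len(y, x, ny, nx))
        branch_nodes[[length(branch_nodes) + 1L]] <- c(node_id[y, x], nid)
      } else if (!visited[ny, nx]) {
        # walk a degree-2 chain until the next node pixel
        len <- step_len(y, x, ny, nx)
        py <- y; px_ <- x; cy <- ny; cx <- nx
        repeat {
          visited[cy, cx] <- TRUE
          nxt <- neighbors_of(cy, cx)
          nxt <- nxt[!(nxt[, 1] == py & nxt[, 2] == px_), , drop = FALSE]
          if (nrow(nxt) == 0L) {       # isolated spur end (shouldn't occur)
            branch_len <- c(branch_len, len)
            branch_nodes[[length(branch_nodes) + 1L]] <- c(node_id[y, x], 0L)
            break
          }
          ty <- nxt[1, 1]; tx <- nxt[1, 2]
          len <- len + step_len(cy, cx, ty, tx)
          if (node_id[ty, tx] > 0L) {
            branch_len <- c(branch_len, len)
            branch_nodes[[length(branch_nodes) + 1L]] <-
              c(node_id[y, x], node_id[ty, tx])
            break
          }
          py <- cy; px_ <- cx; cy <- ty; cx <- tx
        }
      }
    }
  }
  # closed loops with no node pixels: each remaining chain is one branch
  leftover <- skel & !visited & node_id == 0L
  while (any(leftover)) {
    p <- which(leftover)[1]
    y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
    len <- 0; py <- y; px_ <- x; cy <- y; cx <- x
    repeat {
      leftover[cy, cx] <- FALSE
      nxt <- neighbors_of(cy, cx)
      nxt <- nxt[leftover[nxt], , drop = FALSE]
      if (nrow(nxt) == 0L) {
        # close the loop back to the start
        if (!(cy == y && cx == x)) len <- len + step_len(cy, cx, y, x)
        break
      }
      ty <- nxt[1, 1]; tx <- nxt[1, 2]
      len <- len + step_len(cy, cx, ty, tx)
      py <- cy; px_ <- cx; cy <- ty; cx <- tx
    }
    branch_len <- c(branch_len, len)
    branch_nodes[[length(branch_nodes) + 1L]] <- c(0L, 0L)
  }

  # junction multiplicities = number of incident branch ends
  mult <- integer(n_junctions)
  for (bn in branch_nodes) {
    for (nid in bn) {
      if (nid >= 1L && nid <= n_junctions) mult[nid] <- mult[nid] + 1L
    }
  }
  n <- length(branch_len)
  structure(list(
    n_branches = n,
    avg_branch_len_nm = if (n) mean(branch_len) * pixel_size_nm else 0,
    max_branch_len_nm = if (n) max(branch_len) * pixel_size_nm else 0,
    n_junctions_total = n_junctions,
    n_triple = sum(mult == 3L),
    n_quadruple = sum(mult == 4L),
    skeleton = skel
  ), class = "skeleton_stats")
}

#' Mesh-size statistics of a meshwork mask
#'
#' Inverts the mask and takes its 4-connected background components that do
#' not touch the ROI border as the meshes (enclosed polygons). Areas are
#' converted to nm^2 via the squared pixel size.
#'
#' @param mask a `meshwork_mask` covering the full ROI.
#' @return A list of class `mesh_stats`: `n_meshes`, `mean_mesh_area_nm2`,
#'   `var_mesh_area_nm2` (sample variance; 0 for a single mesh, `NA` for
#'   none), `pct_segmented_area`, and the per-mesh `areas_px2`.
#' @export
mesh_statistics <- function(mask) {
  stopifnot(inherits(mask, "meshwork_mask"))
  m <- mask$mask
  lab <- label_components(!m, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mesh_labels <- setdiff(seq_len(max(lab, 0L)), border)
  areas <- if (length(mesh_labels)) {
    tabulate(lab[lab > 0L], nbins = max(lab))[mesh_labels]
  } else numeric(0)
  n <- length(areas)
  ps2 <- mask$pixel_size_nm^2
  structure(list(
    n_meshes = n,
    mean_mesh_area_nm2 = if (n) mean(areas) * ps2 else NA_real_,
    var_mesh_area_nm2 = if (n >= 2) stats::var(areas * ps2)
                        else if (n == 1) 0 else NA_real_,
    pct_segmented_area = 100 * sum(m) / length(m),
    areas_px2 = areas
  ), class = "mesh_stats")
}

# label matrix + ids of enclosed (border-excluded) background components
mesh_labels <- function(mask) {
  lab <- label_components(!mask, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  list(labels = lab,
       interior = setdiff(seq_len(max(lab, 0L)), border[border > 0L]))
}

#' Mesh correspondence between a ground-truth and a measured mask
#'
#' Matches the enclosed meshes of a measured segmentation against those of
#' a ground-truth strand mask by pixel overlap. Used to validate that
#' segmentation recovers every true mesh one-to-one. Cells that reach the
#' image border are open in a thin-strand truth mask but can be sealed
#' shut by a thicker segmented band; measured meshes confined to the
#' border band are therefore reported separately instead of counting as
#' spurious detections.
#'
#' @param truth_mask logical matrix of true strand pixels.
#' @param measured_mask logical matrix of segmented strand pixels (same
#'   shape).
#' @param border_margin_px extras whose extent comes within this distance
#'   of the border are classed as border-band effects.
#' @param min_area_truth_px2 only truth meshes at least this large must be
#'   recovered (e.g. 5x the strand width); smaller ones are ignored.
#' @param min_area_measured_px2 measured enclosures below this area are
#'   discarded as pinholes inside thick strands (default 9 px^2).
#' @return List with `n_truth`, `n_matched` (truth meshes overlapped by
#'   exactly one measured mesh), `n_merged`, `n_split`,
#'   `n_extra_interior`, `n_extra_border`.
#' @export
mesh_correspondence <- function(truth_mask, measured_mask,
                                border_margin_px = 6,
                                min_area_truth_px2 = 0,
                                min_area_measured_px2 = 9) {
  stopifnot(all(dim(truth_mask) == dim(measured_mask)))
  h <- nrow(truth_mask); w <- ncol(truth_mask)
  mt <- mesh_labels(truth_mask != 0)
  mm <- mesh_labels(measured_mask != 0)
  big <- function(ml, min_area) {
    keep <- ml$interior
    if (min_area > 0 && length(keep)) {
      areas <- tabulate(ml$labels[ml$labels > 0L], nbins = max(ml$labels))
      keep <- keep[areas[keep] >= min_area]
    }
    keep
  }
  it <- big(mt, min_area_truth_px2)
  im <- big(mm, min_area_measured_px2)
  overlaps_of <- function(k, lab_from, lab_to, valid) {
    o <- lab_to[lab_from == k]
    unique(o[o > 0L & o %in% valid])
  }
  fwd <- lapply(it, overlaps_of, lab_from = mt$labels, lab_to = mm$labels,
                valid = im)
  rev_ <- lapply(im, overlaps_of, lab_from = mm$labels, lab_to = mt$labels,
                 valid = it)
  names(rev_) <- as.character(im)
  # matched = bijective: one measured partner that itself covers only this
  # truth mesh
  n_matched <- 0L; n_split <- 0L
  for (i in seq_along(it)) {
    hits <- fwd[[i]]
    if (length(hits) > 1L) n_split <- n_split + 1L
    if (length(hits) == 1L &&
        length(rev_[[as.character(hits)]]) == 1L) {
      n_matched <- n_matched + 1L
    }
  }
  n_merged <- 0L; n_extra_interior <- 0L; n_extra_border <- 0L
  for (k in im) {
    hits <- rev_[[as.character(k)]]
    if (length(hits) > 1L) n_merged <- n_merged + 1L
    if (length(hits) == 0L) {
      rc <- which(mm$labels == k, arr.ind = TRUE)
      near_border <- min(rc[, 1] - 1L, h - rc[, 1], rc[, 2] - 1L,
                         w - rc[, 2]) < border_margin_px
      if (near_border) n_extra_border <- n_extra_border + 1L
      else n_extra_interior <- n_extra_interior + 1L
    }
  }
  list(n_truth = length(it), n_matched = n_matched, n_merged = n_merged,
       n_split = n_split, n_extra_interior = n_extra_interior,
       n_extra_border = n_extra_border)
}

#' Quality filter for per-ROI feature rows
#'
#' An ROI is kept only if its segmented area lies within 10-90 % of the ROI
#' (both bounds inclusive; "less/more than" are strict exclusions) and its
#' skeleton has at least 10 branches.
#'
#' @param row a list or one-row data frame with `pct_segmented_area` and
#'   `n_branches`.
#' @return A list with logical `keep` and a `reason` string recording which
#'   rule fired (empty when kept).
#' @export
qc_filter <- function(row) {
  if (is.null(row$pct_segmented_area) || is.null(row$n_branches) ||
      is.na(row$pct_segmented_area) || is.na(row$n_branches)) {
    stop("row must contain pct_segmented_area and n_branches")
  }
  reasons <- character(0)
  if (row$pct_segmented_area < 10) reasons <- c(reasons, "area<10%")
  if (row$pct_segmented_area > 90) reasons <- c(reasons, "area>90%")
  if (row$n_branches < 10) reasons <- c(reasons, "branches<10")
  list(keep = length(reasons) == 0L, reason = paste(reasons, collapse = ";"))
}
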