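#' Extract the per-ROI texture and morphometry feature row
#'
#' Runs the full single-ROI pipeline: Gaussian prefilter and selected
#' Haralick features on the intensity image; tubularity filtering, fixed
#' thresholding with largest-component selection, skeleton branch/junction
#' analysis and mesh-size statistics on the segmentation side; and the
#' area/branch quality flags.
#'
#' @param image a `pixel_image` (already cropped to the ROI).
#' @param sample_id,roi_id,group_label identifiers carried into the row.
#' @param threshold fixed segmentation threshold; `NULL` = per-image Otsu
#'   (see [calibrate_threshold()] to freeze one across a dataset).
#' @param radii_px tubularity scales in px.
#' @return One-row data frame with identifiers, the 12 texture features,
#'   the 10 morphometry features, and `qc_keep`/`qc_reason`.
#' @export
extract_features <- function(image, sample_id = "sample", roi_id = 1L,
                             group_label = "", threshold = NULL,
                             radii_px = c(2, 3, 4)) {
  stopifnot(inherits(image, "pixel_image"))
  tex <- haralick_selected(prefilter_gaussian(image))
  resp <- tubularity(image, radii_px)
  mask <- segment_meshwork(resp, threshold)
  if (mask$empty) {
    morph <- stats::setNames(as.list(rep(0, 10)), morphometry_feature_names())
  } else {
    sk <- skeletonize_and_measure(mask)
    ms <- mesh_statistics(mask)
    morph <- list(
      pct_segmented_area = ms$pct_segmented_area,
      n_branches = sk$n_branches,
      avg_branch_len_nm = sk$avg_branch_len_nm,
      max_branch_len_nm = sk$max_branch_len_nm,
      n_junctions_total = sk$n_junctions_total,
      n_triple = sk$n_triple,
      n_quadruple = sk$n_quadruple,
      n_meshes = ms$n_meshes,
      mean_mesh_area_nm2 = if (is.na(ms$mean_mesh_area_nm2)) 0
                           else ms$mean_mesh_area_nm2,
      var_mesh_area_nm2 = if (is.na(ms$var_mesh_area_nm2)) 0
                          else ms$var_mesh_area_nm2
    )
  }
  row <- data.frame(sample_id = sample_id, roi_id = roi_id,
                    group_label = group_label, as.list(tex), morph,
                    stringsAsFactors = FALSE)
  qc <- qc_filter(row)
  row$qc_keep <- qc$keep
  row$qc_reason <- qc$reason
  row
}

#' Simulate a meshwork-class image library and extract its features
#'
#' Generates `n_per_class` synthetic images for each of the three meshwork
#' archetypes under one master seed, freezes a single segmentation
#' threshold over the library (mean Otsu of the tubularity responses), and
#' extracts one feature row per image. The archetype is recorded as
#' `group_label`, giving ground truth for classification tests.
#'
#' @param n_per_class images per archetype.
#' @param seed master seed; per-image seeds are derived from it.
#' @param archetypes archetype names (default: the three meshwork classes).
#' @param noiseless render without noise.
#' @return Data frame of per-ROI feature rows.
#' @export
simulate_library <- function(n_per_class = 5, seed = 1L,
                             archetypes = c("class_A_large_mesh",
                                            "class_B_small_mesh",
                                            "class_C_dense_parallel"),
                             noiseless = FALSE) {
  images <- list(); labels <- character(0)
  k <- 0L
  for (a in archetypes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cfg <- synth_config(archetype = a, noiseless = noiseless,
                          seed = (seed * 1000L + k) %% .Machine$integer.max)
      images[[k]] <- make_meshwork(cfg)$image
      labels[k] <- a
    }
  }
  responses <- lapply(images, tubularity)
  thr <- calibrate_threshold(responses)
  rows <- vector("list", length(images))
  for (k in seq_along(images)) {
    rows[[k]] <- extract_features(images[[k]],
                                  sample_id = sprintf("img%03d", k),
                                  roi_id = 1L, group_label = labels[k],
                                  threshold = thr)
  }
  do.call(rbind, rows)
}

#' Classify a feature library into meshwork classes
#'
#' The meshwork-former configuration: quality filtering, per-sample
#' aggregation of combined texture + morphometry features, ln(x+1)
#' transform with column unit-variance scaling, correlation-distance
#' average-linkage clustering, and silhouette-based selection of the
#' cluster count.
#'
#' @param rows per-ROI feature rows from [extract_features()].
#' @param k_range candidate cluster counts.
#' @return List with `assignment` (a `cluster_assignment`), `dendrogram`
#'   (`hclust`), `features` (the scaled per-sample matrix), and `purity`
#'   (against `group_label`, when present).
#' @export
classify_library <- function(rows, k_range = 2:6) {
  mat <- build_feature_matrix(rows, mode = "combined")
  scaled <- scale_features(mat, ln_transform = TRUE)
  hc <- hcluster(scaled, metric = "correlation")
  asg <- cut_and_score(hc, k_range)
  purity <- NA_real_
  if ("group_label" %in% names(rows)) {
    truth <- rows$group_label[match(mat$sample_id, rows$sample_id)]
    purity <- cluster_purity(asg$labels, truth)
  }
  list(assignment = asg, dendrogram = hc, features = scaled,
       purity = purity)
}
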