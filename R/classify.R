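#' Assemble the per-sample feature matrix
#'
#' Aggregates per-ROI feature rows into one row per sample by arithmetic
#' mean over that sample's ROIs. `mode = "texture"` keeps the 12 texture
#' columns only (the all-claudin analysis); `mode = "combined"` keeps the
#' texture columns plus the morphometry columns (the meshwork-former
#' analysis) and applies the quality filter first.
#'
#' @param rows data frame of per-ROI rows with `sample_id`, `roi_id`, the
#'   texture columns, and (for combined mode) the morphometry columns.
#' @param mode `"texture"` or `"combined"`.
#' @param apply_qc run [qc_filter()] before aggregation (default: only in
#'   combined mode).
#' @return Data frame with one row per sample; `sample_id` as first column.
#' @export
build_feature_matrix <- function(rows, mode = c("combined", "texture"),
                                 apply_qc = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rows), "sample_id" %in% names(rows))
  if (is.null(apply_qc)) apply_qc <- mode == "combined"
  if (apply_qc) {
    keep <- vapply(seq_len(nrow(rows)),
                   function(i) qc_filter(rows[i, ])$keep, logical(1))
    dropped <- unique(rows$sample_id[!keep])
    rows <- rows[keep, , drop = FALSE]
    lost <- setdiff(dropped, rows$sample_id)
    if (length(lost)) {
      warning("all ROIs dropped by QC for sample(s): ",
              paste(lost, collapse = ", "))
    }
  }
  if (nrow(rows) == 0L) stop("no rows left after QC")
  feature_cols <- if (mode == "texture") texture_feature_names()
                  else c(texture_feature_names(), morphometry_feature_names())
  missing <- setdiff(feature_cols, names(rows))
  if (length(missing)) stop("missing feature column(s): ",
                            paste(missing, collapse = ", "))
  agg <- stats::aggregate(rows[feature_cols],
                          by = list(sample_id = rows$sample_id), FUN = mean)
  if (nrow(agg) < 2L) stop("need at least 2 samples")
  agg[order(agg$sample_id), , drop = FALSE]
}

texture_feature_names <- function(distances_px = c(1L, 3L, 5L, 10L)) {
  as.vector(vapply(distances_px, function(d) {
    paste0(c("sum_average", "sum_variance", "variance_sos"), "_d", d)
  }, character(3)))
}

morphometry_feature_names <- function() {
  c("pct_segmented_area", "n_branches", "avg_branch_len_nm",
    "max_branch_len_nm", "n_junctions_total", "n_triple", "n_quadruple",
    "n_meshes", "mean_mesh_area_nm2", "var_mesh_area_nm2")
}

#' Scale a feature table for clustering
#'
#' Optionally applies `ln(x + 1)` per cell (morphometry features can be 0,
#' where a plain log is undefined), then centers every column to mean 0 and
#' scales it to unit variance. Constant columns are set to 0 with a warning.
#'
#' @param table data frame from [build_feature_matrix()] (non-feature
#'   columns such as `sample_id` are carried through untouched).
#' @param ln_transform apply `ln(x + 1)` first.
#' @return The table with scaled feature columns.
#' @export
scale_features <- function(table, ln_transform = FALSE) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  x <- as.matrix(table[num])
  if (any(is.na(x))) stop("NaN/NA in feature table")
  if (ln_transform) {
    if (any(x <= -1)) stop("ln(x + 1) undefined for values <= -1")
    x <- log(x + 1)
  }
  x <- scale(x)
  const <- attr(x, "scaled:scale") == 0 | !is.finite(attr(x, "scaled:scale"))
  if (any(const)) {
    warning("constant column(s) set to 0: ",
            paste(colnames(x)[const], collapse = ", "))
    x[, const] <- 0
  }
  table[num] <- as.data.frame(x)
  table
}

#' Agglomerative hierarchical clustering of feature rows
#'
#' Average-linkage clustering under either euclidean distance or
#' correlation distance (1 - Pearson correlation between rows), the two
#' configurations used for the all-claudin and meshwork-former analyses.
#'
#' @param table data frame whose numeric columns are the features; a
#'   `sample_id` column supplies leaf labels.
#' @param metric `"correlation"` (default, meshwork-former analysis) or
#'   `"euclidean"` (all-claudin analysis).
#' @return An `hclust` object with extra fields `metric` and `dist` (the
#'   distance object used).
#' @export
hcluster <- function(table, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(table[vapply(table, is.numeric, logical(1))])
  if (nrow(x) < 2L) stop("need at least 2 rows")
  rownames(x) <- if ("sample_id" %in% names(table)) table$sample_id
                 else seq_len(nrow(x))
  if (metric == "correlation") {
    if (ncol(x) < 2L) stop("correlation distance needs >= 2 columns")
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) stop("constant row under correlation metric")
    d <- stats::as.dist(1 - stats::cor(t(x)))
  } else {
    d <- stats::dist(x, method = "euclidean")
  }
  hc <- stats::hclust(d, method = "average")
  hc$metric <- metric
  hc$dist <- d
  hc
}

#' Cut a dendrogram and select the cluster count by silhouette
#'
#' Cuts the tree at each candidate `k`, scores the assignment by mean
#' silhouette width under the same distance used for clustering, and
#' returns the assignment with the highest mean silhouette (ties go to the
#' smallest k). An explicit criterion replaces a visual cut so the cluster
#' count is reproducible.
#'
#' @param hc result of [hcluster()].
#' @param k_range candidate cluster counts, each within `2 .. n - 1`.
#' @return A list of class `cluster_assignment`: `labels` (named integer
#'   vector in `1..k`), `k`, `silhouette` per leaf, `mean_silhouette`, and
#'   the per-k score table.
#' @export
cut_and_score <- function(hc, k_range = 2:6) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop("each k must satisfy 2 <= k <= n - 1")
  }
  scores <- data.frame(k = k_range, mean_silhouette = NA_real_)
  best <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    labels <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(labels, dist = hc$dist)
    ms <- mean(sil[, "sil_width"])
    scores$mean_silhouette[i] <- ms
    if (is.null(best) || ms > best$mean_silhouette + 1e-12) {
      best <- list(labels = labels, k = k, silhouette = sil[, "sil_width"],
                   mean_silhouette = ms)
    }
  }
  best$scores <- scores
  class(best) <- "cluster_assignment"
  best
}

#' Principal component scores of a scaled feature table
#'
#' @param table data frame whose numeric columns are the (already scaled)
#'   features.
#' @param n_components number of components to keep; must not exceed
#'   `min(n_rows - 1, n_cols)`.
#' @return A list with `scores` (rows x components), `explained_variance`
#'   (fractions, non-increasing, summing to <= 1), and `rotation`.
#' @export
pca_scores <- function(table, n_components = 2L) {
  x <- as.matrix(table[vapply(table, is.numeric, logical(1))])
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stop("n_components exceeds min(n_rows - 1, n_cols)")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE])
}

#' Label purity of a cluster assignment
#'
#' Fraction of samples whose cluster's majority ground-truth label matches
#' their own; 1 means every cluster is pure.
#'
#' @param labels integer cluster labels.
#' @param truth ground-truth class per sample.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  sum(apply(tab, 1, max)) / length(labels)
}
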