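# helper: wrap a logical matrix as a meshwork_mask
as_mask <- function(m, pixel_size_nm = 20) {
  structure(list(mask = m != 0, pixel_size_nm = pixel_size_nm,
                 threshold_used = NA_real_, tubularity_scales_px = NULL,
                 empty = !any(m != 0)),
            class = "meshwork_mask")
}

test_that("tubularity responds to ridges, not constants", {
  const <- pixel_image(matrix(3, 40, 40), 20)
  expect_equal(max(tubularity(const)$pixels), 0, tolerance = 1e-8)

  # straight horizontal ridge of Gaussian cross-section sigma = 2.5 px
  y <- matrix(rep(1:60, 80), 60, 80)
  ridge <- pixel_image(exp(-(y - 30)^2 / (2 * 2.5^2)) * 100, 20)
  resp <- tubularity(ridge)$pixels
  argmax_rows <- apply(resp, 2, which.max)
  expect_true(all(abs(argmax_rows - 30) <= 1))
})

test_that("tubularity response is approximately rotation invariant", {
  n <- 81
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), n), n, n)
  mid <- (n - 1) / 2
  horiz <- exp(-(ys - mid)^2 / (2 * 2.5^2)) * 100
  diag45 <- exp(-((xs - ys) / sqrt(2))^2 / (2 * 2.5^2)) * 100
  r1 <- tubularity(pixel_image(horiz, 20))$pixels
  r2 <- tubularity(pixel_image(diag45, 20))$pixels
  # compare peak response away from borders
  core <- 30:52
  m1 <- max(r1[core, core]); m2 <- max(r2[core, core])
  expect_lt(abs(m1 - m2) / m1, 0.10)
})

test_that("tubularity validates its scales", {
  img <- pixel_image(matrix(runif(100), 10, 10), 20)
  expect_error(tubularity(img, numeric(0)), "non-empty")
  expect_error(tubularity(img, 6), "half the ROI")
})

test_that("segmentation keeps the largest component with declared tie-break", {
  resp <- matrix(0, 20, 30)
  resp[2:5, 2:11] <- 1        # 40 px
  resp[10:17, 5:19] <- 1      # 120 px
  img <- pixel_image(resp, 20)
  mask <- segment_meshwork(img, threshold = 0.5)
  expect_false(mask$empty)
  expect_equal(sum(mask$mask), 120)
  expect_true(all(which(mask$mask, arr.ind = TRUE)[, 1] >= 10))

  empty <- segment_meshwork(pixel_image(resp * 0, 20), threshold = 0.5)
  expect_true(empty$empty)
  expect_equal(sum(empty$mask), 0)

  # two equal components: keep the one whose topmost-leftmost pixel comes
  # first in row-major scan order
  tie <- matrix(0, 10, 10)
  tie[2, 6:9] <- 1   # row 2, starts at x = 6
  tie[4, 2:5] <- 1   # row 4, starts at x = 2
  mt <- segment_meshwork(pixel_image(tie, 20), threshold = 0.5)
  expect_true(mt$mask[2, 6])
  expect_false(any(mt$mask[4, ]))
})

test_that("skeleton morphometry matches hand-constructed shapes", {
  # straight 51-px line: 1 branch, no junctions, 50 steps x 20 nm
  line <- matrix(0, 9, 60); line[5, 5:55] <- 1
  st <- skeletonize_and_measure(as_mask(line))
  expect_equal(st$n_branches, 1)
  expect_equal(st$n_junctions_total, 0)
  expect_equal(st$avg_branch_len_nm, 1000)
  expect_equal(st$max_branch_len_nm, 1000)

  # plus sign: two 21-px perpendicular lines crossing centrally
  plus <- matrix(0, 25, 25)
  plus[13, 3:23] <- 1; plus[3:23, 13] <- 1
  stp <- skeletonize_and_measure(as_mask(plus))
  expect_equal(stp$n_branches, 4)
  expect_equal(stp$n_junctions_total, 1)
  expect_equal(stp$n_quadruple, 1)
  expect_equal(stp$n_triple, 0)
  # arms are measured from the rim of the 5-px junction cluster: 9 steps
  expect_equal(stp$avg_branch_len_nm, 180)

  # T shape: 3 branches, one triple junction
  tee <- matrix(0, 25, 25)
  tee[5, 3:23] <- 1; tee[5:20, 13] <- 1
  stt <- skeletonize_and_measure(as_mask(tee))
  expect_equal(stt$n_branches, 3)
  expect_equal(stt$n_junctions_total, 1)
  expect_equal(stt$n_triple, 1)
  expect_equal(stt$n_quadruple, 0)

  expect_error(skeletonize_and_measure(as_mask(matrix(0, 5, 5))), "empty")
})

test_that("skeleton stays inside the mask with bounded total length", {
  mw <- make_meshwork(synth_config("class_B_small_mesh", seed = 2,
                                   noiseless = TRUE))
  mask <- segment_meshwork(tubularity(mw$image))
  st <- skeletonize_and_measure(mask)
  expect_true(all(mask$mask[st$skeleton]))
  total_len <- st$n_branches * st$avg_branch_len_nm
  expect_lte(total_len, sum(st$skeleton) * sqrt(2) * mask$pixel_size_nm)
  expect_gte(st$max_branch_len_nm, st$avg_branch_len_nm)
})

test_that("mesh statistics match constructed shapes", {
  # 2-px-thick square annulus enclosing an 11x11 hole in a 200x200 ROI
  m <- matrix(0, 200, 200)
  m[50:64, 50:64] <- 1
  m[52:62, 52:62] <- 0
  ms <- mesh_statistics(as_mask(m))
  expect_equal(ms$n_meshes, 1)
  expect_equal(ms$mean_mesh_area_nm2, 121 * 400)
  expect_equal(ms$var_mesh_area_nm2, 0)

  # open C shape: hole connected to the border -> no mesh
  cshape <- m
  cshape[55, 63:64] <- 0
  expect_equal(mesh_statistics(as_mask(cshape))$n_meshes, 0)

  # 2x2 grid of identical cells -> 4 meshes, zero variance
  g <- matrix(0, 40, 40)
  for (i in c(5, 17, 29)) { g[i:(i + 1), 5:30] <- 1; g[5:30, i:(i + 1)] <- 1 }
  mg <- mesh_statistics(as_mask(g))
  expect_equal(mg$n_meshes, 4)
  expect_equal(mg$var_mesh_area_nm2, 0)
})

test_that("mesh statistics equal the flood-fill oracle on random masks", {
  for (s in 1:100) {
    m <- withr::with_seed(s, matrix(stats::runif(15 * 15) < 0.45, 15, 15))
    got <- mesh_statistics(as_mask(m))
    want <- bf_mesh_stats(m, 20)
    expect_equal(got$n_meshes, want$n_meshes)
    expect_equal(got$mean_mesh_area_nm2, want$mean_mesh_area_nm2)
    expect_equal(got$var_mesh_area_nm2, want$var_mesh_area_nm2)
    expect_equal(got$pct_segmented_area, want$pct_segmented_area)
  }
})

test_that("pixel conservation: meshes + mask + border background = ROI", {
  # border-connected background counted independently by 4-neighbour
  # propagation from the border
  border_background <- function(m) {
    inv <- !m
    reach <- matrix(FALSE, nrow(m), ncol(m))
    reach[1, ] <- inv[1, ]; reach[nrow(m), ] <- inv[nrow(m), ]
    reach[, 1] <- inv[, 1]; reach[, ncol(m)] <- inv[, ncol(m)]
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-nrow(m), ]
      grown[-nrow(m), ] <- grown[-nrow(m), ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -ncol(m)]
      grown[, -ncol(m)] <- grown[, -ncol(m)] | reach[, -1]
      grown <- grown & inv
      if (identical(grown, reach)) break
      reach <- grown
    }
    sum(reach)
  }
  for (s in 1:20) {
    m <- withr::with_seed(100 + s, matrix(stats::runif(30 * 30) < 0.4, 30, 30))
    ms <- mesh_statistics(as_mask(m))
    expect_equal(sum(ms$areas_px2) + sum(m) + border_background(m),
                 length(m))
  }
})

test_that("mesh correspondence detects matches, merges, and extras", {
  truth <- matrix(FALSE, 30, 30)
  for (r in c(5, 15, 25)) truth[r, 5:25] <- TRUE
  for (cc in c(5, 15, 25)) truth[5:25, cc] <- TRUE
  # perfect segmentation: every truth mesh matched
  mc <- mesh_correspondence(truth, truth, min_area_measured_px2 = 0)
  expect_equal(mc$n_matched, mc$n_truth)
  expect_equal(mc$n_truth, 4L)
  expect_equal(mc$n_merged + mc$n_split + mc$n_extra_interior, 0L)
  # broken middle wall: two truth meshes merge into one measured mesh
  broken <- truth; broken[8:12, 15] <- FALSE
  mc2 <- mesh_correspondence(truth, broken, min_area_measured_px2 = 0)
  expect_equal(mc2$n_merged, 1L)
  expect_lt(mc2$n_matched, mc2$n_truth)
  # an extra enclosure away from the border counts as interior extra
  extra <- truth
  extra[27:29, 10:12] <- TRUE; extra[28, 11] <- FALSE
  mc3 <- mesh_correspondence(truth, extra, border_margin_px = 0,
                             min_area_measured_px2 = 0)
  expect_equal(mc3$n_extra_interior, 1L)
})

test_that("QC filter applies the area and branch rules inclusively", {
  expect_false(qc_filter(list(pct_segmented_area = 5, n_branches = 50))$keep)
  expect_match(qc_filter(list(pct_segmented_area = 5,
                              n_branches = 50))$reason, "area<10%")
  expect_false(qc_filter(list(pct_segmented_area = 50, n_branches = 9))$keep)
  expect_match(qc_filter(list(pct_segmented_area = 50,
                              n_branches = 9))$reason, "branches<10")
  expect_true(qc_filter(list(pct_segmented_area = 10, n_branches = 10))$keep)
  expect_true(qc_filter(list(pct_segmented_area = 90, n_branches = 10))$keep)
  expect_false(qc_filter(list(pct_segmented_area = 90.5,
                              n_branches = 10))$keep)
  expect_error(qc_filter(list(n_branches = 10)), "must contain")
})
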