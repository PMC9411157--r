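#' Configuration for the synthetic STED-like image generator
#'
#' Defines one generated image: a morphology archetype, the physical scales
#' of its strands, the imaging blur, and a photon-counting noise model.
#' The three meshwork archetypes mirror the three claudin meshwork classes
#' (large polygonal meshes; much smaller meshes; dense, predominantly
#' parallel strands); the remaining archetypes emulate the non-meshwork
#' phenotypes (uniform distribution, small punctae, irregular clusters).
#'
#' Default physical scales: strand cross-section sigma 14 nm plus a PSF
#' sigma of 21 nm (about 50 nm lateral FWHM) renders strands of about
#' 59 nm FWHM at 20 nm/px, matching measured claudin strand widths.
#'
#' @param archetype one of `"class_A_large_mesh"`, `"class_B_small_mesh"`,
#'   `"class_C_dense_parallel"`, `"punctae"`, `"uniform"`, `"clusters"`.
#' @param mean_mesh_diameter_nm target mean mesh diameter (classes A/B) or
#'   strand spacing (class C); defaults 600 / 250 / 150 nm respectively.
#' @param dispersion relative jitter of the tessellation seed lattice
#'   (0 = perfectly regular).
#' @param strand_sigma_nm Gaussian cross-section sigma of rendered strands.
#' @param psf_sigma_nm imaging blur sigma.
#' @param photon_scale expected photon counts at peak signal.
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param pixel_size_nm physical pixel size (default 20 nm, the
#'   texture-analysis convention).
#' @param image_size_px image edge length in px (default 200, the
#'   classification crop size).
#' @param noiseless render the deterministic expected image (no Poisson or
#'   read noise).
#' @param seed integer RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(archetype = c("class_A_large_mesh",
                                       "class_B_small_mesh",
                                       "class_C_dense_parallel",
                                       "punctae", "uniform", "clusters"),
                         mean_mesh_diameter_nm = NULL, dispersion = 0.2,
                         strand_sigma_nm = 14, psf_sigma_nm = 21,
                         photon_scale = 50, read_noise_sd = 1,
                         pixel_size_nm = 20, image_size_px = 200,
                         noiseless = FALSE, seed = 1L) {
  archetype <- match.arg(archetype)
  if (is.null(mean_mesh_diameter_nm)) {
    mean_mesh_diameter_nm <- switch(archetype,
      class_A_large_mesh = 600, class_B_small_mesh = 250,
      class_C_dense_parallel = 150, 300)
  }
  for (v in c(mean_mesh_diameter_nm, strand_sigma_nm, psf_sigma_nm,
              pixel_size_nm)) {
    if (!is.finite(v) || v <= 0) stop("all length scales must be > 0")
  }
  if (photon_scale <= 0) stop("photon_scale must be > 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(as.list(environment()), class = "synth_config")
}

# render a centerline mask into a smooth tube image (peak 1). The strand
# cross-section and the Gaussian PSF compose into a single Gaussian of
# sigma = sqrt(strand^2 + psf^2), evaluated on the distance transform of
# the centerline.
render_tubes <- function(centerline, config) {
  sigma_nm <- sqrt(config$strand_sigma_nm^2 + config$psf_sigma_nm^2)
  d_px <- EBImage::distmap(matrix(as.numeric(!centerline),
                                  nrow(centerline), ncol(centerline)))
  exp(-(as.matrix(d_px) * config$pixel_size_nm)^2 / (2 * sigma_nm^2))
}

# apply the photon-counting noise model to a [0, 1] signal
apply_noise <- function(signal, config) {
  if (config$noiseless) return(config$photon_scale * signal)
  counts <- stats::rpois(length(signal), config$photon_scale * signal)
  counts <- counts + stats::rnorm(length(signal), 0, config$read_noise_sd)
  matrix(pmax(counts, 0), nrow(signal), ncol(signal))
}

# seeded jittered-lattice tessellation: returns cell label matrix, seed
# coordinates (x, y in 0-based px), and the boundary (centerline) mask
make_tessellation <- function(n_px_x, n_px_y, config) {
  area_nm2 <- n_px_x * n_px_y * config$pixel_size_nm^2
  cell_area <- pi * (config$mean_mesh_diameter_nm / 2)^2
  n_seeds <- round(area_nm2 / cell_area)
  if (config$mean_mesh_diameter_nm < 3 * config$pixel_size_nm) {
    stop("mesh diameter below 3 pixels is unresolvable")
  }
  if (n_seeds < 2) stop("image too small for at least one mesh")
  spacing <- sqrt(n_px_x * n_px_y / n_seeds)
  gx <- seq(spacing / 2, n_px_x - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, n_px_y - spacing / 2, by = spacing)
  seeds <- expand.grid(x = gx, y = gy)
  seeds$x <- seeds$x + stats::rnorm(nrow(seeds), 0, config$dispersion * spacing)
  seeds$y <- seeds$y + stats::rnorm(nrow(seeds), 0, config$dispersion * spacing)
  seeds$x <- pmin(pmax(seeds$x, 0), n_px_x - 1)
  seeds$y <- pmin(pmax(seeds$y, 0), n_px_y - 1)
  # nearest-seed (discrete Voronoi) labelling by running minimum
  xs <- matrix(rep(0:(n_px_x - 1), each = n_px_y), n_px_y, n_px_x)
  ys <- matrix(rep(0:(n_px_y - 1), n_px_x), n_px_y, n_px_x)
  dmin <- matrix(Inf, n_px_y, n_px_x)
  lab <- matrix(0L, n_px_y, n_px_x)
  for (s in seq_len(nrow(seeds))) {
    d <- (xs - seeds$x[s])^2 + (ys - seeds$y[s])^2
    upd <- d < dmin
    dmin[upd] <- d[upd]
    lab[upd] <- s
  }
  h <- n_px_y; w <- n_px_x
  # 1-px centerline: mark only the left/top pixel of each differing pair
  boundary <- matrix(FALSE, h, w)
  boundary[, -w] <- boundary[, -w] | (lab[, -w] != lab[, -1])
  boundary[-h, ] <- boundary[-h, ] | (lab[-h, ] != lab[-1, ])
  list(labels = lab, seeds = seeds, boundary = boundary,
       expected_cell_area_nm2 = area_nm2 / nrow(seeds))
}

# centerlines of near-parallel, gently crossing sinusoidal strands
make_parallel_strands <- function(n_px, config) {
  spacing_px <- config$mean_mesh_diameter_nm / config$pixel_size_nm
  n_strands <- max(2L, floor(n_px / spacing_px))
  centerline <- matrix(FALSE, n_px, n_px)
  x <- 0:(n_px - 1)
  for (i in seq_len(n_strands)) {
    y0 <- (i - 0.5) * spacing_px + stats::rnorm(1, 0, 0.3 * spacing_px)
    slope <- stats::rnorm(1, 0, 0.06)
    amp <- stats::runif(1, 0.1, 0.4) * spacing_px
    wl <- stats::runif(1, 60, 140)
    phase <- stats::runif(1, 0, 2 * pi)
    y <- round(y0 + slope * (x - n_px / 2) + amp * sin(2 * pi * x / wl + phase))
    ok <- y >= 0 & y <= n_px - 1
    centerline[cbind(y[ok] + 1L, x[ok] + 1L)] <- TRUE
  }
  centerline
}

#' Generate one synthetic STED-like image with ground truth
#'
#' Builds strand centerlines for the configured archetype, renders them as
#' Gaussian-cross-section tubes blurred by the PSF, and corrupts the result
#' with Poisson photon noise plus additive Gaussian read noise (clipped at
#' 0). For tessellation archetypes the returned truth contains the cell
#' labels, per-interior-cell areas, and the interior mesh count (cells
#' whose pixels never touch the image border, matching the border exclusion
#' used when measuring meshes).
#'
#' @param config a [synth_config()].
#' @return A list with `image` (a `pixel_image`), `truth` (list with
#'   `centerline`, `mask` at half-maximum, `n_meshes`, `mesh_areas_px2`,
#'   `expected_cell_area_nm2`, `cell_labels` where applicable), and
#'   `config`.
#' @export
make_meshwork <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, make_meshwork_impl(config))
}

make_meshwork_impl <- function(config) {
  n <- config$image_size_px
  truth <- list(centerline = NULL, mask = NULL, n_meshes = 0L,
                mesh_areas_px2 = numeric(0),
                expected_cell_area_nm2 = NA_real_, cell_labels = NULL)
  if (config$archetype %in% c("class_A_large_mesh", "class_B_small_mesh")) {
    tess <- make_tessellation(n, n, config)
    centerline <- tess$boundary
    interior <- setdiff(seq_len(nrow(tess$seeds)),
                        unique(c(tess$labels[1, ], tess$labels[nrow(tess$labels), ],
                                 tess$labels[, 1], tess$labels[, ncol(tess$labels)])))
    areas <- tabulate(tess$labels, nbins = nrow(tess$seeds))[interior]
    truth$cell_labels <- tess$labels
    truth$n_meshes <- length(interior)
    truth$mesh_areas_px2 <- areas
    truth$expected_cell_area_nm2 <- tess$expected_cell_area_nm2
  } else if (config$archetype == "class_C_dense_parallel") {
    centerline <- make_parallel_strands(n, config)
  } else if (config$archetype == "punctae") {
    centerline <- matrix(FALSE, n, n)
    npts <- max(1L, round(n * n / 250))
    centerline[cbind(sample.int(n, npts, TRUE), sample.int(n, npts, TRUE))] <- TRUE
  } else if (config$archetype == "clusters") {
    sigma_nm <- sqrt(config$strand_sigma_nm^2 + config$psf_sigma_nm^2)
    xs <- matrix(rep(0:(n - 1), each = n), n, n)
    ys <- matrix(rep(0:(n - 1), n), n, n)
    signal <- matrix(0, n, n)
    for (b in seq_len(10)) {
      cx <- stats::runif(1, 0, n - 1); cy <- stats::runif(1, 0, n - 1)
      s_px <- stats::runif(1, 80, 200) / config$pixel_size_nm
      signal <- signal +
        exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s_px^2))
    }
    signal <- pmin(signal, 1)
    img <- pixel_image(apply_noise(signal, config), config$pixel_size_nm,
                       config$archetype)
    return(list(image = img, truth = truth, config = config))
  } else {  # uniform
    signal <- matrix(0.5, n, n)
    img <- pixel_image(apply_noise(signal, config), config$pixel_size_nm,
                       config$archetype)
    return(list(image = img, truth = truth, config = config))
  }
  signal <- render_tubes(centerline, config)
  truth$centerline <- centerline
  truth$mask <- signal >= 0.5
  img <- pixel_image(apply_noise(signal, config), config$pixel_size_nm,
                     config$archetype)
  list(image = img, truth = truth, config = config)
}

#' Generate a two-channel co-expression image pair with known pattern
#'
#' Emulates the five nanoscale co-organization patterns of two co-expressed
#' claudins. `intermix`, `integrate`, and `induction` render identical
#' strand geometry into both channels with independent noise (the
#' distinction between the three is biological, not geometric);
#' `segregate` partitions every strand (tessellation edge) into alternating
#' single-channel segments of `segment_length_nm`; `exclude` builds two
#' spatially disjoint meshworks in opposite halves of the field.
#'
#' @param config a [synth_config()] (a tessellation archetype for
#'   `segregate`; any meshwork archetype otherwise).
#' @param mode one of `"intermix"`, `"integrate"`, `"induction"`,
#'   `"segregate"`, `"exclude"`.
#' @param segment_length_nm alternating segment length for `segregate`;
#'   must exceed the rendered strand FWHM.
#' @return A list with `ch1`, `ch2` (`pixel_image`s) and `truth` (mode plus
#'   per-channel centerline and half-maximum masks).
#' @export
make_two_channel <- function(config, mode = c("intermix", "integrate",
                                              "induction", "segregate",
                                              "exclude"),
                             segment_length_nm = 500) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  withr::with_seed(config$seed, {
    n <- config$image_size_px
    fwhm_nm <- 2.355 * sqrt(config$strand_sigma_nm^2 + config$psf_sigma_nm^2)
    if (mode %in% c("intermix", "integrate", "induction")) {
      mw <- make_meshwork_impl(config)
      cl <- mw$truth$centerline
      if (is.null(cl)) stop("mode requires a strand-forming archetype")
      cl1 <- cl; cl2 <- cl
    } else if (mode == "segregate") {
      if (segment_length_nm < fwhm_nm) {
        stop("segment_length_nm below the strand FWHM cannot be resolved")
      }
      tess <- make_tessellation(n, n, config)
      part <- partition_edges(tess, config, segment_length_nm)
      cl1 <- part$ch1; cl2 <- part$ch2
    } else {  # exclude
      gap <- 6L
      half <- (n - gap) %/% 2L
      sub <- config; sub$image_size_px <- half
      t1 <- make_tessellation(half, n, sub)
      t2 <- make_tessellation(half, n, sub)
      cl1 <- matrix(FALSE, n, n); cl2 <- matrix(FALSE, n, n)
      cl1[, seq_len(half)] <- t1$boundary
      cl2[, n - half + seq_len(half)] <- t2$boundary
    }
    s1 <- render_tubes(cl1, config)
    s2 <- render_tubes(cl2, config)
    ch1 <- pixel_image(apply_noise(s1, config), config$pixel_size_nm, "ch1")
    ch2 <- pixel_image(apply_noise(s2, config), config$pixel_size_nm, "ch2")
    list(ch1 = ch1, ch2 = ch2,
         truth = list(mode = mode, segment_length_nm = segment_length_nm,
                      centerline1 = cl1, centerline2 = cl2,
                      mask1 = s1 >= 0.5, mask2 = s2 >= 0.5))
  })
}

# split tessellation boundary pixels into alternating per-edge segments.
# Each boundary pixel lies on the edge between two Voronoi cells; pixels of
# one edge are ordered along the edge direction and assigned to channels in
# alternating runs of segment_length_nm.
partition_edges <- function(tess, config, segment_length_nm) {
  lab <- tess$labels
  h <- nrow(lab); w <- ncol(lab)
  ij <- which(tess$boundary, arr.ind = TRUE)
  key <- character(nrow(ij))
  for (r in seq_len(nrow(ij))) {
    y <- ij[r, 1]; x <- ij[r, 2]
    own <- lab[y, x]
    other <- own
    for (o in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w && lab[yy, xx] != own) {
        other <- lab[yy, xx]; break
      }
    }
    key[r] <- paste(min(own, other), max(own, other), sep = "-")
  }
  ch <- integer(nrow(ij))
  for (k in unique(key)) {
    rows <- which(key == k)
    ab <- as.integer(strsplit(k, "-")[[1]])
    if (ab[1] == ab[2]) {  # orphan pixel: random channel
      ch[rows] <- sample(1:2, length(rows), TRUE)
      next
    }
    dvec <- c(tess$seeds$x[ab[2]] - tess$seeds$x[ab[1]],
              tess$seeds$y[ab[2]] - tess$seeds$y[ab[1]])
    edge_dir <- c(-dvec[2], dvec[1]) / sqrt(sum(dvec^2))
    t_pos <- (ij[rows, 2] - 1) * edge_dir[1] + (ij[rows, 1] - 1) * edge_dir[2]
    t_nm <- (t_pos - min(t_pos)) * config$pixel_size_nm
    seg <- floor(t_nm / segment_length_nm + stats::runif(1))
    ch[rows] <- 1L + (seg + sample(0:1, 1)) %% 2L
  }
  ch1 <- matrix(FALSE, h, w); ch2 <- matrix(FALSE, h, w)
  ch1[ij[ch == 1L, , drop = FALSE]] <- TRUE
  ch2[ij[ch == 2L, , drop = FALSE]] <- TRUE
  list(ch1 = ch1, ch2 = ch2)
}

#' Generate a noisy Gaussian line profile
#'
#' Forward model feeding the strand-width (FWHM) fitting stage: a Gaussian
#' bump on a constant offset, sampled on an even grid, with i.i.d. Gaussian
#' noise.
#'
#' @param sigma_nm true Gaussian sigma (> 0).
#' @param amplitude peak height above offset.
#' @param offset baseline intensity.
#' @param noise_sd additive noise SD.
#' @param n_points number of samples (>= 7).
#' @param spacing_nm sample spacing (> 0).
#' @param center_nm profile center; defaults to the grid midpoint.
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return A `line_profile` (positions in nm, intensities).
#' @export
make_line_profile <- function(sigma_nm, amplitude = 100, offset = 10,
                              noise_sd = 0, n_points = 16, spacing_nm = 20,
                              center_nm = NULL, seed = NULL) {
  if (sigma_nm <= 0 || spacing_nm <= 0) stop("sigma and spacing must be > 0")
  if (n_points < 7) stop("need at least 7 samples")
  gen <- function() {
    x <- (seq_len(n_points) - 1) * spacing_nm
    if (is.null(center_nm)) center_nm <- max(x) / 2
    y <- offset + amplitude * exp(-(x - center_nm)^2 / (2 * sigma_nm^2))
    if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
    line_profile(x, y)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic dilution-potential dataset
#'
#' Forward-models an Ussing-chamber dilution-potential experiment: each
#' replicate's potential is the GHK prediction for the true permeability
#' ratio plus Gaussian measurement noise. Solution compositions default to
#' NaCl Ringer (140 mM Na+, 128.8 mM Cl-) basolaterally and the
#' mannitol-substituted apical solution (80.5 mM Na+, 69.3 mM Cl-).
#'
#' @param r_true true PNa/PCl ratio (> 0).
#' @param TER_true true trans-epithelial resistance (ohm cm^2, > 0).
#' @param n number of replicates.
#' @param noise_sd_mV potential measurement noise SD.
#' @param temperature_K bath temperature.
#' @param c_na_api,c_cl_api,c_na_baso,c_cl_baso concentrations in mM.
#' @param seed RNG seed.
#' @return List of `dilution_experiment` objects.
#' @export
make_dilution_dataset <- function(r_true, TER_true, n = 200,
                                  noise_sd_mV = 0.5, temperature_K = 310.15,
                                  c_na_api = 80.5, c_cl_api = 69.3,
                                  c_na_baso = 140, c_cl_baso = 128.8,
                                  seed = 1L) {
  if (r_true <= 0) stop("r_true must be > 0")
  if (TER_true <= 0) stop("TER_true must be > 0")
  if (any(c(c_na_api, c_cl_api, c_na_baso, c_cl_baso) <= 0)) {
    stop("concentrations must be > 0")
  }
  base <- dilution_experiment(c_na_api, c_cl_api, c_na_baso, c_cl_baso,
                              v_dil_mv = 0, ter_ohm_cm2 = TER_true,
                              temperature_K = temperature_K)
  v0 <- dilution_from_ratio(r_true, base)
  withr::with_seed(seed, {
    vs <- v0 + stats::rnorm(n, 0, noise_sd_mV)
    lapply(vs, function(v) {
      dilution_experiment(c_na_api, c_cl_api, c_na_baso, c_cl_baso,
                          v_dil_mv = v, ter_ohm_cm2 = TER_true,
                          temperature_K = temperature_K)
    })
  })
}

#' Generate a synthetic emission spectrum with known FRET content
#'
#' Forward model for the spectral FRET stage: the measured lambda-stack is
#' `c_donor * S_D + (fret_fraction * c_donor + direct_acceptor) * S_A`
#' plus optional noise, where `direct_acceptor` is the directly excited
#' acceptor (crosstalk) component. The ground-truth FRET ratio is the
#' sensitized acceptor emission at the acceptor readout wavelength divided
#' by the donor emission at the donor readout wavelength.
#'
#' @param c_donor donor abundance (> 0).
#' @param fret_fraction sensitized-emission coefficient per unit donor.
#' @param direct_acceptor directly excited acceptor coefficient.
#' @param noise_sd additive spectral noise SD.
#' @param preset instrument preset, `"HEK"` (readouts 532/468 nm) or
#'   `"COS7"` (530/478 nm).
#' @param seed RNG seed (`NULL` = current state).
#' @return A list with `stack` (a `spectral_stack`), `true_ratio`, and
#'   `direct_acceptor`.
#' @export
make_fret_spectrum <- function(c_donor, fret_fraction, direct_acceptor = 0,
                               noise_sd = 0, preset = c("HEK", "COS7"),
                               seed = NULL) {
  preset <- match.arg(preset)
  if (c_donor <= 0) stop("c_donor must be > 0")
  ref <- fret_reference_spectra(preset)
  c_acc <- fret_fraction * c_donor + direct_acceptor
  m <- c_donor * ref$s_donor + c_acc * ref$s_acceptor
  gen <- function() {
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    stack <- spectral_stack(ref$wavelength_nm, m, ref$s_donor,
                            ref$s_acceptor, ref$lambda_donor_nm,
                            ref$lambda_acceptor_nm)
    i_d <- which.min(abs(ref$wavelength_nm - ref$lambda_donor_nm))
    i_a <- which.min(abs(ref$wavelength_nm - ref$lambda_acceptor_nm))
    true_ratio <- (fret_fraction * c_donor * ref$s_acceptor[i_a]) /
      (c_donor * ref$s_donor[i_d])
    list(stack = stack, true_ratio = true_ratio,
         direct_acceptor = direct_acceptor)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
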