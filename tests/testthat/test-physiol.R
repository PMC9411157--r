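test_that("GHK forward model reproduces its closed-form anchors", {
  e <- dilution_experiment()
  # symmetric dilution deltas: r = 1 gives exactly zero potential
  expect_equal(dilution_from_ratio(1, e), 0, tolerance = 1e-12)
  rt_f <- 8.314462618 * 310.15 / 96485.332 * 1000
  expect_equal(dilution_from_ratio(1e9, e), rt_f * log(140 / 80.5),
               tolerance = 1e-6)
  expect_equal(dilution_from_ratio(1e-9, e), rt_f * log(69.3 / 128.8),
               tolerance = 1e-6)
  lims <- limiting_potentials(e)
  expect_equal(unname(lims["v_max_mv"]), 14.79, tolerance = 1e-2)
  expect_equal(unname(lims["v_min_mv"]), -16.57, tolerance = 1e-2)
  expect_error(dilution_from_ratio(0, e), "> 0")
})

test_that("GHK inversion is exact and rejects out-of-range potentials", {
  e <- dilution_experiment()
  expect_equal(ratio_from_dilution(e), 1, tolerance = 1e-12)
  for (r in c(0.01, 0.25, 1, 4, 15, 100)) {
    v <- dilution_from_ratio(r, e)
    e2 <- dilution_experiment(v_dil_mv = v)
    expect_equal(ratio_from_dilution(e2), r, tolerance = 1e-9)
  }
  expect_error(ratio_from_dilution(dilution_experiment(v_dil_mv = 20)),
               "admissible")
  expect_error(ratio_from_dilution(dilution_experiment(v_dil_mv = -18)),
               "admissible")
})

test_that("dilution potential increases monotonically with the ratio", {
  e <- dilution_experiment()
  rs <- 10^seq(-2, 2, length.out = 41)
  vs <- vapply(rs, dilution_from_ratio, numeric(1), exp = e)
  expect_true(all(diff(vs) > 0))
})

test_that("ratio estimation recovers truth from noisy replicates", {
  for (r in c(0.25, 1, 4, 15)) {
    ds <- make_dilution_dataset(r, 100, n = 200, noise_sd_mV = 0.5,
                                seed = 17)
    est <- estimate_ratio(ds)
    expect_lt(abs(est - r) / r, 0.05)
  }
})

test_that("absolute permeabilities follow the conductance partition", {
  p <- absolute_permeabilities(1, 100)
  expected <- (1 / 100) * 8.314462618 * 310.15 /
    (96485.332^2 * (140e-6 + 128.8e-6)) * 1e6
  expect_equal(p$p_na, expected, tolerance = 1e-9)
  expect_equal(p$p_cl, expected, tolerance = 1e-9)

  for (r in c(0.2, 1, 7)) {
    pr <- absolute_permeabilities(r, 250)
    expect_equal(pr$p_na / pr$p_cl, r, tolerance = 1e-12)
  }
  # permeabilities scale with conductance, vanish for a perfect barrier
  p1 <- absolute_permeabilities(2, 100)
  p2 <- absolute_permeabilities(2, 50)
  expect_equal(p2$p_na, 2 * p1$p_na, tolerance = 1e-12)
  expect_lt(absolute_permeabilities(2, 1e12)$p_na, 1e-8)
  expect_error(absolute_permeabilities(2, 0), "> 0")
})

test_that("apparent permeability converts a flux slope exactly", {
  t_min <- c(0, 5, 10, 15)
  expect_equal(papp_flux(t_min, rep(0, 4)), 0)
  k <- 0.37  # uM / min
  expect_equal(papp_flux(t_min, 2 + k * t_min, volume_ml = 5,
                         area_cm2 = 0.6, c0_um = 100),
               (k / 60) * 5 / (0.6 * 100) * 1e6, tolerance = 1e-12)
  expect_warning(papp_flux(t_min, c(3, 2, 1, 0)), "negative")
  expect_error(papp_flux(0, 1), "at least 2")
  # unbiasedness over repeated noisy simulations
  true_p <- (k / 60) * 5 / (0.6 * 100) * 1e6
  ests <- withr::with_seed(21, vapply(1:1000, function(i) {
    papp_flux(t_min, k * t_min + stats::rnorm(4, 0, 0.2))
  }, numeric(1)))
  sem <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_p), 3 * sem)
})

test_that("spectral unmixing recovers mixing coefficients", {
  ref <- fret_reference_spectra("HEK")
  pure <- spectral_stack(ref$wavelength_nm, ref$s_donor, ref$s_donor,
                         ref$s_acceptor, 468, 532)
  um <- unmix_spectrum(pure)
  expect_equal(um$c_donor, 1, tolerance = 1e-10)
  expect_equal(um$c_acceptor, 0, tolerance = 1e-10)
  expect_lt(um$residual, 1e-10)

  mixed <- spectral_stack(ref$wavelength_nm,
                          0.3 * ref$s_donor + 0.7 * ref$s_acceptor,
                          ref$s_donor, ref$s_acceptor, 468, 532)
  um2 <- unmix_spectrum(mixed)
  expect_equal(um2$c_donor, 0.3, tolerance = 1e-10)
  expect_equal(um2$c_acceptor, 0.7, tolerance = 1e-10)

  expect_error(spectral_stack(ref$wavelength_nm, ref$s_donor, ref$s_donor,
                              ref$s_donor * 2, 468, 532), "unit-peak")
  expect_error(unmix_spectrum(
    spectral_stack(ref$wavelength_nm, ref$s_donor, ref$s_donor,
                   ref$s_donor, 468, 532)), "collinear")
})

test_that("FRET ratio round-trips the forward simulator", {
  fs <- make_fret_spectrum(c_donor = 2, fret_fraction = 0.4,
                           direct_acceptor = 0.15)
  expect_equal(fret_ratio(fs$stack, fs$direct_acceptor), fs$true_ratio,
               tolerance = 1e-9)
  # acceptor-free spectrum: ratio 0
  fs0 <- make_fret_spectrum(c_donor = 1.5, fret_fraction = 0)
  expect_equal(fret_ratio(fs0$stack), 0, tolerance = 1e-9)
  # both instrument presets round-trip
  fsc <- make_fret_spectrum(1, 0.25, preset = "COS7")
  expect_equal(fret_ratio(fsc$stack), fsc$true_ratio, tolerance = 1e-9)
  # acceptor-only spectrum has no donor emission
  ref <- fret_reference_spectra("HEK")
  acc <- spectral_stack(ref$wavelength_nm, ref$s_acceptor, ref$s_donor,
                        ref$s_acceptor, 468, 532)
  expect_error(fret_ratio(acc), "donor")
})
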