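# Physical constants (SI)
.R_GAS <- 8.314462618   # J mol^-1 K^-1
.F_FARADAY <- 96485.332 # C mol^-1

#' Ussing-chamber dilution-potential experiment
#'
#' One transwell measurement: the NaCl concentrations on both sides after
#' the apical dilution step, the recorded dilution potential (apical minus
#' basolateral), and the trans-epithelial resistance. Standard conditions
#' are NaCl Ringer (140 mM Na+, 128.8 mM Cl-) basolaterally and the
#' mannitol-substituted apical solution (80.5 mM Na+, 69.3 mM Cl-) at
#' 37 degrees C.
#'
#' @param c_na_api,c_cl_api apical Na+/Cl- concentrations (mM, > 0).
#' @param c_na_baso,c_cl_baso basolateral Na+/Cl- concentrations (mM, > 0).
#' @param v_dil_mv dilution potential, apical minus basolateral (mV).
#' @param ter_ohm_cm2 trans-epithelial resistance (ohm cm^2, > 0).
#' @param temperature_K bath temperature in (270, 320) K.
#' @return A list of class `dilution_experiment`.
#' @export
dilution_experiment <- function(c_na_api = 80.5, c_cl_api = 69.3,
                                c_na_baso = 140, c_cl_baso = 128.8,
                                v_dil_mv = 0, ter_ohm_cm2 = 100,
                                temperature_K = 310.15) {
  if (any(c(c_na_api, c_cl_api, c_na_baso, c_cl_baso) <= 0)) {
    stop("concentrations must be > 0")
  }
  if (ter_ohm_cm2 <= 0) stop("TER must be > 0")
  if (temperature_K <= 270 || temperature_K >= 320) {
    stop("temperature must lie in (270, 320) K")
  }
  structure(list(c_na_api = c_na_api, c_cl_api = c_cl_api,
                 c_na_baso = c_na_baso, c_cl_baso = c_cl_baso,
                 v_dil_mv = v_dil_mv, ter_ohm_cm2 = ter_ohm_cm2,
                 temperature_K = temperature_K),
            class = "dilution_experiment")
}

#' GHK forward model: dilution potential from a permeability ratio
#'
#' Goldman-Hodgkin-Katz prediction of the dilution potential for a
#' NaCl-selective barrier:
#' `V = (RT/F) ln[(r c_Na_baso + c_Cl_api) / (r c_Na_api + c_Cl_baso)]`
#' with `r = PNa/PCl`. Under the apical-minus-basolateral sign convention
#' an apically diluted bath gives V > 0 for a cation-selective barrier
#' (r > 1) and V = 0 for r = 1 when both dilution deltas are equal (as
#' they are for the standard solution pair).
#'
#' @param r PNa/PCl permeability ratio (> 0).
#' @param exp a `dilution_experiment` supplying solutions and temperature.
#' @return Dilution potential in mV.
#' @export
dilution_from_ratio <- function(r, exp = dilution_experiment()) {
  if (any(r <= 0)) stop("ratio must be > 0")
  rt_f <- .R_GAS * exp$temperature_K / .F_FARADAY * 1000  # mV
  rt_f * log((r * exp$c_na_baso + exp$c_cl_api) /
             (r * exp$c_na_api + exp$c_cl_baso))
}

#' GHK inverse: permeability ratio from a measured dilution potential
#'
#' Inverts the GHK dilution-potential relation:
#' `r = (e^x c_Cl_baso - c_Cl_api) / (c_Na_baso - e^x c_Na_api)` with
#' `x = V F / (RT)`. The potential must lie strictly between the two
#' limiting potentials (the r -> 0 and r -> Inf limits), otherwise no
#' positive ratio exists.
#'
#' @param exp a `dilution_experiment` (uses its `v_dil_mv`).
#' @return The PNa/PCl ratio (> 0).
#' @export
ratio_from_dilution <- function(exp) {
  rt_f <- .R_GAS * exp$temperature_K / .F_FARADAY * 1000  # mV
  ex <- exp(exp$v_dil_mv / rt_f)
  num <- ex * exp$c_cl_baso - exp$c_cl_api
  den <- exp$c_na_baso - ex * exp$c_na_api
  if (num <= 0 || den <= 0) {
    stop("potential outside the admissible range of the GHK model")
  }
  num / den
}

#' Limiting dilution potentials of the GHK model
#'
#' The potentials approached as the barrier becomes perfectly cation-
#' (r -> Inf) or anion-selective (r -> 0):
#' `(RT/F) ln(c_Na_baso / c_Na_api)` and
#' `(RT/F) ln(c_Cl_api / c_Cl_baso)`.
#'
#' @param exp a `dilution_experiment`.
#' @return Named numeric vector `c(v_max_mv, v_min_mv)`.
#' @export
limiting_potentials <- function(exp = dilution_experiment()) {
  rt_f <- .R_GAS * exp$temperature_K / .F_FARADAY * 1000
  c(v_max_mv = rt_f * log(exp$c_na_baso / exp$c_na_api),
    v_min_mv = rt_f * log(exp$c_cl_api / exp$c_cl_baso))
}

#' Estimate a permeability ratio from replicate dilution potentials
#'
#' Least-squares fit of the GHK forward model to a set of measured
#' potentials: minimizes `sum (V_i - V(r))^2` over `log r`, which stays
#' robust when individual noisy potentials fall outside the admissible
#' inversion range.
#'
#' @param experiments list of `dilution_experiment` objects sharing the
#'   same solutions and temperature.
#' @return Estimated PNa/PCl ratio.
#' @export
estimate_ratio <- function(experiments) {
  stopifnot(length(experiments) >= 1)
  vs <- vapply(experiments, function(e) e$v_dil_mv, numeric(1))
  e0 <- experiments[[1]]
  obj <- function(logr) sum((vs - dilution_from_ratio(exp(logr), e0))^2)
  opt <- stats::optimize(obj, interval = log(c(1e-4, 1e4)))
  exp(opt$minimum)
}

#' Absolute Na+ and Cl- permeabilities from ratio and TER
#'
#' Kimizuka-Koketsu partition of the measured conductance into the two
#' ionic permeabilities: with `G = 1/TER`,
#' `P_Cl = G R T / (F^2 (r c_Na + c_Cl))` and `P_Na = r P_Cl`, where
#' `c_Na`, `c_Cl` are the symmetric Ringer concentrations converted to
#' mol/cm^3. Concentrations (not activities) are used; halving the TER
#' doubles both permeabilities.
#'
#' @param r PNa/PCl ratio (> 0).
#' @param ter_ohm_cm2 trans-epithelial resistance (> 0); a cell-free blank
#'   resistance can be subtracted via `blank_ter_ohm_cm2`.
#' @param c_na_mm,c_cl_mm symmetric bath concentrations in mM.
#' @param temperature_K bath temperature.
#' @param blank_ter_ohm_cm2 blank (filter-only) resistance to subtract.
#' @return A list of class `permeability_result`: `ratio`, `p_na`, `p_cl`
#'   in 1e-6 cm/s.
#' @export
absolute_permeabilities <- function(r, ter_ohm_cm2, c_na_mm = 140,
                                    c_cl_mm = 128.8,
                                    temperature_K = 310.15,
                                    blank_ter_ohm_cm2 = 0) {
  if (r <= 0) stop("ratio must be > 0")
  ter <- ter_ohm_cm2 - blank_ter_ohm_cm2
  if (ter <= 0) stop("TER must be > 0 (after blank subtraction)")
  g <- 1 / ter                           # S / cm^2
  c_na <- c_na_mm * 1e-6                 # mol / cm^3
  c_cl <- c_cl_mm * 1e-6
  p_cl <- g * .R_GAS * temperature_K /
    (.F_FARADAY^2 * (r * c_na + c_cl))   # cm / s
  structure(list(ratio = r, p_na = r * p_cl * 1e6, p_cl = p_cl * 1e6),
            class = "permeability_result")
}

#' Apparent permeability from a tracer flux time course
#'
#' Ordinary-least-squares slope of the basolateral tracer concentration
#' over time, converted to an apparent permeability
#' `P_app = (dC/dt V) / (A C0)`. Units: time in minutes (converted to
#' seconds), volume in ml (= cm^3), area in cm^2; the tracer concentration
#' unit cancels. A negative fitted slope is reported with a warning, not
#' clamped.
#'
#' @param times_min sampling times in minutes (strictly increasing, >= 2).
#' @param c_baso_um basolateral tracer concentrations (uM) at those times.
#' @param volume_ml basolateral bath volume (ml).
#' @param area_cm2 filter area (cm^2); default 0.6, the standard transwell.
#' @param c0_um apical tracer concentration (uM); default 100.
#' @return Apparent permeability in 1e-6 cm/s.
#' @export
papp_flux <- function(times_min, c_baso_um, volume_ml = 5, area_cm2 = 0.6,
                      c0_um = 100) {
  if (length(times_min) < 2) stop("need at least 2 samples")
  if (any(diff(times_min) <= 0)) stop("times must strictly increase")
  if (length(times_min) != length(c_baso_um)) {
    stop("times and concentrations differ in length")
  }
  if (c0_um <= 0 || area_cm2 <= 0 || volume_ml <= 0) {
    stop("C0, area and volume must be > 0")
  }
  slope_per_min <- unname(stats::coef(stats::lm(c_baso_um ~ times_min))[2])
  if (slope_per_min < 0) warning("negative fitted flux slope")
  slope_per_s <- slope_per_min / 60
  p_app <- slope_per_s * volume_ml / (area_cm2 * c0_um)  # cm / s
  p_app * 1e6
}

#' Emission lambda-stack with reference spectra
#'
#' Container for spectral FRET analysis: the measured ROI spectrum on a
#' common wavelength grid, the donor and acceptor reference emission
#' spectra (each normalized to unit peak), and the two readout
#' wavelengths.
#'
#' @param wavelength_nm common wavelength grid (strictly increasing).
#' @param measured measured spectrum M(lambda).
#' @param s_donor,s_acceptor nonnegative reference spectra, unit peak.
#' @param lambda_donor_nm,lambda_acceptor_nm readout wavelengths.
#' @return A list of class `spectral_stack`.
#' @export
spectral_stack <- function(wavelength_nm, measured, s_donor, s_acceptor,
                           lambda_donor_nm, lambda_acceptor_nm) {
  n <- length(wavelength_nm)
  if (length(measured) != n || length(s_donor) != n ||
      length(s_acceptor) != n) {
    stop("spectra must share the wavelength grid")
  }
  if (any(diff(wavelength_nm) <= 0)) stop("wavelengths must increase")
  if (any(s_donor < 0) || any(s_acceptor < 0)) {
    stop("reference spectra must be nonnegative")
  }
  for (s in list(s_donor, s_acceptor)) {
    if (abs(max(s) - 1) > 1e-9) stop("references must be unit-peak")
  }
  structure(list(wavelength_nm = wavelength_nm, measured = measured,
                 s_donor = s_donor, s_acceptor = s_acceptor,
                 lambda_donor_nm = lambda_donor_nm,
                 lambda_acceptor_nm = lambda_acceptor_nm),
            class = "spectral_stack")
}

#' Instrument presets for spectral FRET
#'
#' Gaussian emission models for the Turquoise2 donor and YFP acceptor on
#' the two instrument configurations used for lateral-contact FRET:
#' `"HEK"` (grid 436-650 nm, readouts 532/468 nm) and `"COS7"` (grid
#' 438-639 nm, readouts 530/478 nm). The spectra are synthetic stand-ins
#' for instrument reference spectra, normalized to unit peak.
#'
#' @param preset `"HEK"` or `"COS7"`.
#' @return List with `wavelength_nm`, `s_donor`, `s_acceptor`,
#'   `lambda_donor_nm`, `lambda_acceptor_nm`.
#' @export
fret_reference_spectra <- function(preset = c("HEK", "COS7")) {
  preset <- match.arg(preset)
  if (preset == "HEK") {
    wl <- seq(436, 650, by = 2)
    l_d <- 468; l_a <- 532
  } else {
    wl <- seq(438, 639, by = 2)
    l_d <- 478; l_a <- 530
  }
  norm_peak <- function(s) s / max(s)
  s_d <- norm_peak(exp(-(wl - 474)^2 / (2 * 30^2)) +
                     0.35 * exp(-(wl - 505)^2 / (2 * 40^2)))
  s_a <- norm_peak(exp(-(wl - 527)^2 / (2 * 22^2)) +
                     0.3 * exp(-(wl - 560)^2 / (2 * 35^2)))
  list(wavelength_nm = wl, s_donor = s_d, s_acceptor = s_a,
       lambda_donor_nm = l_d, lambda_acceptor_nm = l_a)
}

#' Linear spectral unmixing of a measured lambda-stack
#'
#' Least-squares decomposition `M ~ c_D S_D + c_A S_A`. If a coefficient
#' comes out negative it is clamped to 0 and the other refit
#' (nonnegativity by clamping with refit).
#'
#' @param stack a `spectral_stack`.
#' @return List with `c_donor`, `c_acceptor`, `residual` (L2 norm of the
#'   unexplained spectrum).
#' @export
unmix_spectrum <- function(stack) {
  stopifnot(inherits(stack, "spectral_stack"))
  A <- cbind(stack$s_donor, stack$s_acceptor)
  if (qr(A)$rank < 2) stop("collinear reference spectra")
  cf <- qr.solve(A, stack$measured)
  if (any(cf < 0)) {
    keep <- which.max(cf)
    cf_pos <- sum(A[, keep] * stack$measured) / sum(A[, keep]^2)
    cf <- c(0, 0)
    cf[keep] <- max(cf_pos, 0)
  }
  res <- stack$measured - A %*% cf
  list(c_donor = cf[1], c_acceptor = cf[2],
       residual = sqrt(sum(res^2)))
}

#' Spectral FRET ratio
#'
#' Acceptor-to-donor emission ratio after crosstalk correction: the
#' measured spectrum is unmixed into donor and acceptor components, the
#' directly excited acceptor (crosstalk) coefficient -- obtained from an
#' acceptor-only control -- is subtracted from the acceptor coefficient,
#' and the ratio is the corrected acceptor emission at the acceptor
#' readout wavelength divided by the donor emission at the donor readout
#' wavelength.
#'
#' @param stack a `spectral_stack`.
#' @param direct_acceptor_coef crosstalk (directly excited acceptor)
#'   coefficient to subtract; default 0.
#' @return FRET ratio (dimensionless, >= 0 for a physical spectrum).
#' @export
fret_ratio <- function(stack, direct_acceptor_coef = 0) {
  um <- unmix_spectrum(stack)
  i_d <- which.min(abs(stack$wavelength_nm - stack$lambda_donor_nm))
  i_a <- which.min(abs(stack$wavelength_nm - stack$lambda_acceptor_nm))
  donor_em <- um$c_donor * stack$s_donor[i_d]
  if (donor_em <= 0) stop("zero or negative donor emission")
  acc_em <- (um$c_acceptor - direct_acceptor_coef) * stack$s_acceptor[i_a]
  acc_em / donor_em
}
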