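#' Simulation configuration for a fluorescence titration
#'
#' Defaults reproduce the study design this package targets: 3 uM serum
#' albumin excited at 280 nm, emission band centred at 347 nm, titrated
#' with ligand from 0 to 80 uM in 10 uM steps, at 287/298/307 K.
#'
#' @param seed Integer RNG seed; fully determines the output.
#' @param mechanism `"dynamic"` (collisional, Stern-Volmer) or
#'   `"static_binding"` (ground-truth defined through the double-log
#'   isotherm with ligand depletion).
#' @param true_K_SV Stern-Volmer constant in M^-1 (dynamic mode).
#' @param true_K_a Association constant in M^-1 (static_binding mode).
#' @param true_n Binding stoichiometry (static_binding mode).
#' @param protein_conc Total protein in mol/L (default 3e-6).
#' @param ligand_ladder Ligand concentrations in mol/L, starting at 0
#'   (default 0..80 uM in 10 uM steps).
#' @param temperature Temperature in K (default 298).
#' @param emission_center Emission band centre in nm (default 347).
#' @param emission_sigma Gaussian band width in nm (default 25).
#' @param F0_amplitude Peak intensity of the unquenched band (a.u.).
#' @param excitation_wavelength nm (default 280).
#' @param apply_ife Attenuate the emitted spectra by the ligand's inner
#'   filter effect (and emit matching absorbance spectra).
#' @param ligand_absorptivity_ex,ligand_absorptivity_em Ligand molar
#'   absorptivity (M^-1 cm^-1) at the excitation wavelength and at the
#'   emission centre; defaults 5000 and 500 (strong near-UV absorber,
#'   weak tail under the emission band).
#' @param noise_sigma_rel Gaussian noise s.d. as a fraction of
#'   `F0_amplitude`, applied to signal values only.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       mechanism = c("dynamic", "static_binding"),
                       true_K_SV = 3.62e4,
                       true_K_a = 2.76e4,
                       true_n = 1,
                       protein_conc = 3e-6,
                       ligand_ladder = seq(0, 80e-6, by = 10e-6),
                       temperature = 298,
                       emission_center = 347,
                       emission_sigma = 25,
                       F0_amplitude = 1000,
                       excitation_wavelength = 280,
                       apply_ife = FALSE,
                       ligand_absorptivity_ex = 5000,
                       ligand_absorptivity_em = 500,
                       noise_sigma_rel = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(ligand_ladder[1] == 0, all(diff(ligand_ladder) > 0),
            noise_sigma_rel >= 0, true_K_SV > 0, true_K_a > 0, true_n > 0,
            F0_amplitude > 0, emission_sigma > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Solve F self-consistently from the double-log isotherm
#   log10((F0-F)/F) = n log10(Ka) + n log10(LT - (F0-F) PT / F0)
# by damped fixed-point iteration to 1e-12 relative.
solve_static_F <- function(F0, LT, PT, Ka, n, tol = 1e-12, max_iter = 1e4) {
  if (LT <= 0) return(F0)
  f <- F0 / (1 + (Ka * LT)^n)
  for (it in seq_len(max_iter)) {
    free <- LT - (F0 - f) * PT / F0
    if (free <= 0) free <- .Machine$double.eps * LT
    ratio <- (Ka * free)^n
    f_new <- F0 / (1 + ratio)
    if (abs(f_new - f) <= tol * F0) return(f_new)
    f <- 0.5 * f + 0.5 * f_new
  }
  stop("generation error: fixed-point iteration did not converge",
       call. = FALSE)
}

# Ligand absorbance spectrum model used by the simulator: a near-UV band
# anchored at the excitation wavelength plus a weak broad tail anchored at
# the emission centre, both scaled by the ligand concentration.
ligand_absorbance_curve <- function(wl, conc, config) {
  band_ex <- exp(-(wl - config$excitation_wavelength)^2 / (2 * 15^2))
  band_em <- exp(-(wl - config$emission_center)^2 / (2 * 40^2))
  conc * (config$ligand_absorptivity_ex * band_ex +
            config$ligand_absorptivity_em * band_em)
}

#' Simulate a fluorescence quenching titration with known ground truth
#'
#' Emission spectra are Gaussian bands whose peak intensity follows the
#' configured quenching law: `dynamic` mode uses the Stern-Volmer relation
#' \eqn{F = F_0 / (1 + K_{SV} [Q])}; `static_binding` mode solves the
#' double-log binding isotherm (with free-ligand depletion) self-consistently
#' to 1e-12, so that [double_log_fit()] is exactly consistent with the
#' generator. If `apply_ife` is set, each spectrum is attenuated by
#' \eqn{10^{-(A_{ex}+A_{em})/2}} computed from the emitted ligand absorbance
#' spectra — so [correct_titration()] inverts the effect exactly. Gaussian
#' noise is added last; the seed fully determines the output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `series` (a [titration_series]) and `truth`
#'   (the generating parameters, including the noise-free peak
#'   intensities).
#' @export
simulate_titration <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  wl <- seq(300, 450, by = 1)
  abs_wl <- seq(260, 470, by = 1)
  Q <- config$ligand_ladder
  F0 <- config$F0_amplitude
  peak_F <- switch(config$mechanism,
    dynamic = F0 / (1 + config$true_K_SV * Q),
    static_binding = vapply(Q, function(q) {
      solve_static_F(F0, q, config$protein_conc, config$true_K_a,
                     config$true_n)
    }, numeric(1)))
  band <- exp(-(wl - config$emission_center)^2 / (2 * config$emission_sigma^2))
  emission <- vector("list", length(Q))
  absorbance <- if (config$apply_ife) vector("list", length(Q)) else NULL
  for (i in seq_along(Q)) {
    sig <- peak_F[i] * band
    if (config$apply_ife) {
      a_curve <- ligand_absorbance_curve(abs_wl, Q[i], config)
      ab_sp <- spectrum(abs_wl, a_curve, sprintf("%g", Q[i] * 1e6))
      a_ex <- absorbance_at(ab_sp, config$excitation_wavelength)
      a_em <- absorbance_at(ab_sp, config$emission_center)
      sig <- sig * 10^(-(a_ex + a_em) / 2)
      absorbance[[i]] <- ab_sp
    }
    if (config$noise_sigma_rel > 0) {
      sig <- sig + stats::rnorm(length(sig),
                                sd = config$noise_sigma_rel * F0)
    }
    emission[[i]] <- spectrum(wl, sig, sprintf("%g", Q[i] * 1e6))
  }
  series <- titration_series(
    temperature = config$temperature,
    protein_conc = config$protein_conc,
    ligand_concs = Q,
    emission_spectra = emission,
    excitation_wavelength = config$excitation_wavelength,
    absorbance_spectra = absorbance)
  list(series = series,
       truth = list(mechanism = config$mechanism,
                    K_SV = config$true_K_SV, K_a = config$true_K_a,
                    n = config$true_n, F0 = F0, peak_F = peak_F,
                    seed = config$seed))
}

#' Van't Hoff-consistent association constants
#'
#' Closed form \eqn{K(T) = \exp(-\Delta H/(RT) + \Delta S/R)}; the exact
#' inverse of [vant_hoff_fit()].
#'
#' @param dH Enthalpy change in J/mol.
#' @param dS Entropy change in J/(mol K).
#' @param temps Temperatures in K, all > 0.
#' @return Association constants in M^-1, one per temperature.
#' @export
simulate_vant_hoff <- function(dH, dS, temps) {
  if (any(!is.finite(temps)) || any(temps <= 0)) {
    stop("validation error: temperatures must be positive", call. = FALSE)
  }
  exp(-dH / (R_GAS * temps) + dS / R_GAS)
}

#' Simulate a far-UV CD spectrum with a configured helix fraction
#'
#' Builds a mean-residue-ellipticity curve as a weighted sum of an
#' alpha-helix basis (double minima at 208 and 222 nm, depth -33,000 at
#' 208 nm) and a random-coil basis (-4,000 at 208 nm), then converts back
#' to observed millidegrees through the inverse of
#' [mre_from_ellipticity()]. By construction, running the CD pipeline on
#' the output returns the configured fraction exactly (up to noise).
#'
#' @param helix_fraction Target fraction in \[0, 1\].
#' @param conc Protein concentration in mg/mL (default 0.1995: 3 uM of a
#'   66.5 kDa albumin).
#' @param path_length Path length in cm (default 0.1).
#' @param mrw Mean residue weight in Da (default 110).
#' @param wavelengths Wavelength grid in nm (default 200..250, 1 nm pitch).
#' @param noise_sd_mdeg Gaussian noise s.d. in mdeg (default 0).
#' @param seed Optional RNG seed (used only when noise is on).
#' @return A [spectrum] in mdeg with attribute `mre_truth` (the noise-free
#'   MRE curve).
#' @export
simulate_cd <- function(helix_fraction, conc = 0.1995, path_length = 0.1,
                        mrw = 110, wavelengths = 200:250,
                        noise_sd_mdeg = 0, seed = NULL) {
  if (!is.finite(helix_fraction) || helix_fraction < 0 || helix_fraction > 1) {
    stop("validation error: helix_fraction must be in [0, 1]", call. = FALSE)
  }
  wl <- as.numeric(wavelengths)
  # helix basis: bands at 208 and 222 nm, normalized to -33,000 at 208 nm
  g <- exp(-(wl - 208)^2 / (2 * 6.5^2)) + 0.9 * exp(-(wl - 222)^2 / (2 * 7^2))
  g208 <- exp(0) + 0.9 * exp(-(208 - 222)^2 / (2 * 7^2))
  helix_basis <- HELIX_MRE_208 * g / g208
  # coil basis: shallow band toward 198 nm, normalized to -4,000 at 208 nm
  h <- exp(-(wl - 198)^2 / (2 * 10^2))
  h208 <- exp(-(208 - 198)^2 / (2 * 10^2))
  coil_basis <- COIL_MRE_208 * h / h208
  mre <- helix_fraction * helix_basis + (1 - helix_fraction) * coil_basis
  theta <- mre * 10 * conc * path_length / mrw
  if (noise_sd_mdeg > 0) {
    if (!is.null(seed)) set.seed(seed)
    theta <- theta + stats::rnorm(length(theta), sd = noise_sd_mdeg)
  }
  out <- spectrum(wl, theta, sprintf("helix %.1f%%", 100 * helix_fraction))
  attr(out, "mre_truth") <- mre
  out
}

#' Simulate an excitation-emission matrix
#'
#' A sum of 2-D Gaussian fluorophore peaks plus, optionally, first-order
#' (\eqn{\lambda_{em} = \lambda_{ex}}) and second-order
#' (\eqn{\lambda_{em} = 2\lambda_{ex}}) Rayleigh scattering ridges. Default
#' grids match a 220-350 nm (5 nm pitch) excitation by 220-500 nm
#' (1 nm pitch) emission acquisition.
#'
#' @param peaks Data frame with columns `ex`, `em`, `height` and optional
#'   `sigma_ex`, `sigma_em` (defaults 12 and 18 nm). May have zero rows.
#' @param rayleigh Add scattering ridges (default TRUE).
#' @param ex_grid,em_grid Wavelength grids in nm.
#' @param rayleigh_height Ridge amplitude (first order; second order is
#'   40% of it).
#' @param noise_sd Gaussian noise s.d. (default 0).
#' @param seed Optional RNG seed (used only when noise is on).
#' @return An [eem].
#' @export
simulate_eem <- function(peaks, rayleigh = TRUE,
                         ex_grid = seq(220, 350, by = 5),
                         em_grid = seq(220, 500, by = 1),
                         rayleigh_height = 100, noise_sd = 0, seed = NULL) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) {
    if (is.null(peaks$sigma_ex)) peaks$sigma_ex <- 12
    if (is.null(peaks$sigma_em)) peaks$sigma_em <- 18
    if (any(peaks$ex < min(ex_grid)) || any(peaks$ex > max(ex_grid)) ||
        any(peaks$em < min(em_grid)) || any(peaks$em > max(em_grid))) {
      stop("validation error: peak outside the grids", call. = FALSE)
    }
  }
  exm <- matrix(ex_grid, nrow = length(ex_grid), ncol = length(em_grid))
  emm <- matrix(em_grid, nrow = length(ex_grid), ncol = length(em_grid),
                byrow = TRUE)
  m <- matrix(0, length(ex_grid), length(em_grid))
  for (k in seq_len(nrow(peaks))) {
    m <- m + peaks$height[k] *
      exp(-(exm - peaks$ex[k])^2 / (2 * peaks$sigma_ex[k]^2) -
            (emm - peaks$em[k])^2 / (2 * peaks$sigma_em[k]^2))
  }
  if (rayleigh) {
    m <- m + rayleigh_height * exp(-(emm - exm)^2 / (2 * 5^2)) +
      0.4 * rayleigh_height * exp(-(emm - 2 * exm)^2 / (2 * 8^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + stats::rnorm(length(m), sd = noise_sd)
  }
  eem(ex_grid, em_grid, m)
}

#' Simulate a differential pulse voltammogram
#'
#' A Gaussian oxidation peak on a linear baseline over a stated potential
#' window.
#'
#' @param E_p Peak potential in V.
#' @param I_p Peak current above baseline (uA).
#' @param width Gaussian s.d. in V (> 0), default 0.05.
#' @param baseline_slope,baseline_intercept Linear baseline (uA/V, uA).
#' @param potentials Potential grid in V (default 0.5..1.3 V, 2 mV pitch).
#' @param noise_sd Gaussian noise s.d. in uA (default 0).
#' @param seed Optional RNG seed (used only when noise is on).
#' @param label Trace label.
#' @return A [spectrum] (potential vs current).
#' @export
simulate_voltammogram <- function(E_p, I_p, width = 0.05,
                                  baseline_slope = 0,
                                  baseline_intercept = 0,
                                  potentials = seq(0.5, 1.3, by = 0.002),
                                  noise_sd = 0, seed = NULL, label = "") {
  if (!is.finite(width) || width <= 0) {
    stop("validation error: width must be positive", call. = FALSE)
  }
  v <- as.numeric(potentials)
  i <- baseline_intercept + baseline_slope * v +
    I_p * exp(-(v - E_p)^2 / (2 * width^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    i <- i + stats::rnorm(length(i), sd = noise_sd)
  }
  spectrum(v, i, label)
}
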