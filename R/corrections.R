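#' Inner-filter-effect correction
#'
#' Attenuation of both the excitation beam and the emitted light by sample
#' absorbance depresses measured fluorescence. The standard multiplicative
#' correction restores the signal from the absorbances at the excitation
#' and emission wavelengths:
#' \deqn{F_{cor} = F_{obs} \cdot 10^{(A_{ex} + A_{em})/2}}
#'
#' @param F_obs Observed fluorescence (a.u.); vectorized.
#' @param A_ex Absorbance at the excitation wavelength (>= 0).
#' @param A_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected fluorescence, same shape as `F_obs`.
#' @examples
#' correct_inner_filter(100, 0.2, 0.1) # 100 * 10^0.15
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(!is.finite(F_obs))) stop("F_obs must be finite", call. = FALSE)
  if (any(A_ex < 0) || any(A_em < 0)) {
    stop("validation error: absorbance must be non-negative", call. = FALSE)
  }
  F_obs * 10^((A_ex + A_em) / 2)
}

#' Interpolate an absorbance (or any) spectrum at a wavelength
#'
#' Linear interpolation between the bracketing grid points; exact at grid
#' points. Queries outside the abscissa range are an error rather than an
#' extrapolation.
#'
#' @param spectrum A [spectrum] object.
#' @param wavelength Query abscissa value(s), within the spectrum range.
#' @return Interpolated signal value(s).
#' @export
absorbance_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "spectrum"))
  rng <- range(spectrum$abscissa)
  if (any(wavelength < rng[1]) || any(wavelength > rng[2])) {
    stop(sprintf("range error: query outside abscissa range [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(spectrum$abscissa, spectrum$signal, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Beer-Lambert concentration from absorbance
#'
#' \eqn{c = A / (\epsilon \, l)}. Used e.g. to set the albumin working
#' concentration from its 280 nm absorbance
#' (\eqn{\epsilon = 36{,}500\ M^{-1} cm^{-1}} for BSA).
#'
#' @param A Absorbance (>= 0); vectorized.
#' @param epsilon Molar absorptivity in M^-1 cm^-1 (> 0).
#' @param path_length Cuvette path length in cm (> 0), default 1.
#' @return Concentration in mol/L.
#' @examples
#' conc_from_absorbance(0.1095, 36500) # the 3 uM albumin working solution
#' @export
conc_from_absorbance <- function(A, epsilon, path_length = 1) {
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("validation error: epsilon must be positive", call. = FALSE)
  }
  if (!is.finite(path_length) || path_length <= 0) {
    stop("validation error: path_length must be positive", call. = FALSE)
  }
  if (any(A < 0)) stop("validation error: absorbance must be >= 0", call. = FALSE)
  A / (epsilon * path_length)
}

#' Inner-filter-correct a whole titration series
#'
#' For each rung of the ladder, reads the absorbance at the excitation
#' wavelength and at the emission maximum of the F0 (zero-ligand) spectrum
#' from the rung's absorbance spectrum, then applies
#' [correct_inner_filter()]. By default the correction is a scalar per rung
#' (A_em held at the F0 emission-maximum wavelength across the titration);
#' `pointwise = TRUE` instead evaluates A_em at every emission wavelength of
#' each spectrum.
#'
#' A series without absorbance spectra, or one whose absorbance is
#' identically zero, is returned unchanged.
#'
#' @param series A [titration_series] with `absorbance_spectra`.
#' @param pointwise Apply the correction per emission wavelength instead of
#'   as a scalar per spectrum.
#' @return A corrected [titration_series].
#' @export
correct_titration <- function(series, pointwise = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$absorbance_spectra)) return(series)
  f0 <- series$emission_spectra[[1]]
  em_wl <- f0$abscissa[which.max(f0$signal)]
  out <- series
  for (i in seq_along(series$ligand_concs)) {
    ab <- series$absorbance_spectra[[i]]
    a_ex <- absorbance_at(ab, series$excitation_wavelength)
    sp <- series$emission_spectra[[i]]
    if (pointwise) {
      a_em <- absorbance_at(ab, sp$abscissa)
    } else {
      a_em <- absorbance_at(ab, em_wl)
    }
    out$emission_spectra[[i]] <- spectrum(
      sp$abscissa, correct_inner_filter(sp$signal, a_ex, a_em), sp$label)
  }
  out
}
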