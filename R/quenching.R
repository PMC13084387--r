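# Simple OLS of y on x returning slope, intercept and Pearson r.
# r is NA when either variable is constant (correlation undefined).
ols_line <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]), r = r)
}

#' Read the fluorescence intensity of each titration rung
#'
#' By default the intensity is the per-spectrum emission maximum; with
#' `wavelength` set, the signal is interpolated at that fixed emission
#' wavelength instead (the convention for site-marker experiments, read at
#' 347 nm).
#'
#' For noisy spectra, `smooth_halfwidth` averages the signal over a boxcar
#' window of that half-width (in abscissa units) centred on the readout
#' point. Around a band maximum the window applies the same band-shape
#' factor to every rung, so it cancels exactly in the F0/F ratios the
#' downstream fits consume while suppressing point noise.
#'
#' @param series A [titration_series].
#' @param wavelength Optional fixed emission wavelength in nm.
#' @param smooth_halfwidth Boxcar half-width in nm (default 0: single
#'   point).
#' @return Numeric vector of intensities, one per rung.
#' @export
titration_intensities <- function(series, wavelength = NULL,
                                  smooth_halfwidth = 0) {
  stopifnot(inherits(series, "titration_series"))
  read_one <- function(sp) {
    target <- if (is.null(wavelength)) {
      sp$abscissa[which.max(sp$signal)]
    } else {
      wavelength
    }
    if (smooth_halfwidth > 0) {
      keep <- abs(sp$abscissa - target) <= smooth_halfwidth
      mean(sp$signal[keep])
    } else if (is.null(wavelength)) {
      max(sp$signal)
    } else {
      absorbance_at(sp, wavelength)
    }
  }
  vapply(series$emission_spectra, read_one, numeric(1))
}

#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation \eqn{F_0/F = 1 + K_{SV} [Q]} by ordinary
#' least squares of \eqn{F_0/F} on the quencher concentration. The slope is
#' the Stern-Volmer constant \eqn{K_{SV}}; the intercept is reported, not
#' forced to 1. The bimolecular quenching rate constant is
#' \eqn{k_q = K_{SV}/\tau_0} with \eqn{\tau_0} the unquenched fluorophore
#' lifetime (default 1e-8 s, the standard protein intrinsic-fluorescence
#' scale).
#'
#' Zero-concentration points (the F0 measurement itself) are excluded from
#' the regression.
#'
#' @param F0 Unquenched fluorescence intensity (a.u.), > 0.
#' @param F_values Fluorescence at each quencher concentration, all > 0.
#' @param Q_values Quencher concentrations in mol/L, same length.
#' @param tau0 Unquenched lifetime in seconds (default 1e-8).
#' @param temperature Optional temperature in K, carried on the result.
#' @return An object of class `quenching_fit` with fields `K_SV` (M^-1),
#'   `intercept`, `k_q` (M^-1 s^-1), `tau0`, `r` and `points`.
#' @examples
#' Q <- seq(1e-5, 8e-5, 1e-5)
#' f <- 1000 / (1 + 3.62e4 * Q)
#' stern_volmer_fit(1000, f, Q)
#' @export
stern_volmer_fit <- function(F0, F_values, Q_values, tau0 = 1e-8,
                             temperature = NA_real_) {
  if (!is.finite(F0) || F0 <= 0) {
    stop("validation error: F0 must be positive", call. = FALSE)
  }
  if (length(F_values) != length(Q_values)) {
    stop("F_values and Q_values must have equal length", call. = FALSE)
  }
  if (any(F_values <= 0)) {
    stop("validation error: all F values must be positive", call. = FALSE)
  }
  if (!is.finite(tau0) || tau0 <= 0) {
    stop("validation error: tau0 must be positive", call. = FALSE)
  }
  keep <- Q_values > 0
  Q <- Q_values[keep]
  y <- F0 / F_values[keep]
  if (length(Q) < 3) {
    stop("fit error: need at least 3 quencher-present points", call. = FALSE)
  }
  line <- ols_line(Q, y)
  structure(list(K_SV = line$slope, intercept = line$intercept,
                 k_q = line$slope / tau0, tau0 = tau0, r = line$r,
                 temperature = temperature,
                 points = data.frame(Q = Q, F0_over_F = y)),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("<quenching_fit> K_SV = %.4g M^-1, k_q = %.4g M^-1 s^-1 (tau0 = %g s), intercept = %.4g, r = %.4f, %d points\n",
              x$K_SV, x$k_q, x$tau0, x$intercept, x$r, nrow(x$points)))
  invisible(x)
}

#' Classify the quenching mechanism from the temperature trend of K_SV
#'
#' Collisional (dynamic) quenching intensifies with temperature because
#' diffusion accelerates, so K_SV rises; ground-state complexation (static
#' quenching) weakens as complexes dissociate, so K_SV falls. A strictly
#' increasing K_SV across temperatures is therefore called dynamic, strictly
#' decreasing static, anything else indeterminate.
#'
#' Optionally annotates whether each \eqn{k_q} exceeds the
#' diffusion-controlled limit (~2e10 M^-1 s^-1), a secondary line of
#' evidence often quoted alongside the temperature trend.
#'
#' @param fits A list of [stern_volmer_fit()] results carrying
#'   temperatures, or a data frame with columns `temperature` and `K_SV`.
#' @param annotate_diffusion_limit Add a `k_q_exceeds_diffusion_limit`
#'   logical vector (needs `k_q` available).
#' @param diffusion_limit The limit in M^-1 s^-1 (default 2e10).
#' @return An object of class `mechanism_call` with fields `verdict`
#'   (`"dynamic"`, `"static"` or `"indeterminate"`) and `K_SV_by_T`.
#' @export
classify_mechanism <- function(fits, annotate_diffusion_limit = FALSE,
                               diffusion_limit = 2e10) {
  if (is.data.frame(fits)) {
    tab <- data.frame(temperature = fits$temperature, K_SV = fits$K_SV)
    kq <- if ("k_q" %in% names(fits)) fits$k_q else NULL
  } else {
    tab <- data.frame(
      temperature = vapply(fits, function(f) f$temperature, numeric(1)),
      K_SV = vapply(fits, function(f) f$K_SV, numeric(1)))
    kq <- vapply(fits, function(f) f$k_q, numeric(1))
  }
  if (nrow(tab) < 2) {
    stop("fit error: need K_SV at >= 2 temperatures", call. = FALSE)
  }
  if (anyDuplicated(tab$temperature)) {
    stop("validation error: duplicate temperatures", call. = FALSE)
  }
  ord <- order(tab$temperature)
  tab <- tab[ord, , drop = FALSE]
  d <- diff(tab$K_SV)
  verdict <- if (all(d > 0)) "dynamic" else if (all(d < 0)) "static" else
    "indeterminate"
  out <- structure(list(verdict = verdict, K_SV_by_T = tab),
                   class = "mechanism_call")
  if (annotate_diffusion_limit && !is.null(kq)) {
    out$k_q_exceeds_diffusion_limit <- kq[ord] > diffusion_limit
    out$diffusion_limit <- diffusion_limit
  }
  out
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s quenching (K_SV at %s K: %s)\n",
              x$verdict, paste(x$K_SV_by_T$temperature, collapse = "/"),
              paste(signif(x$K_SV_by_T$K_SV, 3), collapse = "/")))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Estimates the association constant \eqn{K_a} and apparent binding-site
#' number \eqn{n} from the double-log form of the binding isotherm with
#' free-ligand depletion correction:
#' \deqn{\log_{10}\frac{F_0 - F}{F} = n \log_{10} K_a +
#'   n \log_{10}\left([L_T] - \frac{(F_0-F)[P_T]}{F_0}\right)}
#' The slope of the OLS line is \eqn{n} and
#' \eqn{K_a = 10^{\mathrm{intercept}/n}}.
#'
#' Points with apparent enhancement (\eqn{F \ge F_0}) or a non-positive
#' free-ligand term are dropped with a warning rather than failing the fit;
#' at least 3 usable points are required.
#'
#' @param F0 Unquenched intensity (a.u.), > 0.
#' @param F_values Intensities at each total ligand concentration.
#' @param L_T Total ligand concentrations in mol/L (quencher-present rungs).
#' @param P_T Total protein concentration in mol/L.
#' @return An object of class `binding_fit` with fields `K_a` (M^-1), `n`,
#'   `r`, `points`, `dropped` (indices) and `warning_flag` (TRUE when the
#'   slope was non-positive).
#' @export
double_log_fit <- function(F0, F_values, L_T, P_T) {
  if (!is.finite(F0) || F0 <= 0) {
    stop("validation error: F0 must be positive", call. = FALSE)
  }
  if (length(F_values) != length(L_T)) {
    stop("F_values and L_T must have equal length", call. = FALSE)
  }
  if (!is.finite(P_T) || P_T < 0) {
    stop("validation error: P_T must be non-negative", call. = FALSE)
  }
  dF <- F0 - F_values
  free <- L_T - dF * P_T / F0
  ok <- is.finite(F_values) & F_values > 0 & dF > 0 & free > 0
  dropped <- which(!ok)
  if (sum(ok) < 3) {
    stop(sprintf("fit error: only %d usable points (dropped: %s)",
                 sum(ok), paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d point(s) with F >= F0 or non-positive free-ligand term (indices %s)",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  x <- log10(free[ok])
  y <- log10(dF[ok] / F_values[ok])
  line <- ols_line(x, y)
  n <- line$slope
  warn <- !is.finite(n) || n <= 0
  K_a <- if (warn) NA_real_ else 10^(line$intercept / n)
  structure(list(K_a = K_a, n = n, intercept = line$intercept, r = line$r,
                 points = data.frame(log_free_ligand = x,
                                     log_quench_ratio = y),
                 dropped = dropped, warning_flag = warn),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_a = %.4g M^-1, n = %.4g, r = %.4f, %d points%s\n",
              x$K_a, x$n, x$r, nrow(x$points),
              if (x$warning_flag) " [non-positive slope]" else ""))
  invisible(x)
}

#' Percent fluorescence quenched
#'
#' @param F0 Unquenched intensity, > 0.
#' @param F Quenched intensity; vectorized.
#' @return `100 * (F0 - F) / F0`, in percent.
#' @export
percent_quench <- function(F0, F) {
  if (!is.finite(F0) || F0 <= 0) {
    stop("validation error: F0 must be positive", call. = FALSE)
  }
  100 * (F0 - F) / F0
}

#' Site-marker competition comparison
#'
#' Compares ligand-induced quenching of the bare protein with quenching in
#' the presence of two site markers (classically a Sudlow site I marker
#' such as phenylbutazone and a site II marker such as ibuprofen). F/F0
#' curves are read at a fixed emission wavelength (default 347 nm) for each
#' series; the divergence score of a marker is the mean absolute difference
#' of its curve from the plain-protein curve. The ligand is assigned to the
#' site of the marker with the LARGER divergence — pre-occupying the
#' ligand's own site perturbs its quenching curve the most.
#'
#' @param plain [titration_series] of the bare protein.
#' @param with_marker_A Series premixed with marker A.
#' @param with_marker_B Series premixed with marker B.
#' @param wavelength Fixed emission wavelength in nm (default 347).
#' @param site_A,site_B Site labels of the two markers (defaults "I", "II").
#' @return An object of class `marker_report`: F/F0 curves, both divergence
#'   scores, and `assigned_site` (`"indeterminate"` when the scores tie).
#' @export
site_marker_comparison <- function(plain, with_marker_A, with_marker_B,
                                   wavelength = 347,
                                   site_A = "I", site_B = "II") {
  for (s in list(plain, with_marker_A, with_marker_B)) {
    stopifnot(inherits(s, "titration_series"))
  }
  ladder <- plain$ligand_concs
  if (!isTRUE(all.equal(ladder, with_marker_A$ligand_concs)) ||
      !isTRUE(all.equal(ladder, with_marker_B$ligand_concs))) {
    stop("validation error: ligand ladders differ between series",
         call. = FALSE)
  }
  ratio <- function(series) {
    f <- titration_intensities(series, wavelength = wavelength)
    f / f[1]
  }
  r_plain <- ratio(plain)
  r_a <- ratio(with_marker_A)
  r_b <- ratio(with_marker_B)
  div_a <- mean(abs(r_a - r_plain))
  div_b <- mean(abs(r_b - r_plain))
  assigned <- if (div_a > div_b) site_A else if (div_b > div_a) site_B else
    "indeterminate"
  structure(list(
    curves = data.frame(ligand_conc = ladder, plain = r_plain,
                        marker_A = r_a, marker_B = r_b),
    divergence_A = div_a, divergence_B = div_b,
    site_A = site_A, site_B = site_B,
    wavelength = wavelength, assigned_site = assigned),
    class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report> divergence A (site %s) = %.4g, B (site %s) = %.4g -> assigned site %s\n",
              x$site_A, x$divergence_A, x$site_B, x$divergence_B,
              x$assigned_site))
  invisible(x)
}
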